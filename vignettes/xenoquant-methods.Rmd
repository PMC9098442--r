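---
title: "Methods: calibration, validation, quantitation and infant exposure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, validation, quantitation and infant exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoquant)
```

# Scope and model

`xenoquant` implements the data-processing layer of a multi-class targeted
LC-MS/MS human-biomonitoring assay: everything that happens after peak
integration. Inputs are long-format tables of integrated MRM peak areas
(one row per sample x analyte, with a role column distinguishing
calibrants, solvent calibrants, spikes, matrix/system blanks and unknowns)
plus a panel configuration holding each analyte's chemical class,
calibration matrix, optional internal-standard link, health-based guidance
value and blank-correction flag.

The quantitation model is a weighted straight line per analyte and matrix,

$$y_i = a + b\,x_i + \varepsilon_i,\qquad
  \hat{a},\hat{b} = \arg\min \sum_i w_i (y_i - a - b x_i)^2,\quad
  w_i = 1/x_i,$$

with response $y$ (peak area, or area ratio to an isotopically labelled
internal standard) and concentration $x$ in ng/mL. The $1/x$ weighting
reflects the roughly proportional growth of signal variance with
concentration at trace level; on homoscedastic noiseless data the weighted
and unweighted fits coincide exactly, which the test suite asserts.
Linearity is judged by the coefficient of determination *of the weighted
objective* (the quantity the fit actually minimises), with acceptance at
$R^2 > 0.9$. Calibration never extrapolates above the top calibrant:
higher responses are flagged `above_range` rather than reported.

Matrix effects are summarised as signal suppression/enhancement,
$\mathrm{SSE} = 100\,b_\text{matrix}/b_\text{solvent}$ (%), evaluated once
per validation run from run-wise slopes and averaged.

# Sensitivity: LOD and LOQ

Limits are defined through signal-to-noise: LOD at S/N = 3, LOQ at
S/N = 10, with per-measurement S/N
$(\text{area} - \text{intercept})/\text{noise}$ from an explicit noise
column, so the definition is unambiguous in-package (vendor software
differs in how noise windows are taken). Per calibrant level the mean S/N
is used, and the limit is the concentration where a straight-line fit of
$\log(\text{S/N})$ against $\log(x)$ crosses the threshold. This choice is
deliberate: for a proportional S/N response the crossing is exact (a line
with S/N = 10 at 0.05 ng/mL yields LOQ 0.05 and LOD 0.015, the 10:3
ratio), and unlike "report the lowest calibrant level whose S/N meets the
threshold" it is not upward-biased by the additive noise floor, which near
the LOQ perturbs single-injection S/N by about one unit and would otherwise
push the estimate to the next level about a quarter of the time. Reporting
a calibrant level (`method = "lowest-level"`) is retained only for the
degenerate case of a single usable level. Limits are estimated once per
validation run and averaged arithmetically across the three runs; this
"average LOQ" also drives the conditional recovery correction. Increasing
every noise value can only increase the estimated LOQ (property-tested).

# Quantitation rules

Unknowns are quantified in a fixed order:

1. **Inverse prediction** from the analyte's matrix-matched curve
   ($x = (y - \hat a)/\hat b$, floored at zero). Serum and plasma share a
   calibration.
2. **System-blank correction** for the contamination-prone analytes
   flagged in the panel (bisphenols, phthalate metabolites and similar
   extractables/leachables from labware): the contamination level is the
   mean of triplicate water-blank concentrations read off the *solvent*
   calibration, subtracted with flooring at zero. Correction precedes the
   recovery step because the contamination enters after extraction (tubes,
   LC system) and therefore does not experience extraction losses; with
   that order the generator's ground truth is recovered exactly on
   noiseless data, which is the package's end-to-end identity test.
   Method-validation results are corrected with the same value.
3. **Censoring**: at or above the average LOQ (or S/N > 10) a value is
   `quantified`; from LOD to LOQ `below_loq`; below LOD `below_lod`. The
   boundary is closed on the right — exactly at the LOQ counts as
   quantified, exactly at the LOD as below_loq — fixing a convention the
   strict "<LOQ" labels leave open.
4. **Conditional recovery correction**: only reliable detections
   (concentration above the average LOQ, or S/N > 10) are divided by the
   analyte's average extraction recovery. The average is taken across both
   spike levels and all three validation days. Recoveries used for
   validation pass/fail are computed *before* this correction, which would
   otherwise make them 100% by construction.

Censored values are substituted downstream by policy: half the LOQ for
descriptive statistics and distribution summaries, the full LOQ for
upper-bound intake estimation (which therefore dominates the statistics
policy on every censored record), or zero for lower bounds.

# Method validation

Per analyte, matrix and spike level (3x and 30x the approximate LOQ,
triplicate preparations on three days):

* **Recovery** = 100 x detected/spiked; accepted between 50 and 120%.
* **Intermediate precision** = RSD over the nine spiking results;
  **repeatability** = RSD over six same-day injections of the low-level
  validation batch. Both are compared to tiered limits — 32% below
  10 ng/mL, 27% to 100 ng/mL, 23% to 1000 ng/mL, 16% above — which are
  deliberately stricter than the Horwitz tolerances the guideline
  suggests ($\mathrm{RSD} = 2^{1 - 0.5\log_{10} C}$, i.e. 45%, 64% and
  91% at 1, 0.1 and 0.01 ng/mL); Horwitz values are still reported for
  reference.
* **Linearity**: weighted $R^2 > 0.9$.
* **Selectivity**: the mean response of triplicate matrix and system
  blanks must not exceed 30% of the lowest calibrant's response. The 30%
  figure is an explicit, configurable default ("screened for interfering
  peaks" fixes no number); blank-corrected analytes are screened on the
  residual after subtracting their determined contamination, since for
  them the interference is quantified and removed rather than
  disqualifying.

An analyte "fulfils all criteria" at a level when every verdict passes;
the matrix summary reports the percentage of analytes fulfilling all
criteria at at least one level, plus the median recovery. Verdicts are
monotone: improving any single metric never flips a pass to a fail
(property-tested).

# Exposure and risk assessment

The high-exposure infant scenario assumes 1000 mL of breast milk per day
and a 6 kg body weight. The assumed concentration per analyte is the
highest quantified value, or the LOQ if the analyte was only seen below
it. The hypothetical upper-bound intake is

$$\mathrm{hUBI} = \frac{c\,[\mathrm{ng/mL}] \times 1000\,\mathrm{mL/day}}
  {6\,\mathrm{kg} \times 1000}\ \ \mu\mathrm{g/kg\ bw/day}.$$

Adult TDI/ADI guidance values are corrected by one third for infants below
16 weeks; BMDL10 values are never corrected, and enter a margin of
exposure $\mathrm{MoE} = \mathrm{BMDL}_{10}/\mathrm{hUBI}$ with concern
flagged strictly below 10,000. Class intakes (e.g. all bisphenols) sum the
member concentrations before conversion, so cumulative intake is additive.

**Rounding ledger.** All intermediates are kept at full double precision;
display values are rounded to two significant figures, and ratios/margins
to the nearest integer above 10 (two significant figures below). Published
risk tables are not always consistent about whether the division uses the
full-precision or the displayed intake, so the table emits both
conventions side by side: the default divides full-precision values, and a
display-compatibility column pre-rounds the intake (and infant guidance
value) to two significant figures first. Guidance values ship as data
(`inst/extdata/milk_guidance_panel.yaml`), not code, because agency
recommendations change over time.

# Synthetic data: what it emulates and what it does not

The generator exists so every stage is testable against known ground truth
without any external download. Per analyte it draws:

* matrix-matched and solvent calibration series (default 7 levels,
  geometric from 0.5x to 50x the true LOQ — two decades) per validation
  day;
* spiking experiments (2 levels x 3 replicates x 3 days) passing through
  the true extraction recovery, plus 6 same-day repeat injections;
* triplicate matrix and water blanks carrying the system contamination;
* unknown cohort samples with log-normal true concentrations.

The noise model is
$\text{area} = \mu(1 + cv\,\varepsilon_1) + \text{floor}\,\varepsilon_2$,
truncated at zero — heteroscedastic, consistent with the 1/x weighting —
and the emitted noise column equals the floor, so the true LOQ has the
closed form $10\,\text{floor}/b_\text{matrix}$ and the generated S/N at it
is 10 in expectation. An optional per-day sensitivity factor multiplies
all of a day's signals and the internal-standard areas, so IS
normalisation demonstrably cancels it.

Longitudinal series emulate repeated single-subject sampling: constant,
episodic (per-day Bernoulli events multiplying the level by a log-normal
burst — mimicking isolated dietary exposure spikes without claiming their
mechanism) and accumulating (AR(1) with autocorrelation 0.95, a slow drift
as for bioaccumulative compounds) dynamics; analytes sharing an exposure
source co-vary through a shared latent day factor (default loading 0.9,
giving rank correlations near 0.8); days below a per-analyte reporting
limit — the quantile of the level distribution matching the target
detection probability — are emitted as censored; and the sampling schedule
can be irregularly thinned (days kept with probability 0.75, a stand-in
for, not a reconstruction of, a real schedule).

What the generator does *not* emulate: chromatogram-shaped signals,
carryover, retention-time drift, pharmacokinetics of mother-to-milk
transfer, or correlated matrix effects across analytes. Passing tests
therefore demonstrate the correctness of the arithmetic and decision rules
under the stated noise model, not method performance on real extracts;
cohort-dependent published figures (detection counts, matrix-wise pass
rates and median recoveries) are data properties and are only mirrored by
constructed fixtures with a designed outcome.

# Numerical choices and degenerate inputs

* Weighted fits require at least five distinct non-zero levels; zero
  concentrations are excluded under 1/x weighting with a warning.
* Noiseless tables have no defined S/N: `estimate_lod_loq()` errors, and
  the batch calibrator then reports zero limits so that noiseless
  end-to-end identity tests can run with every value quantified.
* Negative blank-corrected concentrations are floored at zero and
  re-censored; blank correction is idempotent once contamination is
  removed.
* Quartiles use linear interpolation between order statistics
  (`quantile` type 7), stated explicitly because violin-plot software
  conventions differ.
* Inter-analyte correlation defaults to Spearman rank correlation,
  robust to the mass point that half-LOQ substitution creates; cells with
  fewer than three overlapping days or a constant series are reported as
  unavailable rather than zero.
* Internal-standard mapping is explicit panel data with no default: the
  assay's IS-to-analyte assignment is configuration, not inference.
* Pipeline stage order: validation runs before quantitation of unknowns
  because the conditional recovery correction consumes the validated
  average recoveries.
* All randomness flows from one master seed recorded in the run manifest;
  per-stage substreams are derived deterministically from it, so outputs
  are a pure function of (inputs, config, seed).

# Problem sizes used by the shipped checks

The test suite and the demonstration configuration run at deliberately
small scale, chosen to exercise every code path while keeping a full run
interactive: panels of one to eight analytes, seven-level calibrations
over three days, twelve-sample cohorts, 120–200-day longitudinal series,
100-seed Monte-Carlo loops for estimator-convergence properties and
100-dataset oracle comparisons for the weighted fit. The exposure table is
evaluated at the full 27-analyte guidance registry shipped with the
package.

# Known limitations

* No uncertainty propagation on reported concentrations (point values
  only), and no probabilistic exposure modelling, body-weight growth
  curves or dose-addition mixture toxicology beyond the class-sum intake.
* No decision-limit machinery (CCalpha/CCbeta) beyond the implemented
  criteria.
* Censoring-aware statistics use substitution, not maximum-likelihood or
  Kaplan-Meier estimators for left-censored data; with heavy censoring the
  half-LOQ mass point biases dispersion estimates.
* The wet-lab chemistry itself (extraction, deconjugation enzymology,
  instrument parameters) is out of scope; paired comparisons of treated
  vs untreated aliquots summarise its effect without modelling it.
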