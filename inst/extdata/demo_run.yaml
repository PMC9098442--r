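# Demonstration run: simulate a full measurement campaign for the demo
# panel, then calibrate, validate, quantify, assess and summarize.
panel: demo_panel.yaml
seed: 7
stages: [simulate, calibrate, validate, quantify, assess, summarize]
simulate:
  truth:
    - {analyte: BPA, matrix: milk, true_slope: 800, sse_true: 0.8,
       recovery_true: 0.85, noise_floor: 4, noise_cv: 0.05,
       contamination_conc: 0.3}
    - {analyte: MBP, matrix: milk, true_slope: 500, sse_true: 0.7,
       recovery_true: 0.6, noise_floor: 8, noise_cv: 0.05,
       contamination_conc: 0.1}
    - {analyte: daidzein, matrix: milk, true_slope: 1200, sse_true: 0.9,
       recovery_true: 0.75, noise_floor: 3, noise_cv: 0.05}
    - {analyte: PFOA, matrix: milk, true_slope: 2000, sse_true: 1.05,
       recovery_true: 0.95, noise_floor: 2, noise_cv: 0.05}
    - {analyte: jacobine-N-oxide, matrix: milk, true_slope: 900,
       sse_true: 0.6, recovery_true: 0.55, noise_floor: 5, noise_cv: 0.05}
  design:
    unknowns: 12
  longitudinal:
    n_days: 120
    sampling_gaps: true
    profiles:
      - {analyte: daidzein, dynamics: episodic, median_conc: 0.02,
         dispersion: 0.8, detection_prob: 0.6, correlation_group: food}
      - {analyte: jacobine-N-oxide, dynamics: episodic, median_conc: 0.03,
         dispersion: 0.8, detection_prob: 0.4, correlation_group: food}
      - {analyte: PFOA, dynamics: accumulating, median_conc: 0.05,
         dispersion: 0.2, detection_prob: 0.9}
      - {analyte: MBP, dynamics: constant, median_conc: 1.5,
         dispersion: 0.5, detection_prob: 0.95}
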