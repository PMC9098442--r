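# High-exposure infant intake scenario: 1000 mL breast milk per day,
# 6 kg body weight; TDI/ADI corrected to one third for infants below
# 16 weeks; MoE against the uncorrected BMDL10, low concern above 10,000.

#' Assumed concentration for the high-exposure scenario
#'
#' Upper-bound convention: the highest quantified concentration when any
#' exists, otherwise the LOQ for analytes detected only below it.
#'
#' @param results Data frame of quantitation results for one analyte with
#'   columns `conc` and `status` (an `xq_quant` subset works).
#' @param loq Average LOQ, ng/mL.
#' @return List with `conc` (ng/mL) and `assumed_from`
#'   (`"max_quantified"` or `"loq"`).
#' @export
assumed_concentration <- function(results, loq) {
  if (!nrow(results)) stop("empty result series", call. = FALSE)
  detected <- results$status %in% c("quantified", "below_loq")
  if (!any(detected))
    stop("no detections; analyte excluded from assessment", call. = FALSE)
  q <- results$conc[results$status == "quantified"]
  q <- q[is.finite(q)]
  if (length(q)) list(conc = max(q), assumed_from = "max_quantified")
  else list(conc = loq, assumed_from = "loq")
}

#' Hypothetical upper-bound intake (hUBI)
#'
#' hUBI = concentration (ng/mL) x milk intake (mL/day) / body weight (kg),
#' converted from ng to ug per kg body weight per day. Full precision is
#' returned; display rounding to two significant figures is applied by the
#' reporting layer.
#'
#' @param conc Milk concentration, ng/mL.
#' @param intake_volume Daily milk consumption, mL/day (default 1000).
#' @param bw Body weight, kg (default 6).
#' @return Intake in ug/kg bw/day.
#' @export
hubi <- function(conc, intake_volume = 1000, bw = 6) {
  stopifnot(all(conc >= 0))
  if (any(bw <= 0)) stop("body weight must be > 0", call. = FALSE)
  conc * intake_volume / bw / 1000
}

#' Infant-corrected guidance value
#'
#' Adult TDI/ADI values are corrected by a factor of one third for infants
#' below 16 weeks of age. BMDL10 values are never corrected.
#'
#' @param adult_value Adult TDI or ADI, ug/kg bw/day (> 0).
#' @return Infant guidance value, ug/kg bw/day (full precision).
#' @export
infant_guidance <- function(adult_value) {
  stopifnot(all(adult_value > 0))
  adult_value / 3
}

#' Ratio of infant guidance value to intake
#'
#' @param guidance_infant Infant-corrected TDI/ADI, ug/kg bw/day.
#' @param hubi Intake, ug/kg bw/day.
#' @return Dimensionless ratio at full precision; `Inf` ("not limiting")
#'   when `hubi` is 0.
#' @export
risk_ratio <- function(guidance_infant, hubi) {
  if (hubi == 0) return(Inf)
  stopifnot(hubi > 0)
  guidance_infant / hubi
}

#' Margin of exposure against a BMDL10
#'
#' MoE = BMDL10 / hUBI; a margin above 10,000 is considered of low concern
#' for genotoxic carcinogens (the boundary itself is not of concern:
#' strict `<`). `compat = TRUE` pre-rounds the intake to two significant
#' figures before dividing, matching reporting pipelines that divide by the
#' displayed intake value.
#'
#' @param bmdl10 BMDL10, ug/kg bw/day (> 0).
#' @param hubi Intake, ug/kg bw/day (> 0).
#' @param compat Logical, pre-round `hubi` to 2 significant figures.
#' @return List with `moe` and `concern` (TRUE when MoE < 10,000).
#' @export
moe <- function(bmdl10, hubi, compat = FALSE) {
  stopifnot(bmdl10 > 0)
  if (hubi <= 0) stop("hubi must be > 0 for a margin of exposure",
                      call. = FALSE)
  m <- bmdl10 / (if (compat) signif(hubi, 2) else hubi)
  list(moe = m, concern = m < 10000)
}

#' Cumulative intake over a chemical class
#'
#' Member assumed concentrations are summed before the intake conversion,
#' so the cumulative hUBI is additive across disjoint groups.
#'
#' @param concs Assumed concentrations of the group members, ng/mL.
#' @param intake_volume,bw Scenario parameters, see [hubi()].
#' @return Cumulative intake, ug/kg bw/day.
#' @export
cumulative_hubi <- function(concs, intake_volume = 1000, bw = 6) {
  if (!length(concs)) stop("empty group", call. = FALSE)
  hubi(sum(concs), intake_volume, bw)
}

#' Build a full exposure/risk assessment table
#'
#' One row per detected analyte, ordered by chemical class then name:
#' assumed concentration and its provenance, hUBI, infant-corrected
#' guidance value (TDI/ADI only), ratio of guidance to intake or margin of
#' exposure (BMDL10), in both rounding conventions, and the concern flag.
#' Analytes without guidance values get intake columns only.
#'
#' @param panel An `xq_panel` (guidance values are read from it).
#' @param assumed Data frame with columns `analyte`, `conc` (ng/mL) and
#'   optionally `assumed_from`; typically collected via
#'   [assumed_concentration()].
#' @param intake_volume,bw Scenario parameters, see [hubi()].
#' @return Data frame of class `xq_assessment` with full-precision columns
#'   (`hubi`, `guidance_infant`, `ratio`, `moe`, `moe_compat`,
#'   `ratio_compat`) and display columns (`hubi_disp` 2 s.f.,
#'   `ratio_disp`/`moe_disp` integer above 10, 2 s.f. below).
#' @export
build_assessment_table <- function(panel, assumed, intake_volume = 1000,
                                   bw = 6) {
  stopifnot(inherits(panel, "xq_panel"), is.data.frame(assumed),
            all(c("analyte", "conc") %in% names(assumed)))
  unknown <- setdiff(assumed$analyte, names(panel))
  if (length(unknown))
    stop("analyte(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(assumed)), function(i) {
    a <- assumed$analyte[i]
    spec <- panel[[a]]
    g <- spec$guidance
    h <- hubi(assumed$conc[i], intake_volume, bw)
    row <- data.frame(
      analyte = a, chemical_class = spec$chemical_class,
      assumed_conc = assumed$conc[i],
      assumed_from = if ("assumed_from" %in% names(assumed))
        assumed$assumed_from[i] else NA_character_,
      guidance_kind = if (is.null(g)) "none" else g$kind,
      guidance_adult = if (is.null(g)) NA_real_ else g$value,
      guidance_infant = NA_real_, hubi = h,
      ratio = NA_real_, ratio_compat = NA_real_,
      moe = NA_real_, moe_compat = NA_real_, concern = NA,
      stringsAsFactors = FALSE)
    if (!is.null(g)) {
      if (g$kind %in% c("TDI", "ADI")) {
        gi <- infant_guidance(g$value)
        row$guidance_infant <- gi
        row$ratio <- risk_ratio(gi, h)
        row$ratio_compat <- if (h > 0) signif(gi, 2) / signif(h, 2) else Inf
      } else {
        m <- moe(g$value, h)
        row$moe <- m$moe
        row$moe_compat <- moe(g$value, h, compat = TRUE)$moe
        row$concern <- m$concern
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chemical_class, out$analyte), , drop = FALSE]
  rownames(out) <- NULL
  out$hubi_disp <- signif(out$hubi, 2)
  out$guidance_infant_disp <- signif(out$guidance_infant, 2)
  out$ratio_disp <- display_ratio(out$ratio)
  out$moe_disp <- display_ratio(out$moe)
  out$moe_compat_disp <- display_ratio(out$moe_compat)
  out$ratio_compat_disp <- display_ratio(out$ratio_compat)
  class(out) <- c("xq_assessment", "data.frame")
  out
}

# ratios/margins: integers when >= 10, two significant figures below
display_ratio <- function(x) {
  ifelse(is.na(x) | !is.finite(x), x, ifelse(x >= 10, round(x), signif(x, 2)))
}

#' @export
print.xq_assessment <- function(x, ...) {
  needed <- c("analyte", "assumed_conc", "guidance_kind", "guidance_adult",
              "hubi_disp", "ratio_disp", "moe_disp")
  if (!all(needed %in% names(x))) {
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat("<xq_assessment> high-exposure infant scenario, ", nrow(x),
      " analytes\n", sep = "")
  show <- data.frame(analyte = x$analyte,
                     conc = x$assumed_conc,
                     guidance = ifelse(x$guidance_kind == "none", "-",
                                       paste0(x$guidance_kind, " ",
                                              x$guidance_adult)),
                     hUBI = x$hubi_disp,
                     `ratio/MoE` = ifelse(!is.na(x$ratio_disp), x$ratio_disp,
                                          x$moe_disp),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
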