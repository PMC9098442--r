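# In-code fixtures shared across the suite.

# small panel built programmatically; n analytes named A1..An in one matrix
make_panel <- function(n = 1L, matrix = "milk", blank_correct = rep(FALSE, n),
                       internal_standard = rep(NA_character_, n),
                       classes = rep("plasticizer", n)) {
  specs <- lapply(seq_len(n), function(i)
    analyte_spec(paste0("A", i), classes[i], matrix,
                 internal_standard = internal_standard[i],
                 blank_correct = blank_correct[i]))
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(specs, class = "xq_panel")
}

make_truth <- function(panel, ...) {
  args <- list(...)
  tr <- lapply(panel, function(spec) {
    do.call(truth_record, c(list(analyte = spec$name,
                                 matrix = spec$calibration_matrix), args))
  })
  names(tr) <- names(panel)
  tr
}

# independent weighted least-squares oracle: normal equations by hand
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = beta[1L], slope = beta[2L])
}

# independent censoring oracle, written as a plain rule chain
censor_oracle <- function(conc, lod, loq, snr = NA_real_, upper = NA_real_) {
  if (!is.na(upper) && conc > upper) return("above_range")
  if ((!is.na(snr) && snr > 10) || conc >= loq) return("quantified")
  if (conc < lod) return("below_lod")
  "below_loq"
}

# textbook linear-interpolation quantile oracle (type 7), sort-based
quartile_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  c(one(0.25), one(0.5), one(0.75))
}

# write a panel yaml built in code, return its path
write_panel_yaml <- function(entries, path = tempfile(fileext = ".yaml")) {
  yaml::write_yaml(list(analytes = entries), path)
  path
}
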