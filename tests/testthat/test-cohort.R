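test_that("detection summaries follow the <LOQ token convention", {
  res <- data.frame(
    conc = c(0.1, NA, NA, 0.3, 0.2),
    status = c("quantified", "below_loq", "below_lod", "quantified",
               "quantified"))
  ds <- detection_summary(res, cohort = "plasma", analyte = "A1")
  expect_equal(ds$n_positive, 4L)
  expect_equal(ds$min_conc, "<LOQ")
  expect_equal(ds$max_conc, "0.3")
  # all nondetect rows are suppressed
  nd <- data.frame(conc = NA_real_, status = "below_lod")
  expect_null(detection_summary(nd, analyte = "A1"))
  # constant quantified series
  same <- data.frame(conc = c(2, 2), status = "quantified")
  ds2 <- detection_summary(same, analyte = "A1")
  expect_equal(ds2$min_conc, ds2$max_conc)
  # counts are invariant to unit scaling
  scaled <- res; scaled$conc <- scaled$conc * 1000
  expect_equal(detection_summary(scaled, analyte = "A1")$n_positive, 4L)
})

test_that("censoring-aware quartiles use half-LOQ substitution and type-7 interpolation", {
  unc <- data.frame(conc = 1:5, status = "quantified")
  expect_equal(distribution_summary(unc, loq = 0.1),
               c(q1 = 2, median = 3, q3 = 4))
  cens <- data.frame(conc = rep(NA_real_, 4), status = "below_loq")
  expect_equal(distribution_summary(cens, loq = 0.4),
               c(q1 = 0.2, median = 0.2, q3 = 0.2))
  expect_error(distribution_summary(
    data.frame(conc = NA_real_, status = "below_lod")[0, ], 0.4),
    "no detections")
  # sort-based oracle over random censored series
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    conc <- stats::rlnorm(n)
    status <- sample(c("quantified", "below_loq"), n, replace = TRUE)
    loq <- stats::runif(1, 0.1, 1)
    d <- data.frame(conc = ifelse(status == "quantified", conc, NA),
                    status = status)
    vals <- ifelse(status == "quantified", conc, loq / 2)
    expect_equal(unname(distribution_summary(d, loq)),
                 quartile_oracle(vals))
  }
})

test_that("correlation matrices are symmetric with unit diagonal and NA guards", {
  ps <- list(
    exposure_profile("A1", "constant", 1, dispersion = 0.6,
                     correlation_group = "g", loading = 0.9),
    exposure_profile("A2", "constant", 2, dispersion = 0.6,
                     correlation_group = "g", loading = 0.9),
    exposure_profile("A3", "constant", 5, dispersion = 0.4))
  lg <- generate_longitudinal(ps, n_days = 200, seed = 12)
  cm <- correlation_matrix(lg)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), c(A1 = 1, A2 = 1, A3 = 1))
  expect_gt(cm$r["A1", "A2"], 0.7)
  # constant series yields an unavailable cell, not zero
  flat <- data.frame(day = rep(1:10, 2),
                     analyte = rep(c("A1", "A2"), each = 10),
                     conc = c(rep(1, 10), stats::runif(10)),
                     censored = FALSE, reporting_limit = 0)
  expect_true(is.na(correlation_matrix(flat)$r["A1", "A2"]))
  # insufficient overlap
  thin <- flat[c(1:2, 11:12), ]
  expect_true(is.na(correlation_matrix(thin)$r["A1", "A2"]))
  expect_equal(correlation_matrix(thin)$n["A1", "A2"], 2L)
})

test_that("independent analytes show near-zero mean rank correlation", {
  set.seed(7)
  ests <- vapply(1:200, function(s) {
    ps <- list(exposure_profile("A1", "constant", 1, dispersion = 0.5),
               exposure_profile("A2", "constant", 1, dispersion = 0.5))
    lg <- generate_longitudinal(ps, n_days = 50, seed = s)
    correlation_matrix(lg)$r["A1", "A2"]
  }, 0)
  expect_lt(abs(mean(ests)), 0.05)
})

test_that("paired comparisons summarise treated/untreated ratios", {
  u <- data.frame(sample_id = c("s1", "s2", "s3"), conc = c(1, 2, 4))
  t1 <- data.frame(sample_id = c("s1", "s2", "s3"), conc = c(1, 2, 4))
  expect_equal(paired_compare(u, t1)$median_ratio, 1)
  t2 <- data.frame(sample_id = c("s1", "s2", "s3"), conc = c(2, 4, 8))
  expect_equal(paired_compare(u, t2)$median_ratio, 2)
  # lossless deconjugation of a 60% conjugated fraction: ratio 1/(1-0.6)
  set.seed(3)
  total <- stats::rlnorm(30)
  u3 <- data.frame(sample_id = paste0("s", 1:30), conc = 0.4 * total)
  t3 <- data.frame(sample_id = paste0("s", 1:30), conc = total)
  expect_equal(paired_compare(u3, t3)$median_ratio, 2.5, tolerance = 1e-9)
  # zero denominators are excluded and counted
  u4 <- data.frame(sample_id = c("s1", "s2"), conc = c(0, 1))
  t4 <- data.frame(sample_id = c("s1", "s2"), conc = c(1, 3))
  pc <- paired_compare(u4, t4)
  expect_equal(pc$n_pairs, 1L); expect_equal(pc$n_excluded, 1L)
  expect_error(paired_compare(u4, data.frame(sample_id = "x", conc = 1)),
               "zero matched pairs")
})

test_that("covariate normalisation rescales and preserves ordering", {
  expect_equal(as.numeric(normalize_to_covariate(10, 2)), 5)
  expect_error(normalize_to_covariate(10, 0), "> 0")
  v <- c(1, 5, 3)
  expect_equal(order(as.numeric(normalize_to_covariate(v, 2))), order(v))
  # sample metadata validates its volume and covariate
  sm <- sample_meta("s1", "subj1", volume_used = 50,
                    covariate = c(creatinine = 85), collection_day = 28)
  expect_equal(sm$volume_used, 50)
  expect_error(sample_meta("s1", volume_used = 0), "volume_used")
  expect_error(sample_meta("s1", covariate = 3), "named")
})
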