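test_that("an exact line is recovered with perfect weighted R2", {
  cc <- fit_calibration(1:5, c(2, 4, 6, 8, 10))
  expect_equal(coef(cc), c(intercept = 0, slope = 2), tolerance = 1e-12)
  expect_equal(cc$r2, 1)
  expect_equal(cc$range, c(1, 5))
  # weighted and unweighted fits coincide on a noiseless line
  cu <- fit_calibration(1:5, c(2, 4, 6, 8, 10), weighting = "none")
  expect_equal(coef(cc), coef(cu), tolerance = 1e-12)
  expect_equal(invert_calibration(7, cc), 3.5)
})

test_that("weighted fits match an independent normal-equations oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    x <- sort(stats::runif(n, 0.01, 10))
    y <- 3 + 5 * x + x * stats::rnorm(n, 0, 0.2)  # heteroscedastic
    cc <- fit_calibration(x, y)
    ref <- wls_oracle(x, y, 1 / x)
    expect_equal(coef(cc), ref, tolerance = 1e-10)
  }
})

test_that("degenerate calibrations are rejected", {
  expect_error(fit_calibration(c(1, 1, 2, 2), c(1, 2, 3, 4)),
               "insufficient calibration levels")
  expect_warning(cc <- fit_calibration(c(0, 1, 2, 3, 4, 5),
                                       c(0.1, 2, 4, 6, 8, 10)),
                 "1/x weighting")
  expect_equal(cc$n_points, 5L)
  expect_error(invert_calibration(1, structure(list(slope = 0, intercept = 0),
                                               class = "calcurve")), "slope")
})

test_that("matrix effects are slope ratios in percent", {
  m <- fit_calibration(1:5, 0.8 * (1:5))
  s <- fit_calibration(1:5, 1.0 * (1:5))
  expect_equal(compute_sse(m, s), 80)
  expect_equal(compute_sse(s, s), 100)
  expect_equal(compute_sse(m, m), 100)
  neg <- fit_calibration(1:5, -(1:5))
  expect_error(compute_sse(m, neg), "unusable solvent calibration")
  u <- fit_calibration(1:5, 1:5, weighting = "none")
  expect_error(compute_sse(m, u), "weighting")
})

test_that("LOD/LOQ follow the S/N 3 and 10 definitions", {
  # linear S/N model, S/N = 200 * conc: exactly 10 at 0.05 ng/mL
  conc <- c(0.05, 0.1, 0.2, 0.5, 1)
  est <- estimate_lod_loq(conc, area = 200 * conc, noise = rep(1, 5))
  expect_equal(est$loq, 0.05, tolerance = 1e-9)
  expect_equal(est$lod, 0.015, tolerance = 1e-9)
  expect_lte(est$lod, est$loq)
  expect_equal(est$loq / est$lod, 10 / 3, tolerance = 1e-9)
  # dense grid-scan oracle: smallest concentration with predicted S/N >= 10
  grid <- seq(0.001, 1, by = 1e-4)
  expect_equal(est$loq, min(grid[200 * grid >= 10]), tolerance = 1e-3)
  expect_equal(est$lod, min(grid[200 * grid >= 3]), tolerance = 1e-3)
  # proportional S/N response: the regression crossing is exact
  est2 <- estimate_lod_loq(conc, area = 30 * conc, noise = rep(1, 5))
  expect_equal(est2$loq, 10 / 30, tolerance = 1e-9)
  expect_equal(est2$loq_method, "interpolated")
  # noiseless data has no defined S/N
  expect_error(estimate_lod_loq(conc, 200 * conc, rep(NA_real_, 5)),
               "S/N undefined")
  # all points below S/N 3
  expect_error(estimate_lod_loq(conc, 0.5 * conc, rep(1, 5)),
               "not detectable")
})

test_that("increasing noise can only increase the LOQ", {
  conc <- c(0.01, 0.05, 0.2, 1, 5)
  area <- 500 * conc
  loqs <- vapply(c(0.5, 1, 2, 5, 10), function(nf)
    estimate_lod_loq(conc, area, rep(nf, 5))$loq, 0)
  expect_true(all(diff(loqs) >= 0))
})

test_that("internal-standard normalisation forms area ratios", {
  pk <- peak_table(data.frame(
    sample_id = c("s1", "s2"), analyte = c("A1", "A2"), matrix = "milk",
    role = "unknown", area = c(100, 100), is_area = c(50, NA)))
  out <- normalize_by_is(pk, c(A1 = "A1-d4"))
  expect_equal(out$response, c(2, 100))
  expect_equal(out$used_is, c(TRUE, FALSE))
  pk2 <- peak_table(data.frame(
    sample_id = "s1", analyte = "A1", matrix = "milk", role = "unknown",
    area = 100))
  expect_warning(out2 <- normalize_by_is(pk2, c(A1 = "A1-d4")),
                 "internal-standard")
  expect_equal(nrow(out2), 0L)
})

test_that("IS normalisation cancels a day-to-day sensitivity shift", {
  panel <- make_panel(2, internal_standard = c("A1-d4", NA))
  tr <- make_truth(panel, true_slope = 1000, noise_floor = 1,
                   noise_cv = 0.02)
  batch <- generate_batch(panel, tr,
                          design = list(day_effects = c(1, 2, 1),
                                        unknowns = 0L),
                          seed = 3)
  pk <- normalize_by_is(batch$peaks, is_map(panel))
  sp <- pk[pk$role == "spike" & pk$batch != "repeat", ]
  sp <- sp[sp$nominal_conc == max(sp$nominal_conc), ]
  rsd_of <- function(a) {
    day_means <- tapply(sp$response[sp$analyte == a], sp$day[sp$analyte == a],
                        mean)
    stats::sd(day_means) / mean(day_means)
  }
  expect_lt(rsd_of("A1"), rsd_of("A2"))
})
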