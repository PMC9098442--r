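test_that("assumed concentrations follow the upper-bound convention", {
  all_cens <- data.frame(conc = c(NA, NA), status = c("below_loq",
                                                      "below_loq"))
  a <- assumed_concentration(all_cens, loq = 0.40)
  expect_equal(a$conc, 0.40); expect_equal(a$assumed_from, "loq")
  mixed <- data.frame(conc = c(0.2, 6.4, NA),
                      status = c("quantified", "quantified", "below_loq"))
  a <- assumed_concentration(mixed, loq = 0.16)
  expect_equal(a$conc, 6.4); expect_equal(a$assumed_from, "max_quantified")
  one <- data.frame(conc = 1.23, status = "quantified")
  expect_equal(assumed_concentration(one, 0.1)$conc, 1.23)
  expect_error(assumed_concentration(one[0, ], 0.1), "empty")
  nd <- data.frame(conc = NA_real_, status = "below_lod")
  expect_error(assumed_concentration(nd, 0.1), "no detections")
})

test_that("intake arithmetic reproduces the printed scenario values", {
  expect_equal(signif(hubi(6.4), 2), 1.1)
  expect_equal(signif(hubi(0.042), 2), 0.0070)
  expect_equal(hubi(0), 0)
  expect_equal(signif(infant_guidance(4.0), 2), 1.3)
  expect_equal(signif(infant_guidance(10), 2), 3.3)
  expect_equal(signif(infant_guidance(0.016), 2), 0.0053)
  expect_equal(round(risk_ratio(infant_guidance(0.63), hubi(0.092))), 14)
  expect_equal(round(risk_ratio(infant_guidance(2000), hubi(16))), 250)
  expect_equal(risk_ratio(1, 1), 1)
  expect_identical(risk_ratio(1, 0), Inf)
  m <- moe(70, hubi(0.021))
  expect_equal(round(m$moe), 20000); expect_false(m$concern)
  expect_equal(round(moe(480, hubi(0.042))$moe), 68571)
  mj <- moe(70, hubi(0.11), compat = TRUE)
  expect_equal(round(mj$moe), 3889); expect_true(mj$concern)
  expect_equal(signif(cumulative_hubi(c(0.40, 0.028, 0.051)), 2), 0.08)
  expect_equal(cumulative_hubi(0.4), hubi(0.4))
})

test_that("intake is linear in concentration and inverse in body weight", {
  set.seed(13)
  for (i in 1:50) {
    conc <- stats::runif(1, 0, 100); k <- stats::runif(1, 0.1, 10)
    bw <- stats::runif(1, 1, 100)
    expect_equal(hubi(k * conc, bw = bw), k * hubi(conc, bw = bw))
    expect_equal(hubi(conc, bw = k * bw), hubi(conc, bw = bw) / k)
    # margins and guidance ratios fall strictly as intake rises
    h1 <- stats::runif(1, 1e-4, 1); h2 <- h1 * stats::runif(1, 1.01, 5)
    expect_lt(moe(70, h2)$moe, moe(70, h1)$moe)
    expect_lt(risk_ratio(3.3, h2), risk_ratio(3.3, h1))
  }
  # cumulative intake is additive across disjoint groups before rounding
  a <- c(0.1, 0.2); b <- c(0.3)
  expect_equal(cumulative_hubi(c(a, b)),
               cumulative_hubi(a) + cumulative_hubi(b))
})

test_that("the concern boundary at a margin of 10,000 is strict", {
  h <- 0.007
  exact <- moe(10000 * h, h)
  expect_equal(exact$moe, 10000)
  expect_false(exact$concern)
  expect_true(moe(10000 * h * 0.999, h)$concern)
})

test_that("the assessment table reproduces every printed risk cell", {
  panel <- load_panel(system.file("extdata", "milk_guidance_panel.yaml",
                                  package = "xenoquant"))
  assumed <- utils::read.csv(system.file("extdata",
                                         "milk_assumed_concentrations.csv",
                                         package = "xenoquant"),
                             stringsAsFactors = FALSE)
  tab <- build_assessment_table(panel, assumed)
  cell <- function(a, col) tab[tab$analyte == a, col]
  expect_equal(cell("Bisphenol A (BPA)", "guidance_infant_disp"), 1.3)
  expect_equal(cell("Bisphenol A (BPA)", "ratio_disp"), 20)
  expect_equal(cell("Mono-n-butyl phthalate (MBP)", "hubi_disp"), 1.1)
  expect_equal(cell("PhIP", "hubi_disp"), 0.0070)
  expect_equal(cell("PhIP", "moe_disp"), 68571)
  expect_equal(cell("Perfluorooctanoic acid (PFOA)", "ratio_disp"), 14)
  expect_equal(cell("Methylparaben (MP)", "ratio_disp"), 870)
  expect_equal(cell("Propylparaben (PP)", "ratio_disp"), 250)
  expect_equal(cell("Riddelliin-N-oxide", "moe_disp"), 20000)
  expect_equal(cell("Jacobine-N-oxide", "moe_compat_disp"), 3889)
  expect_equal(cell("Scopolamine", "ratio_compat_disp"), 79)
  # analytes without guidance carry intake columns only
  expect_true(is.na(cell("Daidzein", "ratio")))
  expect_equal(cell("Daidzein", "guidance_kind"), "none")
  # deterministic ordering by class then name
  expect_false(is.unsorted(order(tab$chemical_class, tab$analyte)))
  # rebuilding from the table's own columns round-trips identically
  tab2 <- build_assessment_table(
    panel, data.frame(analyte = tab$analyte, conc = tab$assumed_conc,
                      assumed_from = tab$assumed_from,
                      stringsAsFactors = FALSE))
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
})
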