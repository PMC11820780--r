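test_that("drift correction is the identity without drift and flattens linear drift", {
  anchors <- data.frame(injection_index = c(1, 50), value = c(1000, 1000))
  expect_equal(drift_correct(c(500, 700), c(10, 40), anchors), c(500, 700))

  # QC areas declining linearly 100 -> 80: corrected QC areas are constant
  idx <- seq(1, 41, by = 10)
  qc_area <- seq(100, 80, length.out = length(idx))
  anchors2 <- data.frame(injection_index = idx, value = qc_area)
  corr <- drift_correct(qc_area, idx, anchors2, mode = "qc")
  expect_equal(corr, rep(100, length(idx)))
  expect_equal(stats::sd(corr) / mean(corr), 0)

  expect_error(drift_correct(1, 1, anchors[1, , drop = FALSE]), "2 drift")
})

test_that("drift correction reduces QC spread on a simulated drifting sequence", {
  truth <- synthetic_truth("m1", seed = 5, drift = c(1, 0.75))
  plan <- plan_validation_sequence(build_calibration_series("HILIC"),
                                   sprintf("s%d", 1:12), dilutions = 5,
                                   seed = 6, qc_every = 4)
  tab <- simulate_peak_table(truth, plan, seed = 7)
  qc <- tab[tab$role == "qc" & tab$transition == "quantifier", ]
  anchors <- data.frame(injection_index = qc$injection_index,
                        value = qc$area)
  corrected <- drift_correct(qc$area, qc$injection_index, anchors)
  rsd <- function(x) stats::sd(x) / mean(x)
  expect_lt(rsd(corrected), rsd(qc$area))
})

test_that("ion-ratio confirmation applies a relative tolerance", {
  expect_equal(check_ion_ratio(0.50, 0.50), "pass")
  expect_equal(check_ion_ratio(0.70, 0.50, 0.30), "fail")  # 0.20 > 0.15
  expect_equal(check_ion_ratio(0.64, 0.50, 0.30), "pass")  # 0.14 <= 0.15
  expect_equal(check_ion_ratio(NA, 0.50), "not evaluable")
  expect_equal(check_ion_ratio(c(0.5, NA, 2), 0.5),
               c("pass", "not evaluable", "fail"))
})

test_that("recovery correction rescales by 100/RA and is idempotent at 100%", {
  expect_equal(correct_by_recovery(50, 50), 100)
  expect_equal(correct_by_recovery(c(10, 20), 100), c(10, 20))
  expect_error(correct_by_recovery(10, 0), "> 0")
})

test_that("quantification selects the dilution and scales to plasma", {
  cc <- fit_calibration(c(1, 10, 100, 1000), 2 * c(1, 10, 100, 1000))
  cc$lloq <- 1; cc$uloq <- 1000

  # 50 ug/L measured at 1:5 (1:100 below LLOQ) -> plasma 250 ug/L
  q <- quantify_analyte(data.frame(dilution = c(5, 100),
                                   area = c(2 * 50, 2 * 0.5)), cc)
  expect_equal(q$concentration, 250)
  expect_equal(q$dilution_used, 5)
  expect_equal(q$censoring, "quantified")
  expect_false(q$recovery_corrected)

  # both dilutions in range: the most dilute wins
  q2 <- quantify_analyte(data.frame(dilution = c(5, 100),
                                    area = c(2 * 100, 2 * 5)), cc)
  expect_equal(q2$dilution_used, 100)
  expect_equal(q2$concentration, 500)
  # ... unless the least dilute is preferred (low-abundance classes)
  q3 <- quantify_analyte(data.frame(dilution = c(5, 100),
                                    area = c(2 * 100, 2 * 5)), cc,
                         prefer = "least_dilute")
  expect_equal(q3$dilution_used, 5)
  expect_equal(q3$concentration, 500)
})

test_that("recovery correction triggers outside the 70-130 band", {
  cc <- fit_calibration(c(1, 10, 100, 1000), 2 * c(1, 10, 100, 1000))
  cc$lloq <- 1; cc$uloq <- 1000
  areas <- data.frame(dilution = 5, area = 2 * 10)

  # RA 50%: corrected x2 (50 -> 100 in plasma units)
  q <- quantify_analyte(areas, cc, ra = c("5" = 50))
  expect_equal(q$concentration, 100)
  expect_true(q$recovery_corrected)

  # RA 100%: correction (even when forced) changes nothing
  q_thr <- quantify_analyte(areas, cc, ra = c("5" = 100))
  q_alw <- quantify_analyte(areas, cc, ra = c("5" = 100),
                            correction = "always")
  expect_equal(q_thr$concentration, 50)
  expect_equal(q_alw$concentration, 50)
  expect_false(q_thr$recovery_corrected)
  expect_true(q_alw$recovery_corrected)

  # RA 80% inside the band: no correction under the threshold policy
  q80 <- quantify_analyte(areas, cc, ra = c("5" = 80))
  expect_equal(q80$concentration, 50)
  expect_false(q80$recovery_corrected)
})

test_that("saturation at both dilutions censors with a dilution advisory", {
  cc <- fit_calibration(c(1, 10, 100, 1000), 2 * c(1, 10, 100, 1000))
  cc$lloq <- 1; cc$uloq <- 1000
  # glucose-like: even 1:100 back-calculates above the ULOQ
  q <- quantify_analyte(data.frame(dilution = c(5, 100),
                                   area = c(2 * 90000, 2 * 4500)), cc)
  expect_equal(q$censoring, ">ULOQ")
  expect_true(is.na(q$concentration))
  expect_match(q$note, "1:500")

  # below LLOQ everywhere
  q2 <- quantify_analyte(data.frame(dilution = c(5, 100),
                                    area = c(2 * 0.2, 2 * 0.01)), cc)
  expect_equal(q2$censoring, "<LLOQ")
})

test_that("both dilutions agree at zero noise with no matrix effect", {
  m <- response_model("a", slope = 1500)
  cc <- fit_calibration(c(1, 10, 100, 1000),
                        simulate_areas(m, c(1, 10, 100, 1000)))
  cc$lloq <- 0.5; cc$uloq <- 2000
  native <- 800
  q <- quantify_analyte(data.frame(
    dilution = c(5, 100),
    area = simulate_areas(m, native / c(5, 100))), cc)
  for (pref in c("most_dilute", "least_dilute")) {
    qq <- quantify_analyte(data.frame(
      dilution = c(5, 100),
      area = simulate_areas(m, native / c(5, 100))), cc, prefer = pref)
    expect_equal(qq$concentration, native, tolerance = 1e-9)
  }
  expect_equal(q$concentration, native, tolerance = 1e-9)
})

test_that("ion ratios are checked against the curve reference when available", {
  cc <- fit_calibration(c(1, 10, 100, 1000), 2 * c(1, 10, 100, 1000))
  cc$lloq <- 1; cc$uloq <- 1000; cc$ion_ratio_ref <- 0.5
  q <- quantify_analyte(data.frame(dilution = 5, area = 2 * 10,
                                   qualifier_area = 0.48 * 2 * 10), cc)
  expect_equal(q$ion_ratio_observed, 0.48)
  expect_equal(q$ion_ratio_pass, "pass")
  qf <- quantify_analyte(data.frame(dilution = 5, area = 2 * 10,
                                    qualifier_area = 0.9 * 2 * 10), cc)
  expect_equal(qf$ion_ratio_pass, "fail")
  # single-transition analyte: not evaluable, quantification proceeds
  qs <- quantify_analyte(data.frame(dilution = 5, area = 2 * 10), cc)
  expect_equal(qs$ion_ratio_pass, "not evaluable")
  expect_match(qs$note, "single-transition")
  expect_equal(qs$concentration, 50)
})

test_that("duplicate injections combine by censoring-aware averaging", {
  r <- resolve_duplicates(100, "quantified", 110, "quantified")
  expect_equal(r$concentration, 105)
  expect_true(is.na(r$flag))

  r2 <- resolve_duplicates(100, "quantified", NA, "<LLOQ")
  expect_equal(r2$concentration, 100)
  expect_equal(r2$flag, "duplicate censoring mismatch")

  r3 <- resolve_duplicates(NA, ">ULOQ", NA, ">ULOQ")
  expect_equal(r3$censoring, ">ULOQ")
  expect_true(is.na(r3$concentration))
})

test_that("isomer deconvolution subtracts and conserves the sum", {
  expect_equal(deconvolute_isomers(10, 4)$concentration, 6)
  expect_equal(deconvolute_isomers(4, 4)$concentration, 0)
  dneg <- deconvolute_isomers(3, 4)
  expect_equal(dneg$concentration, 0)
  expect_true(dneg$negative_difference)
  expect_false(deconvolute_isomers(NA, 4)$evaluable)
  expect_false(deconvolute_isomers(3, NA)$evaluable)

  # pre-censoring, component + unique reconstitutes the sum exactly
  set.seed(91)
  for (i in 1:20) {
    s <- stats::runif(1, 0, 100); u <- stats::runif(1, 0, s)
    expect_equal(deconvolute_isomers(s, u)$concentration + u, s)
  }
})

test_that("trueness is the rounded measured-to-certified percentage", {
  t1 <- trueness_report("x", 100, 100)
  expect_equal(t1$trueness, 100)
  expect_true(t1$within_band)
  # half-away rounding at the band edge
  expect_equal(trueness_report("y", 1000, 695)$trueness, 70)
  expect_error(trueness_report("z", 0, 10), "> 0")
  tr <- trueness_report(c("a", "b"), c(100, 100), c(50, NA))
  expect_equal(attr(tr, "n_evaluable"), 1)
  expect_equal(attr(tr, "n_within"), 0)
})
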