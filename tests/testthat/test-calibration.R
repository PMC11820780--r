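test_that("exact linear points are fitted exactly", {
  cc <- fit_calibration(c(1, 10, 100), c(3, 21, 201))
  expect_equal(unname(cc$coefficients["intercept"]), 1)
  expect_equal(unname(cc$coefficients["slope"]), 2)
  expect_equal(cc$r2, 1)
  expect_equal(cc$model, "linear")
})

test_that("weighted fits match the normal-equations oracle", {
  set.seed(31)
  for (i in 1:30) {
    conc <- sort(exp(stats::runif(sample(4:9, 1), log(0.5), log(5000))))
    area <- 500 * conc * exp(stats::rnorm(length(conc), 0, 0.1)) + 20
    for (quad in c(FALSE, TRUE)) {
      model <- if (quad) "quadratic" else "linear"
      cc <- fit_calibration(conc, area, model = model)
      o <- wls_oracle(conc, area, quadratic = quad)
      n_cf <- if (quad) 3 else 2
      expect_equal(unname(cc$coefficients[seq_len(n_cf)]),
                   o$coefficients, tolerance = 1e-8)
      expect_equal(cc$r2, o$r2, tolerance = 1e-8)
    }
  }
})

test_that("auto selection falls back to quadratic for saturating data", {
  conc <- c(1, 3, 10, 30, 100, 300, 400)
  area <- conc - 0.001 * conc^2
  # verify via the independent oracle that the linear fit is sub-par
  expect_lt(wls_oracle(conc, area)$r2, 0.995)
  cc <- fit_calibration(conc, area, model = "auto")
  expect_equal(cc$model, "quadratic")
  expect_equal(unname(cc$coefficients["curvature"]), -0.001,
               tolerance = 1e-6)
  # clean linear data stays linear under auto
  expect_equal(fit_calibration(conc, 5 * conc)$model, "linear")
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(fit_calibration(c(1, 10), c(2, 20)), "3 distinct")
  expect_error(fit_calibration(c(1, 3, 10), c(1, 3, 10), model = "quadratic"),
               "4 distinct")
  # zero level is excluded, leaving too few points
  expect_error(fit_calibration(c(0, 1, 10), c(0, 2, 20)), "3 distinct")
})

test_that("LOD and LLOQ follow the S/N 3 and 10 rules", {
  # constructed so S/N crosses 3 at 10 ug/L and 10 at 30 ug/L
  conc <- c(1, 3, 10, 30, 100)
  height <- c(0.5, 1.5, 10, 40, 130)
  area <- height * 4
  res <- determine_lod_lloq(conc, area, height, noise_sd = rep(3.2, 5))
  expect_equal(res$lod, 10)
  expect_equal(res$lloq, 30)
  expect_false(res$fallback_used)

  # all levels comfortably above S/N 10: LLOQ is the lowest level
  res2 <- determine_lod_lloq(conc, conc * 40, conc * 10, rep(0.1, 5))
  expect_equal(res2$lloq, 1)
  expect_equal(res2$lod, 1)

  expect_error(determine_lod_lloq(rev(conc), area, height, rep(1, 5)),
               "ascending")
})

test_that("carryover-dominated low ends trigger the LLOQ fallback", {
  # flat areas at the three lowest levels, then a clear jump
  conc <- c(1, 3, 10, 30, 100)
  area <- c(100, 100, 100, 1000, 3300)
  height <- area / 4
  res <- determine_lod_lloq(conc, area, height, noise_sd = rep(1, 5))
  expect_true(res$fallback_used)
  expect_true(is.na(res$lod))
  expect_equal(res$lloq, 30)  # first level with ratio >= 2 and S/N >= 10
})

test_that("LOD and LLOQ are monotone in the noise level", {
  set.seed(41)
  conc <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  for (i in 1:20) {
    height <- 5 * conc * exp(stats::rnorm(7, 0, 0.05))
    ns <- stats::runif(1, 0.5, 5)
    k <- stats::runif(1, 1, 10)
    r1 <- determine_lod_lloq(conc, height * 4, height, rep(ns, 7))
    r2 <- determine_lod_lloq(conc, height * 4, height, rep(ns * k, 7))
    if (!is.na(r1$lod) && !is.na(r2$lod)) expect_gte(r2$lod, r1$lod)
    if (!is.na(r1$lloq) && !is.na(r2$lloq)) expect_gte(r2$lloq, r1$lloq)
  }
})

test_that("ULOQ search honours linearity and back-calculated accuracy", {
  conc <- c(1, 3, 10, 30, 100, 300, 1000, 3000, 10000)
  # a perfect line keeps the top level
  res <- determine_uloq(conc, 7 * conc, lloq = 1, model = "linear")
  expect_equal(res$uloq, 10000)

  # hard saturation above 3000: the top back-calculates far below nominal
  area <- ifelse(conc <= 3000, 7 * conc, 7 * 3000 + 0.5 * (conc - 3000))
  res2 <- determine_uloq(conc, area, lloq = 1)
  expect_equal(res2$uloq, 3000)

  # nothing quantifiable: no level qualifies
  res3 <- determine_uloq(c(1, 3, 10), c(5, 5, 5), lloq = 1, model = "linear")
  expect_false(res3$determined)
  expect_true(is.na(res3$uloq))
})

test_that("reference ion ratios average three representative levels", {
  expect_equal(ion_ratio_reference(c(50, 49, 51), c(100, 98, 102)), 0.5)
  expect_equal(ion_ratio_reference(c(7, 7, 7), c(7, 7, 7)), 1)
  set.seed(13)
  qa <- stats::runif(3, 10, 100); qn <- stats::runif(3, 100, 500)
  expect_equal(ion_ratio_reference(qa, qn), mean(qa / qn))
  expect_error(ion_ratio_reference(c(1, 2), c(2, 4)), "3 representative")
})

test_that("back-calculation inverts linear and quadratic curves", {
  lin <- fit_calibration(c(1, 10, 100), 2 * c(1, 10, 100))
  expect_equal(back_calculate(lin, 200, lloq = NA, uloq = NA)$conc, 100)

  # y = x - 0.001 x^2: area 90 has roots 100 and 900; the monotone branch
  # (below the vertex at 500) keeps 100
  xq <- c(10, 30, 60, 100, 150, 200)
  quad <- fit_calibration(xq, xq - 0.001 * xq^2, model = "quadratic")
  bc <- back_calculate(quad, 90, lloq = NA, uloq = 200)
  expect_equal(bc$conc, 100, tolerance = 1e-6)
  expect_equal(bc$flag, "quantified")

  # censoring flags
  lin$lloq <- 10; lin$uloq <- 100
  expect_equal(back_calculate(lin, 2)$flag, "<LLOQ")
  expect_equal(back_calculate(lin, 2)$conc, 1)
  expect_equal(back_calculate(lin, 1000)$flag, ">ULOQ")
})

test_that("back_calculate is the inverse of predict_response on the range", {
  set.seed(61)
  for (i in 1:15) {
    conc <- sort(exp(stats::runif(6, log(1), log(1000))))
    slope <- stats::runif(1, 100, 2000)
    lin <- fit_calibration(conc, slope * conc + 5)
    probe <- seq(min(conc), max(conc), length.out = 7)
    bc <- back_calculate(lin, predict_response(lin, probe),
                         lloq = NA, uloq = NA)
    expect_lt(max(abs(bc$conc - probe) / probe), 1e-9)

    curv <- -slope / (4 * max(conc))  # stays monotone on the range
    quad <- fit_calibration(conc, slope * conc + curv * conc^2,
                            model = "quadratic")
    bcq <- back_calculate(quad, predict_response(quad, probe),
                          lloq = NA, uloq = max(conc))
    expect_lt(max(abs(bcq$conc - probe) / probe), 1e-6)
  }
})

test_that("calibrate_analyte chains limits, curve and ion ratio", {
  conc <- build_calibration_series("HILIC")
  m <- response_model("a", slope = 1000, baseline_noise_sd = 1000 * 0.02,
                      ion_ratio = 0.4)
  area <- simulate_areas(m, conc)
  qual <- simulate_areas(m, conc, transition = "qualifier")
  cc <- calibrate_analyte(conc, area, height = area / 4,
                          noise_sd = rep(m$baseline_noise_sd / 4, length(conc)),
                          qualifier_area = qual)
  expect_equal(cc$lod, 0.1)    # expected S/N 3 crossing at 0.06 -> level 0.1
  expect_equal(cc$lloq, 0.3)   # S/N 10 crossing at 0.2 -> level 0.3
  expect_equal(cc$uloq, 50000)
  # baseline noise perturbs the per-level ratios slightly
  expect_equal(cc$ion_ratio_ref, 0.4, tolerance = 5e-3)
})
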