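test_that("carryover percentage and flag bins follow the blank/standard rule", {
  r <- carryover_pct(5, 100)
  expect_equal(r$carryover_pct, 5)
  expect_equal(r$flag, ">=5%")   # bins closed on the left

  r0 <- carryover_pct(0, 100)
  expect_equal(r0$carryover_pct, 0)
  expect_equal(r0$flag, "<1%")

  expect_warning(rb <- carryover_pct(120, 100), "100%")
  expect_equal(rb$carryover_pct, 120)
  expect_equal(rb$flag, ">=5%")

  expect_equal(carryover_pct(c(0.5, 1, 4.99), 100)$flag,
               c("<1%", "<5%", "<5%"))
  expect_error(carryover_pct(5, 0), "> 0")
})

test_that("carryover is invariant under rescaling both areas", {
  set.seed(71)
  for (i in 1:20) {
    b <- stats::runif(1, 0, 50); s <- stats::runif(1, 50, 1000)
    k <- stats::runif(1, 0.01, 100)
    expect_equal(carryover_pct(k * b, k * s)$carryover_pct,
                 carryover_pct(b, s)$carryover_pct, tolerance = 1e-12)
  }
})

test_that("slope-ratio recovery reproduces known matrix factors", {
  ca <- c(50, 100, 150, 200, 250, 300)
  neat <- data.frame(conc = ca, area = 1000 * ca)
  # identical series: 100%
  same <- apparent_recovery_slope(data.frame(conc = ca, area = 1000 * ca),
                                  neat)
  expect_equal(same$ra_mean, 100)
  # uniform 20% suppression: 80%, zero spread
  sup <- apparent_recovery_slope(
    data.frame(conc = c(0, ca), area = 0.8 * 1000 * (120 + c(0, ca))),
    neat)
  expect_equal(sup$ra_mean, 80)
  expect_equal(sup$rsd, 0, tolerance = 1e-9)
  expect_equal(sup$c_ns, 0.8 * 120)  # measured, not true, native conc
  expect_equal(sup$acceptance, "accept")
})

test_that("non-linear series are refused by the slope estimator", {
  ca <- c(50, 100, 150, 200, 250, 300)
  neat <- data.frame(conc = ca, area = 1000 * ca)
  bent <- data.frame(conc = ca, area = 1000 * ca - 2 * ca^2)
  expect_error(apparent_recovery_slope(bent, neat),
               "apparent_recovery_levels")
})

test_that("level-wise recovery implements the subtract-and-divide rule", {
  expect_equal(apparent_recovery_levels(150, 100, 50)$ra_mean, 100)

  # constant suppression at all 18 observations: mean 70, RSD 0
  ca <- rep(c(50, 100, 150, 200, 250, 300), each = 3)
  r <- apparent_recovery_levels(100 + 0.7 * ca, 100, ca)
  expect_equal(r$ra_mean, 70)
  expect_equal(r$rsd, 0, tolerance = 1e-9)
  expect_equal(length(r$ra_per_level), 18)
  expect_equal(r$estimator, "levelwise_quadratic")
  expect_equal(r$acceptance, "accept")

  # a spiked level measuring below native gives a negative RA, retained
  rn <- apparent_recovery_levels(c(90, 180, 150), 100, c(50, 50, 50))
  expect_true(rn$negative_levels)
  expect_equal(rn$ra_per_level[1], -20)
  expect_equal(rn$ra_mean, mean(c(-20, 160, 100)))

  expect_error(apparent_recovery_levels(c(1, 2), 1, c(1, 2, 3)), "length")
  expect_error(apparent_recovery_levels(c(1, 2), c(1, 2), c(1, 2)),
               "single")
})

test_that("recovery acceptance flags mirror the 70-130 band and RSD bound", {
  expect_equal(flag_recovery(83), "accept")
  expect_equal(flag_recovery(70), "accept")
  expect_equal(flag_recovery(130), "accept")
  expect_equal(flag_recovery(49, 10), "correct")
  expect_equal(flag_recovery(140, 8), "correct")
  expect_equal(flag_recovery(29, 105), "reject")
  expect_equal(flag_recovery(29, NA), "correct")  # no RSD: cannot reject
  expect_error(flag_recovery(NaN), "finite")
})

test_that("level-wise and slope-ratio estimates agree on noiseless linear data", {
  set.seed(81)
  for (i in 1:20) {
    slope <- stats::runif(1, 100, 5000)
    m <- stats::runif(1, 0.4, 1.4)
    c_ns_true <- stats::runif(1, 20, 500)
    ca <- rep(c(0.5, 1, 1.5, 2, 2.5, 3) * c_ns_true, each = 3)
    neat_levels <- c(0.5, 1, 1.5, 2, 2.5, 3) * c_ns_true
    neat <- data.frame(conc = neat_levels, area = slope * neat_levels)
    spiked <- data.frame(conc = c(0, ca),
                         area = m * slope * (c_ns_true + c(0, ca)))
    rs <- apparent_recovery_slope(spiked, neat)
    c_ns_meas <- m * c_ns_true
    rl <- apparent_recovery_levels(m * (c_ns_true + ca), c_ns_meas, ca)
    expect_equal(rs$ra_mean, 100 * m, tolerance = 1e-9)
    expect_equal(rl$ra_mean, rs$ra_mean, tolerance = 1e-9)
  }
})

test_that("estimator selection keys on the response shape of the neat standards", {
  set.seed(86)
  lv <- c(50, 100, 150, 200, 250, 300)
  ca <- rep(lv, each = 3)
  # linear analyte with mild noise: slope-ratio route
  lin_area <- function(conc, m = 1) 400 * m * conc * exp(rnorm(length(conc), 0, 0.04))
  spiked <- data.frame(conc = c(0, ca), area = lin_area(80 + c(0, ca), m = 0.8))
  neat <- data.frame(conc = ca, area = lin_area(ca))
  r <- estimate_recovery(spiked, neat, dilution = 5)
  expect_equal(r$estimator, "slope_ratio")
  expect_equal(r$ra_mean, 80, tolerance = 6)  # ~3 sigma at this noise

  # clearly saturating analyte: level-wise route with quadratic back-calc
  sat <- function(conc, m = 1) {
    m * (400 * conc - 0.5 * conc^2) * exp(rnorm(length(conc), 0, 0.005))
  }
  spiked_q <- data.frame(conc = c(0, ca), area = sat(80 + c(0, ca), m = 0.8))
  neat_q <- data.frame(conc = ca, area = sat(ca))
  rq <- estimate_recovery(spiked_q, neat_q, dilution = 5)
  expect_equal(rq$estimator, "levelwise_quadratic")
  expect_equal(rq$ra_mean, 80, tolerance = 2)
})

test_that("class-level summaries aggregate per-analyte recoveries", {
  res <- data.frame(
    analyte_id = c("a", "b", "c", "d"),
    class = c("amino acids", "amino acids", "sugars", "amino acids"),
    dilution = c(5, 5, 5, 100),
    ra_mean = c(80, 90, 60, 95))
  s <- class_recovery_summary(res)
  aa5 <- s[s$class == "amino acids" & s$dilution == 5, ]
  expect_equal(aa5$n, 2)
  expect_equal(aa5$mean_ra, 85)
  expect_equal(aa5$cv_pct, 100 * stats::sd(c(80, 90)) / 85)
})
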