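#' Carryover percentage
#'
#' Carryover is assessed by injecting a pure solvent blank directly after a
#' high standard (the 1 mg/L level, or the highest validation level for
#' analytes whose LLOQ exceeds 1 mg/L) and expressing the blank's peak area
#' as a percentage of the standard's:
#' `carryover = 100 * area_blank / area_standard`.
#'
#' Flags bin the percentage at 1% and 5% (intervals closed on the left):
#' `"<1%"` negligible, `"<5%"` acceptable, `">=5%"` problematic.  Values
#' above 100% additionally raise a warning (blank larger than standard
#' indicates an integration or sequence problem).
#'
#' @param blank_area peak area in the trailing blank (>= 0).
#' @param standard_area peak area of the preceding standard (> 0).
#' @return data.frame with `carryover_pct` and `flag`.
#' @export
#' @examples
#' carryover_pct(5, 100)   # 5%, flagged ">=5%"
#' carryover_pct(0, 100)   # 0%, "<1%"
carryover_pct <- function(blank_area, standard_area) {
  assert_num(blank_area, "blank_area", nonneg = TRUE)
  assert_num(standard_area, "standard_area", positive = TRUE)
  pct <- 100 * blank_area / standard_area
  flag <- as.character(cut(pct, c(0, 1, 5, Inf), right = FALSE,
                           labels = c("<1%", "<5%", ">=5%"),
                           include.lowest = TRUE))
  if (any(pct > 100)) {
    warning("carryover above 100%: blank area exceeds standard area")
  }
  data.frame(carryover_pct = pct, flag = flag, stringsAsFactors = FALSE)
}

# internal: shared recovery-result constructor
new_recovery_result <- function(analyte_id, estimator, ra_mean, ra_per_level,
                                rsd, c_ns, dilution, rsd_max) {
  structure(list(
    analyte_id = analyte_id,
    dilution = dilution,
    estimator = estimator,
    ra_mean = ra_mean,
    ra_per_level = ra_per_level,
    rsd = rsd,
    c_ns = c_ns,
    acceptance = flag_recovery(ra_mean, rsd, rsd_max = rsd_max),
    negative_levels = any(ra_per_level < 0)
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("apparent recovery (%s%s): RA = %.1f%%, RSD = %.1f%% -> %s\n",
              x$estimator,
              if (!is.na(x$dilution)) sprintf(", 1:%d", x$dilution) else "",
              x$ra_mean, x$rsd, x$acceptance))
  invisible(x)
}

#' Apparent recovery by the slope-ratio estimator
#'
#' For analytes with linear response, the mean apparent recovery of a
#' standard-addition experiment is the ratio of the regression slopes of
#' the spiked-matrix series and the neat-solvent series:
#' `RA = 100 * slope(spiked) / slope(neat)`.  Both series must be linear
#' with r2 above `r2_min` (default 0.995); otherwise the level-wise
#' estimator ([apparent_recovery_levels()]) with quadratic
#' back-calculation must be used instead, and this function stops with a
#' message saying so.
#'
#' The regression lines are fitted by ordinary (unweighted) least squares:
#' a spiking design spans less than one order of magnitude, so the
#' heteroscedasticity that motivates 1/x weighting of calibration curves
#' is mild here, and the zero-spike sample still carries the full native
#' signal, so a 1/x variance model keyed to the spike amount would
#' mis-weight the series and inflate the slope variance.
#'
#' Per-level recoveries (for the repeatability RSD) are computed alongside
#' by back-calculating every spiked observation through the neat line and
#' applying the level-wise definition.
#'
#' @param spiked data.frame with columns `conc` (spiking concentration
#'   added, ug/L; 0 rows = unspiked matrix) and `area`.
#' @param neat data.frame with columns `conc`, `area` for the neat-solvent
#'   standards.
#' @param c_ns measured native (unspiked) concentration; if `NULL` it is
#'   back-calculated from the mean area of the `conc == 0` rows of
#'   `spiked` (0 if there are none).
#' @param analyte_id optional identifier carried into the result.
#' @param dilution dilution factor of the plasma series (5 or 100),
#'   metadata only.
#' @param r2_min linearity bound for both fits.
#' @param rsd_max repeatability bound passed to [flag_recovery()].
#' @return object of class `recovery_result`.
#' @export
apparent_recovery_slope <- function(spiked, neat, c_ns = NULL,
                                    analyte_id = NA_character_,
                                    dilution = NA_integer_,
                                    r2_min = 0.995, rsd_max = 25) {
  ols <- function(d) {
    if (nrow(d) < 3 || length(unique(d$conc)) < 2) {
      stop("need at least 3 points on at least 2 levels for the slope fit")
    }
    fit <- stats::lm(area ~ conc, data = d)
    sst <- sum((d$area - mean(d$area))^2)
    r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NaN
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]), r2 = r2)
  }
  fit_sp <- ols(spiked)
  fit_ne <- ols(neat)
  if (!(fit_sp$r2 > r2_min) || !(fit_ne$r2 > r2_min)) {
    stop(sprintf(paste0("linearity precondition not met (spiked r2 = %.4f, ",
                        "neat r2 = %.4f); use apparent_recovery_levels() ",
                        "with quadratic back-calculation"),
                 fit_sp$r2, fit_ne$r2))
  }
  if (fit_ne$slope <= 0) stop("neat series has a non-positive slope")
  ra_mean <- 100 * fit_sp$slope / fit_ne$slope

  neat_line <- structure(list(
    model = "linear",
    coefficients = c(intercept = fit_ne$intercept, slope = fit_ne$slope,
                     curvature = 0),
    r2 = fit_ne$r2, weighting = "none",
    lod = NA_real_, lloq = NA_real_, uloq = NA_real_,
    ion_ratio_ref = NA_real_), class = "calibration_curve")
  if (is.null(c_ns)) {
    blank_rows <- spiked$conc == 0
    c_ns <- if (any(blank_rows)) {
      back_calculate(neat_line, mean(spiked$area[blank_rows]),
                     lloq = NA, uloq = NA)$conc
    } else 0
  }
  spk <- spiked[spiked$conc > 0, ]
  c_sp <- back_calculate(neat_line, spk$area, lloq = NA, uloq = NA)$conc
  per_level <- 100 * (c_sp - c_ns) / spk$conc
  rsd <- 100 * stats::sd(per_level) / abs(mean(per_level))

  new_recovery_result(analyte_id, "slope_ratio", ra_mean, per_level,
                      rsd, c_ns, dilution, rsd_max)
}

#' Apparent recovery by the level-wise estimator
#'
#' Per-observation apparent recovery of a standard-addition experiment:
#' the concentration measured in the spiked sample (`c_sp`, back-calculated
#' through the neat-solvent curve) minus the concentration measured in the
#' unspiked sample (`c_ns`), divided by the spiking concentration (`c_a`):
#' `RA = 100 * (c_sp - c_ns) / c_a`.
#'
#' The mean RA averages all observations (normally 6 levels x 3 replicates,
#' n = 18; a single high level in triplicate for analytes that cannot be
#' spiked across a range).  Repeatability is the relative standard
#' deviation of the per-observation recoveries (sample SD, n - 1).
#' Negative recoveries (spiked measuring below unspiked) are retained, not
#' truncated, so the RSD reflects the raw dispersion.
#'
#' @param c_sp measured concentrations in the spiked samples (ug/L).
#' @param c_ns measured native concentration in the unspiked sample
#'   (scalar, ug/L).
#' @param c_a spiking concentrations, one per observation (> 0).
#' @param analyte_id,dilution metadata carried into the result.
#' @param rsd_max repeatability bound passed to [flag_recovery()].
#' @return object of class `recovery_result`.
#' @export
#' @examples
#' apparent_recovery_levels(150, 100, 50)  # RA 100%
apparent_recovery_levels <- function(c_sp, c_ns, c_a,
                                     analyte_id = NA_character_,
                                     dilution = NA_integer_,
                                     rsd_max = 25) {
  if (length(c_sp) != length(c_a)) {
    stop("c_sp and c_a differ in length")
  }
  if (length(c_ns) != 1) stop("c_ns must be a single measured concentration")
  assert_num(c_a, "c_a", positive = TRUE)
  ra <- 100 * (c_sp - c_ns) / c_a
  ra_mean <- mean(ra)
  rsd <- if (length(ra) > 1) 100 * stats::sd(ra) / abs(ra_mean) else 0
  new_recovery_result(analyte_id, if (length(ra) > 3) "levelwise_quadratic"
                      else "single_level",
                      ra_mean, ra, rsd, c_ns, dilution, rsd_max)
}

#' Acceptance flag for an apparent recovery
#'
#' Recoveries between 70% and 130% are acceptable (`"accept"`); outside
#' that band, quantification must be corrected by the recovery
#' (`"correct"`, see [quantify_analyte()]) — unless the recovery is also
#' erratic, i.e. its repeatability RSD exceeds `rsd_max` (default 25%), in
#' which case the analyte is not reliably quantifiable and is flagged
#' `"reject"`.
#'
#' @param ra_mean mean apparent recovery, percent.
#' @param rsd repeatability RSD of the recoveries, percent (`NA` skips the
#'   reject check).
#' @param lower,upper acceptance band, percent.
#' @param rsd_max repeatability bound for rejection.
#' @return `"accept"`, `"correct"` or `"reject"`.
#' @export
#' @examples
#' flag_recovery(83)          # accept
#' flag_recovery(49, 10)      # correct
#' flag_recovery(29, 105)     # reject
flag_recovery <- function(ra_mean, rsd = NA, lower = 70, upper = 130,
                          rsd_max = 25) {
  if (!is.finite(ra_mean)) stop("ra_mean must be finite")
  if (ra_mean >= lower && ra_mean <= upper) return("accept")
  if (is.finite(rsd) && rsd > rsd_max) return("reject")
  "correct"
}

#' Estimate apparent recovery with automatic estimator selection
#'
#' Mirrors the validation protocol's estimator choice: analytes with a
#' linear response use the slope-ratio estimator
#' ([apparent_recovery_slope()]); analytes showing a quadratic
#' (saturating) response use the level-wise estimator
#' ([apparent_recovery_levels()]) with back-calculation through a
#' quadratic curve fitted to the neat standards.
#'
#' Whether the response is quadratic is judged on the neat standards: a
#' quadratic 1/x-weighted fit whose curvature term is significant at
#' `curvature_p` (default 0.05) marks the analyte as saturating.  The
#' spiking range spans less than one order of magnitude, so a raw r2
#' threshold cannot separate response curvature from measurement noise
#' there; `r2_min` (default 0.9) therefore acts only as a gross-failure
#' guard on the slope fits — erratic series that fail it also fall back
#' to the level-wise estimator.
#'
#' @inheritParams apparent_recovery_slope
#' @param curve optional `calibration_curve` for the analyte, fitted on the
#'   wide-range neat-solvent calibration standards.  When given, its
#'   auto-selected model decides the response shape, and the level-wise
#'   fallback back-calculates through it; otherwise both are derived from
#'   the narrow `neat` comparison series.
#' @param curvature_p significance level for the neat-series curvature
#'   test, used only when no `curve` is supplied.
#' @return a `recovery_result` from whichever estimator applied.
#' @export
estimate_recovery <- function(spiked, neat, c_ns = NULL, curve = NULL,
                              analyte_id = NA_character_,
                              dilution = NA_integer_,
                              r2_min = 0.9, curvature_p = 0.05,
                              rsd_max = 25) {
  n_levels <- length(unique(neat$conc[neat$conc > 0]))
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "calibration_curve"))
    quad_response <- curve$model == "quadratic"
  } else {
    quad_response <- FALSE
    if (n_levels >= 4) {
      keep <- neat$conc > 0
      x <- neat$conc[keep]; y <- neat$area[keep]
      qf <- summary(stats::lm(y ~ x + I(x^2), weights = 1 / x))$coefficients
      quad_response <- nrow(qf) == 3 && is.finite(qf[3, 4]) &&
        qf[3, 4] < curvature_p
    }
  }

  if (!quad_response) {
    res <- tryCatch(
      apparent_recovery_slope(spiked, neat, c_ns = c_ns,
                              analyte_id = analyte_id, dilution = dilution,
                              r2_min = r2_min, rsd_max = rsd_max),
      error = function(e) NULL)
    if (!is.null(res)) return(res)
  }

  bfit <- if (!is.null(curve)) curve else
    fit_calibration(neat$conc, neat$area,
                    model = if (quad_response && n_levels >= 4)
                      "quadratic" else "linear")
  if (is.null(c_ns)) {
    blank_rows <- spiked$conc == 0
    c_ns <- if (any(blank_rows)) {
      back_calculate(bfit, mean(spiked$area[blank_rows]),
                     lloq = NA, uloq = NA)$conc
    } else 0
  }
  spk <- spiked[spiked$conc > 0, ]
  upper <- if (!is.null(curve) && is.finite(curve$uloq)) curve$uloq else
    2 * max(neat$conc)
  c_sp <- back_calculate(bfit, spk$area, lloq = NA, uloq = upper)$conc
  usable <- is.finite(c_sp)
  apparent_recovery_levels(c_sp[usable], c_ns, spk$conc[usable],
                           analyte_id = analyte_id, dilution = dilution,
                           rsd_max = rsd_max)
}

#' Summarize recovery results by compound class
#'
#' Pure aggregation of per-analyte recovery results: mean RA and
#' between-analyte CV% per compound class, per dilution.
#'
#' @param results data.frame with columns `analyte_id`, `class`,
#'   `dilution`, `ra_mean`.
#' @return data.frame with one row per (class, dilution): `n`, `mean_ra`,
#'   `cv_pct`.
#' @export
class_recovery_summary <- function(results) {
  stopifnot(all(c("class", "dilution", "ra_mean") %in% names(results)))
  groups <- unique(results[, c("class", "dilution")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- results[results$class == groups$class[i] &
                     results$dilution == groups$dilution[i], ]
    data.frame(class = groups$class[i], dilution = groups$dilution[i],
               n = nrow(sub), mean_ra = mean(sub$ra_mean),
               cv_pct = 100 * stats::sd(sub$ra_mean) / mean(sub$ra_mean),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
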