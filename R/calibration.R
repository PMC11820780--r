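#' @title Weighted calibration curves
#'
#' @description
#' External calibration with 1/x-weighted least squares.  Weighting by the
#' reciprocal of the nominal concentration counteracts the strong
#' heteroscedasticity of LC-MS/MS peak areas over calibration ranges
#' spanning several orders of magnitude: unweighted fits are dominated by
#' the top levels and back-calculate poorly at the bottom of the range.
#' The zero-concentration standard is excluded from fits (its weight is
#' undefined); it serves only for blank/noise assessment.
#'
#' @name calibration
NULL

# internal: weighted coefficient of determination
weighted_r2 <- function(y, fitted, w) {
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
}

#' Fit a 1/x-weighted calibration curve
#'
#' Fits `area ~ conc` (linear) or `area ~ conc + conc^2` (quadratic) by
#' weighted least squares with weights `1/conc` on the non-zero levels.
#' With `model = "auto"` the linear model is kept when its weighted r2 is at
#' least `r2_linear` (default 0.995, the usual bioanalytical linearity
#' bound); otherwise the quadratic is fitted, which accommodates detector
#' saturation at the top of the range.
#'
#' @param conc nominal concentrations (ug/L); zero levels are dropped.
#' @param area quantifier peak areas.
#' @param model `"auto"`, `"linear"` or `"quadratic"`.
#' @param r2_linear weighted-r2 threshold for accepting the linear model in
#'   auto selection.
#' @return object of class `calibration_curve`: list with `model`,
#'   `coefficients` (`intercept`, `slope`, `curvature`), `r2`, `weighting`,
#'   `data` (the fitted levels), and placeholders `lod`, `lloq`, `uloq`,
#'   `ion_ratio_ref` filled in by the respective determinations.
#' @seealso [determine_lod_lloq()], [determine_uloq()], [back_calculate()]
#' @export
#' @examples
#' cc <- fit_calibration(c(1, 10, 100), c(3, 21, 201))
#' cc$coefficients   # intercept 1, slope 2
fit_calibration <- function(conc, area, model = c("auto", "linear", "quadratic"),
                            r2_linear = 0.995) {
  model <- match.arg(model)
  assert_num(conc, "conc", nonneg = TRUE)
  assert_num(area, "area")
  if (length(conc) != length(area)) stop("conc and area differ in length")
  keep <- conc > 0
  conc <- conc[keep]; area <- area[keep]
  n_distinct <- length(unique(conc))
  if (n_distinct < 2) stop("all calibration concentrations are identical")
  if (n_distinct < 3) stop("need at least 3 distinct non-zero levels")
  w <- 1 / conc

  fit_one <- function(quadratic) {
    if (quadratic) {
      fit <- stats::lm(area ~ conc + I(conc^2), weights = w)
      cf <- c(intercept = unname(stats::coef(fit)[1]),
              slope = unname(stats::coef(fit)[2]),
              curvature = unname(stats::coef(fit)[3]))
    } else {
      fit <- stats::lm(area ~ conc, weights = w)
      cf <- c(intercept = unname(stats::coef(fit)[1]),
              slope = unname(stats::coef(fit)[2]),
              curvature = 0)
    }
    list(coefficients = cf, r2 = weighted_r2(area, stats::fitted(fit), w))
  }

  if (model == "quadratic" && n_distinct < 4) {
    stop("need at least 4 distinct non-zero levels for a quadratic fit")
  }
  chosen <- model
  if (model == "auto") {
    lin <- fit_one(FALSE)
    if (lin$r2 >= r2_linear || n_distinct < 4) {
      chosen <- "linear"
      res <- lin
    } else {
      chosen <- "quadratic"
      res <- fit_one(TRUE)
    }
  } else {
    res <- fit_one(model == "quadratic")
  }

  structure(list(
    model = chosen,
    coefficients = res$coefficients,
    r2 = res$r2,
    weighting = "1/x",
    data = data.frame(conc = conc, area = area),
    lod = NA_real_, lloq = NA_real_, uloq = NA_real_,
    ion_ratio_ref = NA_real_
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("1/x-weighted %s calibration curve (r2 = %.5f)\n",
              x$model, x$r2))
  cat(sprintf("  area = %.4g + %.4g c %s\n", x$coefficients["intercept"],
              x$coefficients["slope"],
              if (x$model == "quadratic")
                sprintf("+ %.4g c^2", x$coefficients["curvature"]) else ""))
  cat(sprintf("  LOD %.4g | LLOQ %.4g | ULOQ %.4g ug/L | ion ratio %.3g\n",
              x$lod, x$lloq, x$uloq, x$ion_ratio_ref))
  invisible(x)
}

#' Predict peak area from a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param conc concentrations (ug/L).
#' @return predicted areas.
#' @export
predict_response <- function(curve, conc) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- curve$coefficients
  cf["intercept"] + cf["slope"] * conc + cf["curvature"] * conc^2
}

#' Determine LOD and LLOQ from a calibration series
#'
#' The limit of detection is the lowest level whose signal-to-noise ratio
#' (peak height over the standard deviation of baseline noise) reaches
#' `sn_lod` (default 3); the lower limit of quantification is the lowest
#' level reaching `sn_lloq` (default 10).
#'
#' Carryover fallback: at very low concentrations, injector carryover can
#' leave a constant residual peak so the areas of the lowest levels fail to
#' grow with concentration.  When the area series starts with one or more
#' consecutive level pairs whose area ratio is below `increase_factor`
#' (default 2; the calibration grids are roughly 3x-spaced), the LOD is
#' reported undetermined (`NA`) and the LLOQ becomes the lowest level at
#' which the area increases by at least `increase_factor` over the previous
#' level *and* S/N >= `sn_lloq`.
#'
#' @param conc nominal concentrations in ascending order (ug/L); a zero
#'   level may be present and is ignored.
#' @param area peak areas per level (replicates averaged beforehand or
#'   supplied per level).
#' @param height peak apex heights per level.
#' @param noise_sd baseline-noise standard deviation per level (same units
#'   as height).
#' @param sn_lod,sn_lloq signal-to-noise thresholds.
#' @param increase_factor consecutive-level area ratio below which the low
#'   end is treated as carryover-dominated.
#' @return list with `lod`, `lloq` (ug/L; `NA` if undetermined) and
#'   `fallback_used` (logical).
#' @export
determine_lod_lloq <- function(conc, area, height, noise_sd,
                               sn_lod = 3, sn_lloq = 10,
                               increase_factor = 2) {
  assert_num(conc, "conc", nonneg = TRUE)
  if (is.unsorted(conc, strictly = FALSE)) {
    stop("calibration levels must be in ascending concentration order")
  }
  keep <- conc > 0
  conc <- conc[keep]; area <- area[keep]
  height <- height[keep]; noise_sd <- noise_sd[keep]
  if (length(conc) < 2) stop("need at least 2 non-zero levels")
  sn <- height / noise_sd

  ratio <- c(NA_real_, area[-1] / area[-length(area)])
  # initial run of non-increasing pairs = carryover-dominated low end
  flat_run <- 0
  for (i in seq_along(ratio)[-1]) {
    if (!is.finite(ratio[i]) || ratio[i] < increase_factor) {
      flat_run <- i - 1
    } else {
      break
    }
  }
  fallback <- flat_run > 0

  if (!fallback) {
    lod_i <- which(sn >= sn_lod)[1]
    lloq_i <- which(sn >= sn_lloq)[1]
    lod <- if (is.na(lod_i)) NA_real_ else conc[lod_i]
    lloq <- if (is.na(lloq_i)) NA_real_ else conc[lloq_i]
  } else {
    lod <- NA_real_
    ok <- !is.na(ratio) & ratio >= increase_factor & sn >= sn_lloq
    lloq_i <- which(ok)[1]
    lloq <- if (is.na(lloq_i)) NA_real_ else conc[lloq_i]
  }
  list(lod = lod, lloq = lloq, fallback_used = fallback)
}

#' Determine the ULOQ of a calibration series
#'
#' Searches downward from the top level for the largest level `L` such that
#' the curve refitted on levels within `[lloq, L]` has weighted r2 above
#' `r2_min` (default 0.995) *and* the concentration back-calculated at `L`
#' falls within `backcalc_band` percent of nominal (default 95-105%).
#'
#' @param conc nominal concentrations, ascending (ug/L).
#' @param area peak areas.
#' @param lloq lower limit of quantification bounding the fit range below.
#' @param model `"auto"`, `"linear"` or `"quadratic"` for the refits.
#' @param r2_min minimum weighted r2.
#' @param backcalc_band length-2 percent band for back-calculated accuracy
#'   at the candidate ULOQ.
#' @return list with `uloq` (ug/L, `NA` if no level qualifies — flagged via
#'   `determined = FALSE`) and the curve refitted on `[lloq, uloq]`.
#' @export
determine_uloq <- function(conc, area, lloq, model = "auto",
                           r2_min = 0.995, backcalc_band = c(95, 105)) {
  assert_num(conc, "conc", nonneg = TRUE)
  if (is.unsorted(conc)) stop("levels must be ascending")
  keep <- conc >= lloq & conc > 0
  conc <- conc[keep]; area <- area[keep]
  levels_desc <- sort(unique(conc), decreasing = TRUE)
  for (L in levels_desc) {
    sub <- conc <= L
    n_lev <- length(unique(conc[sub]))
    if (n_lev < 3) break
    curve <- tryCatch(
      fit_calibration(conc[sub], area[sub], model = model, r2_linear = r2_min),
      error = function(e) NULL
    )
    if (is.null(curve) || curve$r2 <= r2_min) next
    top_area <- mean(area[conc == L])
    bc <- back_calculate(curve, top_area, lloq = 0, uloq = L)
    if (is.na(bc$conc)) next
    pct <- 100 * bc$conc / L
    if (pct >= backcalc_band[1] && pct <= backcalc_band[2]) {
      return(list(uloq = L, determined = TRUE, curve = curve))
    }
  }
  list(uloq = NA_real_, determined = FALSE, curve = NULL)
}

#' Reference ion ratio from calibration standards
#'
#' The compound-specific qualifier/quantifier peak-area ratio, obtained by
#' averaging the per-level ratios at (at least) three representative
#' calibration levels within the linear range.
#'
#' @param qualifier_area qualifier peak areas at the representative levels.
#' @param quantifier_area quantifier peak areas at the same levels (> 0).
#' @return mean qualifier/quantifier area ratio.
#' @export
#' @examples
#' ion_ratio_reference(c(50, 49, 51), c(100, 98, 102))  # 0.5
ion_ratio_reference <- function(qualifier_area, quantifier_area) {
  if (length(qualifier_area) != length(quantifier_area)) {
    stop("qualifier and quantifier vectors differ in length")
  }
  if (length(qualifier_area) < 3) {
    stop("need at least 3 representative calibration levels")
  }
  assert_num(quantifier_area, "quantifier_area", positive = TRUE)
  mean(qualifier_area / quantifier_area)
}

#' Back-calculate a concentration from a peak area
#'
#' Inverts the calibration curve.  Linear: `(area - intercept) / slope`.
#' Quadratic: the root of `curvature * c^2 + slope * c + intercept = area`
#' lying on the monotone branch (below the parabola vertex for a saturating
#' curve) and within `[0, 1.05 * uloq]`; the spurious high root beyond the
#' saturation turnover is rejected.
#'
#' Censoring: results below `lloq` are flagged `"<LLOQ"`, above `uloq`
#' `">ULOQ"`; an area with no admissible root is flagged `"out_of_range"`.
#' The numeric estimate is returned alongside the flag so callers can apply
#' dilution logic before censoring.
#'
#' @param curve a `calibration_curve`.
#' @param area observed quantifier area(s).
#' @param lloq,uloq quantification limits (default: taken from the curve;
#'   `NA` disables the respective check).
#' @return data.frame with columns `conc` (ug/L) and `flag` (one of
#'   `"quantified"`, `"<LLOQ"`, `">ULOQ"`, `"out_of_range"`).
#' @export
back_calculate <- function(curve, area, lloq = curve$lloq,
                           uloq = curve$uloq) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- curve$coefficients
  if (cf["slope"] <= 0) stop("calibration slope must be positive")
  upper <- if (is.na(uloq)) Inf else uloq * 1.05

  solve_one <- function(a) {
    if (curve$model == "linear" || cf["curvature"] == 0) {
      return((a - cf["intercept"]) / cf["slope"])
    }
    b2 <- cf["curvature"]; b1 <- cf["slope"]; b0 <- cf["intercept"] - a
    disc <- b1^2 - 4 * b2 * b0
    if (disc < 0) return(NA_real_)
    roots <- c((-b1 + sqrt(disc)) / (2 * b2), (-b1 - sqrt(disc)) / (2 * b2))
    vertex <- -b1 / (2 * b2)
    # monotone branch: concentrations on the same side of the vertex as 0
    ok <- if (b2 < 0) roots <= vertex else roots >= vertex & roots >= 0
    roots <- roots[ok & roots >= 0 & roots <= upper]
    if (length(roots) == 0) NA_real_ else min(roots)
  }

  conc <- vapply(area, solve_one, numeric(1))
  flag <- ifelse(is.na(conc), "out_of_range", "quantified")
  if (!is.na(lloq)) flag[!is.na(conc) & conc < lloq] <- "<LLOQ"
  if (!is.na(uloq)) flag[!is.na(conc) & conc > uloq] <- ">ULOQ"
  data.frame(conc = unname(conc), flag = flag, stringsAsFactors = FALSE)
}

#' Full calibration of one analyte
#'
#' Convenience wrapper chaining curve fitting, LOD/LLOQ determination, ULOQ
#' determination (the curve is refitted on the retained `[LLOQ, ULOQ]`
#' range) and the reference ion ratio.
#'
#' @param conc nominal concentrations, ascending (ug/L), zero level allowed.
#' @param area quantifier peak areas.
#' @param height peak heights (for S/N).
#' @param noise_sd baseline-noise standard deviations.
#' @param qualifier_area optional qualifier areas (same levels) for the
#'   reference ion ratio; the three levels nearest the geometric middle of
#'   the quantifiable range are used.
#' @param model model selection passed to [fit_calibration()].
#' @param ... further arguments to [determine_lod_lloq()].
#' @return a `calibration_curve` with `lod`, `lloq`, `uloq` and
#'   `ion_ratio_ref` filled in.
#' @export
calibrate_analyte <- function(conc, area, height, noise_sd,
                              qualifier_area = NULL, model = "auto", ...) {
  lims <- determine_lod_lloq(conc, area, height, noise_sd, ...)
  if (is.na(lims$lloq)) {
    stop("LLOQ could not be determined; analyte not quantifiable on this series")
  }
  ul <- determine_uloq(conc, area, lloq = lims$lloq, model = model)
  if (!ul$determined) {
    stop("ULOQ could not be determined; no level passes linearity and accuracy")
  }
  curve <- ul$curve
  curve$lod <- lims$lod
  curve$lloq <- lims$lloq
  curve$uloq <- ul$uloq
  if (!is.null(qualifier_area)) {
    inside <- which(conc >= lims$lloq & conc <= ul$uloq)
    if (length(inside) >= 3) {
      mid <- exp(mean(log(conc[inside])))
      pick <- inside[order(abs(log(conc[inside]) - log(mid)))][1:3]
      curve$ion_ratio_ref <- ion_ratio_reference(qualifier_area[pick],
                                                 area[pick])
    }
  }
  curve
}
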