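#' @title Synthetic peak-area data with known ground truth
#'
#' @description
#' The generator stands in for the instrument: it produces peak-area tables
#' with the statistical structure the downstream analysis assumes —
#' linear-to-saturating response curves, per-dilution matrix effects,
#' multiplicative lognormal measurement noise plus additive baseline noise,
#' carryover into trailing blanks, and slow multiplicative drift over the
#' injection sequence — together with the true parameters, so that every
#' estimator in the package can be checked by parameter recovery.
#' It does not simulate chromatogram shapes or ionization physics: areas,
#' heights and baseline-noise estimates are generated directly.
#'
#' @name synthetic_data
NULL

# peak height is emitted as area / PEAK_SHAPE_FACTOR: a fixed area-to-height
# proxy in lieu of a peak model
PEAK_SHAPE_FACTOR <- 4

#' Calibration level grids
#'
#' Two named grids are exposed, in ug/L:
#'
#' * `"validation"` — the 14-level series used for LOD/LLOQ/ULOQ
#'   determination: 0 and 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000,
#'   10000, 25000, 50000 ug/L (i.e. 0.0001-50 mg/L), identical for all
#'   three standard sets.
#' * `"working"` — a representative 7-level geometric series spanning the
#'   working calibration range of each standard set: 0.03-25000 ug/L for
#'   HILIC, 0.1-50000 ug/L for the two RP sets (`RP_Aqu`, polar to
#'   mid-polar; `RP_Hep`, mid-polar to nonpolar).  Real working grids are
#'   compound-specific; the geometric series is a stand-in with the printed
#'   extremes.
#'
#' @param calibration_set `"HILIC"`, `"RP_Aqu"` or `"RP_Hep"`.
#' @param grid `"validation"` (default) or `"working"`.
#' @return numeric vector of nominal levels in ug/L (ascending; the
#'   validation grid includes the 0 level).
#' @export
#' @examples
#' build_calibration_series("HILIC")          # 14 levels, 0 ... 50000
#' build_calibration_series("RP_Aqu", "working")
build_calibration_series <- function(calibration_set = c("HILIC", "RP_Aqu", "RP_Hep"),
                                     grid = c("validation", "working")) {
  calibration_set <- match.arg(calibration_set)
  grid <- match.arg(grid)
  if (grid == "validation") {
    return(1000 * c(0, 0.0001, 0.0003, 0.001, 0.003, 0.01, 0.03,
                    0.1, 0.3, 1, 3, 10, 25, 50))
  }
  rng <- if (calibration_set == "HILIC") c(0.03, 25000) else c(0.1, 50000)
  exp(seq(log(rng[1]), log(rng[2]), length.out = 7))
}

#' Build a standard-addition spiking design
#'
#' For analytes detected in the QC plasma, six spiking levels at 0.5, 1,
#' 1.5, 2, 2.5 and 3 times the predetermined native concentration are
#' used.  For analytes below the LOD in QC plasma, the levels are pinned to
#' the neat-solvent LLOQ: 12.5, 25, 37.5, 50, 62.5 and 75 times the LLOQ.
#' `mode = "single_level"` covers poorly soluble analytes that can only be
#' spiked at one high level.  Every level is spiked in triplicate
#' (n = 18 for six-level designs).
#'
#' @param analyte_id identifier.
#' @param native_conc native concentration in QC plasma (ug/L, > 0);
#'   exactly one of `native_conc` and `lloq` must be given.
#' @param lloq neat-solvent LLOQ (ug/L) for undetected analytes.
#' @param single_level if `TRUE`, keep only the highest level.
#' @param replicates spikes per level (default 3).
#' @return object of class `spiking_design`: list with `analyte_id`,
#'   `mode`, `levels` (ug/L), `replicates`.
#' @export
#' @examples
#' build_spiking_design("met", native_conc = 100)$levels  # 50 ... 300
#' build_spiking_design("x", lloq = 2)$levels             # 25 ... 150
build_spiking_design <- function(analyte_id, native_conc = NULL, lloq = NULL,
                                 single_level = FALSE, replicates = 3) {
  if (is.null(native_conc) == is.null(lloq)) {
    stop("give exactly one of `native_conc` or `lloq`")
  }
  if (!is.null(native_conc)) {
    if (native_conc <= 0) {
      stop("native_conc must be > 0; for analytes below the LOD use the ",
           "`lloq` mode")
    }
    levels <- c(0.5, 1, 1.5, 2, 2.5, 3) * native_conc
    mode <- "native"
  } else {
    assert_num(lloq, "lloq", positive = TRUE)
    levels <- c(12.5, 25, 37.5, 50, 62.5, 75) * lloq
    mode <- "lloq_based"
  }
  if (single_level) {
    levels <- max(levels)
    mode <- "single_level"
  }
  structure(list(analyte_id = analyte_id, mode = mode, levels = levels,
                 replicates = replicates),
            class = "spiking_design")
}

#' Define a true instrument response for one analyte
#'
#' The expected quantifier area at measurement-solution concentration `c`
#' (ug/L) under matrix factor `m` and drift factor `d` is
#' `d * m * (slope * c + curvature * c^2)`; the realized area multiplies
#' this by a mean-1 lognormal factor with coefficient of variation
#' `measurement_rsd` and adds zero-mean Gaussian baseline noise of SD
#' `baseline_noise_sd`, floored at 0.  The qualifier transition responds at
#' `ion_ratio` times the quantifier expectation with its own noise draws.
#'
#' @param analyte_id identifier.
#' @param slope area per (ug/L), > 0.
#' @param curvature area per (ug/L)^2; <= 0 models detector saturation.
#' @param baseline_noise_sd additive baseline noise SD (area units).
#' @param measurement_rsd multiplicative noise CV (fraction, e.g. 0.05).
#' @param matrix_factor named numeric of true apparent-recovery fractions
#'   per dilution level, e.g. `c("5" = 0.8, "100" = 0.95)`; all > 0.
#' @param carryover_fraction fraction of the previous injection's area
#'   bleeding into a trailing blank, in `[0, 1)`.
#' @param ion_ratio true qualifier/quantifier response ratio (> 0).
#' @return object of class `response_model` with derived fields
#'   `lod_true` and `lloq_true` (the concentrations at which the expected
#'   S/N crosses 3 and 10).
#' @export
response_model <- function(analyte_id, slope, curvature = 0,
                           baseline_noise_sd = 0, measurement_rsd = 0,
                           matrix_factor = c("5" = 1, "100" = 1),
                           carryover_fraction = 0, ion_ratio = 0.5) {
  assert_num(slope, "slope", positive = TRUE)
  assert_num(baseline_noise_sd, "baseline_noise_sd", nonneg = TRUE)
  assert_num(measurement_rsd, "measurement_rsd", nonneg = TRUE)
  assert_num(matrix_factor, "matrix_factor", positive = TRUE)
  assert_num(ion_ratio, "ion_ratio", positive = TRUE)
  if (carryover_fraction < 0 || carryover_fraction >= 1) {
    stop("carryover_fraction must lie in [0, 1)")
  }
  # heights and the emitted noise estimate share the area-to-height factor,
  # so the expected S/N at conc c is slope * c / baseline_noise_sd
  lim <- function(sn) {
    if (baseline_noise_sd == 0) 0 else sn * baseline_noise_sd / slope
  }
  structure(list(analyte_id = analyte_id, slope = slope,
                 curvature = curvature,
                 baseline_noise_sd = baseline_noise_sd,
                 measurement_rsd = measurement_rsd,
                 matrix_factor = matrix_factor,
                 carryover_fraction = carryover_fraction,
                 ion_ratio = ion_ratio,
                 lod_true = lim(3), lloq_true = lim(10)),
            class = "response_model")
}

#' Simulate peak areas for one analyte
#'
#' Draws areas from a [response_model()] at given concentrations using the
#' current RNG state (seed management is the caller's job; the table-level
#' generator [simulate_peak_table()] seeds itself).
#'
#' @param model a `response_model`.
#' @param conc measurement-solution concentrations (ug/L, >= 0).
#' @param matrix_factor multiplicative matrix factor (1 = neat solvent).
#' @param drift multiplicative drift factor.
#' @param transition `"quantifier"` or `"qualifier"`.
#' @return numeric vector of areas (floored at 0).
#' @export
simulate_areas <- function(model, conc, matrix_factor = 1, drift = 1,
                           transition = c("quantifier", "qualifier")) {
  stopifnot(inherits(model, "response_model"))
  transition <- match.arg(transition)
  if (any(conc < 0)) stop("concentration must be >= 0")
  expected <- drift * matrix_factor *
    (model$slope * conc + model$curvature * conc^2)
  if (transition == "qualifier") expected <- expected * model$ion_ratio
  n <- length(expected)
  if (model$measurement_rsd > 0) {
    sdlog <- sqrt(log1p(model$measurement_rsd^2))
    expected <- expected * stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                         sdlog = sdlog)
  }
  if (model$baseline_noise_sd > 0) {
    expected <- expected + stats::rnorm(n, 0, model$baseline_noise_sd)
  }
  pmax(expected, 0)
}

#' Generate ground truth for a panel of synthetic analytes
#'
#' Draws per-analyte response models and native plasma concentrations.
#' Defaults emulate a validated dual-method plasma assay: 5% multiplicative
#' measurement noise, per-analyte matrix factors for the 1:5 dilution drawn
#' uniformly from `matrix_factor_range` with matrix effects shrinking
#' towards 1 at 1:100 (`dilution_shrink` of the deviation remains), small
#' carryover fractions, and a multiplicative response drift from 100% to
#' 80% across the sequence.
#'
#' @param analyte_ids character vector of analyte identifiers.
#' @param seed integer seed; the truth is reproducible given the seed.
#' @param slope_range log-uniform range of response slopes (area per ug/L).
#' @param rsd multiplicative measurement CV (fraction).
#' @param noise_conc baseline noise expressed in concentration units: the
#'   ug/L at which the expected S/N is 1 (so the true LOD is
#'   `3 * noise_conc` and the true LLOQ `10 * noise_conc`).
#' @param matrix_factor_range uniform range for the true 1:5 matrix factor.
#' @param dilution_shrink fraction of the 1:5 matrix deviation from 1 that
#'   persists at 1:100 (default 0.4).
#' @param carryover_range uniform range for carryover fractions.
#' @param native_range log-uniform range of native plasma concentrations
#'   (ug/L).
#' @param drift length-2 multiplicative response factor at the start and
#'   end of a sequence.
#' @param quad_fraction fraction of analytes given a saturating quadratic
#'   response term.
#' @return object of class `synthetic_truth`: list with `models` (named
#'   list of `response_model`), `native` (named ug/L vector), `drift`,
#'   `seed`.
#' @export
synthetic_truth <- function(analyte_ids, seed = 1,
                            slope_range = c(200, 5000), rsd = 0.05,
                            noise_conc = 0.02,
                            matrix_factor_range = c(0.7, 1.3),
                            dilution_shrink = 0.4,
                            carryover_range = c(0, 0.02),
                            native_range = c(50, 20000),
                            drift = c(1, 0.8), quad_fraction = 0) {
  set.seed(seed)
  n <- length(analyte_ids)
  slope <- exp(stats::runif(n, log(slope_range[1]), log(slope_range[2])))
  m5 <- stats::runif(n, matrix_factor_range[1], matrix_factor_range[2])
  m100 <- 1 + dilution_shrink * (m5 - 1)
  carry <- stats::runif(n, carryover_range[1], carryover_range[2])
  native <- exp(stats::runif(n, log(native_range[1]), log(native_range[2])))
  ion <- stats::runif(n, 0.3, 0.8)
  quad <- stats::runif(n) < quad_fraction
  models <- lapply(seq_len(n), function(i) {
    # saturating curvature: lose ~20% of linearity at the top of the
    # native x3 spiking range
    curv <- if (quad[i]) -0.2 * slope[i] / (3 * native[i]) else 0
    response_model(
      analyte_id = analyte_ids[i], slope = slope[i], curvature = curv,
      baseline_noise_sd = slope[i] * noise_conc,
      measurement_rsd = rsd,
      matrix_factor = c("5" = m5[i], "100" = m100[i]),
      carryover_fraction = carry[i], ion_ratio = ion[i]
    )
  })
  names(models) <- analyte_ids
  names(native) <- analyte_ids
  structure(list(models = models, native = native, drift = drift,
                 seed = seed),
            class = "synthetic_truth")
}

#' Plan a validation injection sequence
#'
#' Builds the ordered injection plan of a validation batch: a bracketing
#' calibration series at the start, a pure-solvent blank directly after
#' each standard at the carryover reference level (1 mg/L by default), QC
#' injections interleaved every `qc_every` sample injections, the samples
#' in duplicate in seeded random order, and the closing bracket
#' calibration (again with the trailing blank).
#'
#' @param calib_levels nominal calibration levels (ug/L), ascending;
#'   typically [build_calibration_series()].
#' @param sample_ids sample identifiers to measure in duplicate.
#' @param dilutions dilution factors at which each sample is injected.
#' @param seed integer seed for the duplicate randomization.
#' @param qc_every insert a QC injection every this many sample injections.
#' @param blank_after_level insert a blank after standards at this level
#'   (ug/L).
#' @return data.frame (the sequence plan) with columns `injection_index`,
#'   `sample_id`, `role` (`standard`, `blank`, `qc`, `sample`), `dilution`
#'   (NA for neat injections) and `conc_level` (standards only).
#' @export
plan_validation_sequence <- function(calib_levels, sample_ids,
                                     dilutions = c(5, 100), seed = 1,
                                     qc_every = 10,
                                     blank_after_level = 1000) {
  row <- function(sample_id, role, dilution = NA_real_,
                  conc_level = NA_real_) {
    data.frame(sample_id = sample_id, role = role, dilution = dilution,
               conc_level = conc_level, stringsAsFactors = FALSE)
  }
  bracket <- function(tag) {
    do.call(rbind, lapply(calib_levels, function(lv) {
      std <- row(sprintf("std_%s_%g", tag, lv), "standard", conc_level = lv)
      if (lv == blank_after_level) {
        rbind(std, row(sprintf("blank_after_%s_%g", tag, lv), "blank"))
      } else std
    }))
  }
  set.seed(seed)
  smp <- expand.grid(sample_id = sample_ids, dilution = dilutions,
                     replicate = 1:2, stringsAsFactors = FALSE)
  smp <- smp[sample.int(nrow(smp)), ]
  sample_rows <- do.call(rbind, lapply(seq_len(nrow(smp)), function(i) {
    r <- row(smp$sample_id[i], "sample", dilution = smp$dilution[i])
    if (i %% qc_every == 0) rbind(r, row("qc_pool", "qc", dilution = 5))
    else r
  }))
  plan <- rbind(bracket("start"),
                row("qc_pool", "qc", dilution = 5),
                sample_rows,
                row("qc_pool", "qc", dilution = 5),
                bracket("end"))
  plan$injection_index <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  plan[, c("injection_index", "sample_id", "role", "dilution", "conc_level")]
}

#' Simulate a full peak-area table from a sequence plan
#'
#' Walks the injection plan and draws quantifier and qualifier areas for
#' every analyte at every injection.  Standards and blanks are neat
#' (matrix factor 1); QC and sample injections carry the analyte's
#' per-dilution matrix factor and a measurement-solution concentration of
#' `native / dilution`.  Drift is piecewise linear in injection index from
#' `truth$drift[1]` to `truth$drift[2]`.  A blank following any injection
#' additionally receives `carryover_fraction` times the previous
#' injection's (already carryover-augmented) area, so consecutive blanks
#' decay geometrically.  Identical seed and inputs give an identical table.
#'
#' @param truth a [synthetic_truth()] object.
#' @param plan a sequence plan from [plan_validation_sequence()].
#' @param seed integer seed for the noise draws.
#' @return data.frame with one row per injection x analyte x transition:
#'   `injection_index`, `sample_id`, `role`, `dilution`, `analyte_id`,
#'   `transition`, `conc_nominal` (measurement-solution ug/L), `area`,
#'   `height`, `noise_sd`.
#' @export
simulate_peak_table <- function(truth, plan, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  n_inj <- nrow(plan)
  drift_f <- if (n_inj > 1) {
    truth$drift[1] + (truth$drift[2] - truth$drift[1]) *
      (plan$injection_index - 1) / (n_inj - 1)
  } else rep(truth$drift[1], n_inj)

  one_analyte <- function(id) {
    model <- truth$models[[id]]
    conc <- ifelse(plan$role == "standard", plan$conc_level,
                   ifelse(plan$role == "blank", 0,
                          truth$native[id] / plan$dilution))
    if (any(conc < 0, na.rm = TRUE)) stop("negative concentration in plan")
    mf <- ifelse(plan$role %in% c("standard", "blank"), 1,
                 model$matrix_factor[as.character(plan$dilution)])
    out <- lapply(c("quantifier", "qualifier"), function(tr) {
      area <- simulate_areas(model, conc, matrix_factor = mf,
                             drift = drift_f, transition = tr)
      # carryover into trailing blanks, chained
      f <- model$carryover_fraction
      if (f > 0) {
        for (i in which(plan$role == "blank")) {
          if (i > 1) area[i] <- area[i] + f * area[i - 1]
        }
      }
      data.frame(
        injection_index = plan$injection_index,
        sample_id = plan$sample_id, role = plan$role,
        dilution = plan$dilution, analyte_id = id, transition = tr,
        conc_nominal = conc, area = area,
        height = area / PEAK_SHAPE_FACTOR,
        noise_sd = model$baseline_noise_sd / PEAK_SHAPE_FACTOR,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  }
  tab <- do.call(rbind, lapply(names(truth$models), one_analyte))
  rownames(tab) <- NULL
  tab
}
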