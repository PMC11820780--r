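#' Correct instrument drift over an injection sequence
#'
#' LC-MS/MS response slowly drifts over long sequences (source fouling,
#' spray instability).  Two anchor-based corrections are supported:
#'
#' * `mode = "qc"` — anchors are repeated injections of the same pooled QC
#'   sample; the relative response at any injection index is the
#'   piecewise-linear interpolation of the anchor areas normalized to the
#'   first anchor, and areas are divided by it.
#' * `mode = "bracket"` — anchors are calibration-curve slopes from
#'   bracketing calibrations (at least start and end of the sequence);
#'   the local relative response factor is interpolated linearly in
#'   injection index between brackets.
#'
#' Outside the anchor range, the nearest anchor's factor is used.
#'
#' @param area areas to correct.
#' @param injection_index injection index of each area.
#' @param anchors data.frame with `injection_index` and `value` (QC area or
#'   bracket slope), at least 2 rows.
#' @param mode `"qc"` or `"bracket"` (identical arithmetic; kept explicit
#'   for reporting).
#' @return corrected areas (same length as `area`).
#' @export
drift_correct <- function(area, injection_index, anchors,
                          mode = c("qc", "bracket")) {
  mode <- match.arg(mode)
  stopifnot(all(c("injection_index", "value") %in% names(anchors)))
  if (nrow(anchors) < 2) stop("need at least 2 drift anchors")
  if (length(area) != length(injection_index)) {
    stop("area and injection_index differ in length")
  }
  anchors <- anchors[order(anchors$injection_index), ]
  rel <- anchors$value / anchors$value[1]
  factor <- stats::approx(anchors$injection_index, rel,
                          xout = injection_index, rule = 2)$y
  area / factor
}

#' Ion-ratio confirmation
#'
#' Compound identity is confirmed when the observed qualifier/quantifier
#' area ratio agrees with the reference ratio within a relative tolerance:
#' pass iff `|observed - reference| <= tolerance_rel * reference`.
#' Single-transition analytes have no qualifier; their verdict is
#' `"not evaluable"` and quantification proceeds with a warning flag.
#'
#' @param observed observed ion ratio(s); `NA` for missing qualifier.
#' @param reference reference ion ratio (> 0).
#' @param tolerance_rel relative tolerance (default 0.30).
#' @return character vector: `"pass"`, `"fail"` or `"not evaluable"`.
#' @export
#' @examples
#' check_ion_ratio(0.50, 0.50)        # pass
#' check_ion_ratio(0.70, 0.50, 0.30)  # fail: |0.20| > 0.15
check_ion_ratio <- function(observed, reference, tolerance_rel = 0.30) {
  assert_num(reference, "reference", positive = TRUE)
  out <- ifelse(is.na(observed), "not evaluable",
                ifelse(abs(observed - reference) <= tolerance_rel * reference,
                       "pass", "fail"))
  as.character(out)
}

#' Apply a recovery correction
#'
#' When the apparent recovery of an analyte lies outside the 70-130%
#' acceptance band, the concentration calculated from the calibration
#' curve is corrected by the recovery:
#' `c_corrected = c * 100 / RA`.
#'
#' @param conc concentration(s) from the calibration curve.
#' @param ra_pct apparent recovery, percent (> 0).
#' @return corrected concentration(s).
#' @export
#' @examples
#' correct_by_recovery(50, 50)   # 100
#' correct_by_recovery(50, 100)  # unchanged
correct_by_recovery <- function(conc, ra_pct) {
  assert_num(ra_pct, "ra_pct", positive = TRUE)
  conc * 100 / ra_pct
}

#' Quantify one analyte in one sample from two dilutions
#'
#' Each sample is injected at two dilutions (by default 1:5 and 1:100).
#' The measurement-solution concentration at each dilution is
#' back-calculated from the analyte's calibration curve; the reported
#' plasma concentration is `measurement * dilution_factor` of the selected
#' dilution.
#'
#' Dilution selection: among dilutions whose measurement lies within
#' `[LLOQ, ULOQ]`, the most dilute is preferred (matrix effects shrink with
#' dilution); `prefer = "least_dilute"` flips this for low-abundance
#' compound classes that fall below the LLOQ at high dilution.  If no
#' dilution is in range, the result is censored: `">ULOQ"` when even the
#' highest dilution saturates (with an advisory that a higher dilution,
#' e.g. 1:500, is required), `"<LLOQ"` when even the lowest dilution is
#' below the LLOQ.
#'
#' Recovery correction: when the apparent recovery of the selected dilution
#' lies outside `[70, 130]`% the concentration is corrected by
#' `100 / RA` ([correct_by_recovery()]); `correction = "always"` corrects
#' by the RA whenever one is supplied (parameter-recovery studies),
#' `"never"` disables correction.
#'
#' @param areas data.frame with columns `dilution` (factor, e.g. 5, 100)
#'   and `area` (quantifier area in the measurement solution); optionally
#'   `qualifier_area` for ion-ratio confirmation.
#' @param curve the analyte's `calibration_curve`.
#' @param ra named numeric of apparent recoveries (percent) keyed by
#'   dilution factor (names `"5"`, `"100"`), or `NULL` if unknown.
#' @param prefer `"most_dilute"` (default) or `"least_dilute"`.
#' @param correction `"threshold"` (default, correct outside 70-130%),
#'   `"always"`, or `"never"`.
#' @param accept_band recovery acceptance band, percent.
#' @param ion_ratio_tol relative ion-ratio tolerance.
#' @return one-row data.frame: `concentration` (ug/L in plasma),
#'   `dilution_used`, `censoring`, `recovery_corrected`, `ra_used`,
#'   `ion_ratio_observed`, `ion_ratio_pass`, `note`.
#' @export
quantify_analyte <- function(areas, curve, ra = NULL,
                             prefer = c("most_dilute", "least_dilute"),
                             correction = c("threshold", "always", "never"),
                             accept_band = c(70, 130),
                             ion_ratio_tol = 0.30) {
  prefer <- match.arg(prefer)
  correction <- match.arg(correction)
  if (is.null(curve)) stop("missing calibration curve")
  stopifnot(inherits(curve, "calibration_curve"),
            all(c("dilution", "area") %in% names(areas)))

  bc <- back_calculate(curve, areas$area)
  areas$conc_meas <- bc$conc
  areas$flag <- bc$flag
  ord <- order(areas$dilution, decreasing = (prefer == "most_dilute"))
  areas <- areas[ord, ]

  quantifiable <- which(areas$flag == "quantified")
  note <- NA_character_
  if (length(quantifiable)) {
    sel <- quantifiable[1]
    censoring <- "quantified"
  } else {
    # censored: saturation at the most dilute level wins over <LLOQ
    most_dilute <- which.max(areas$dilution)
    least_dilute <- which.min(areas$dilution)
    if (areas$flag[most_dilute] == ">ULOQ") {
      sel <- most_dilute
      censoring <- ">ULOQ"
      note <- sprintf(paste0("above ULOQ even at 1:%d; a higher dilution ",
                             "(e.g. 1:%d) is required"),
                      areas$dilution[most_dilute],
                      5 * areas$dilution[most_dilute])
    } else {
      sel <- least_dilute
      censoring <- "<LLOQ"
    }
  }

  dil <- areas$dilution[sel]
  conc_plasma <- areas$conc_meas[sel] * dil
  ra_used <- if (!is.null(ra)) unname(ra[as.character(dil)]) else NA_real_
  corrected <- FALSE
  if (censoring == "quantified" && is.finite(ra_used) &&
      correction != "never") {
    outside <- ra_used < accept_band[1] || ra_used > accept_band[2]
    if (correction == "always" || outside) {
      conc_plasma <- correct_by_recovery(conc_plasma, ra_used)
      corrected <- TRUE
    }
  }

  ir_obs <- NA_real_
  ir_pass <- "not evaluable"
  if ("qualifier_area" %in% names(areas) && !is.na(curve$ion_ratio_ref)) {
    qa <- areas$qualifier_area[sel]
    if (is.finite(qa) && areas$area[sel] > 0) {
      ir_obs <- qa / areas$area[sel]
      ir_pass <- check_ion_ratio(ir_obs, curve$ion_ratio_ref, ion_ratio_tol)
    }
  } else if (!"qualifier_area" %in% names(areas) && is.na(note)) {
    note <- "single-transition analyte: identity not confirmable by ion ratio"
  }

  data.frame(
    concentration = if (censoring == "quantified") conc_plasma else NA_real_,
    dilution_used = dil,
    censoring = censoring,
    recovery_corrected = corrected,
    ra_used = ra_used,
    ion_ratio_observed = ir_obs,
    ion_ratio_pass = ir_pass,
    note = note,
    stringsAsFactors = FALSE
  )
}

#' Combine duplicate injections of one sample
#'
#' Samples measured in duplicate in a randomized sequence are averaged
#' after censoring resolution: two quantified results are averaged; if the
#' duplicates disagree in censoring class, the quantified one wins and the
#' result is flagged; two identically censored results stay censored.
#'
#' @param conc1,conc2 plasma concentrations of the duplicates (`NA` if
#'   censored).
#' @param cens1,cens2 censoring classes of the duplicates.
#' @return one-row data.frame `concentration`, `censoring`, `flag`.
#' @export
resolve_duplicates <- function(conc1, cens1, conc2, cens2) {
  q1 <- cens1 == "quantified"
  q2 <- cens2 == "quantified"
  if (q1 && q2) {
    out <- data.frame(concentration = (conc1 + conc2) / 2,
                      censoring = "quantified", flag = NA_character_)
  } else if (q1 || q2) {
    out <- data.frame(concentration = if (q1) conc1 else conc2,
                      censoring = "quantified",
                      flag = "duplicate censoring mismatch")
  } else {
    out <- data.frame(concentration = NA_real_,
                      censoring = if (cens1 == cens2) cens1 else
                        "conflicting censoring",
                      flag = if (cens1 == cens2) NA_character_ else
                        "duplicate censoring mismatch")
  }
  out
}

#' Deconvolute co-eluting isomers
#'
#' Isomers that co-elute but share one MS/MS transition while one of them
#' has a unique transition (the leucine/isoleucine case: the shared
#' m/z 132.1 -> 89 transition measures the sum, the unique
#' m/z 132.1 -> 69 transition measures isoleucine alone) are resolved by
#' subtraction: `component = sum - unique`.  A negative difference is
#' censored at 0 and flagged; if either input is censored/missing the
#' result is not evaluable.
#'
#' @param sum_conc concentration from the shared (sum) transition.
#' @param unique_conc concentration from the unique-isomer transition.
#' @return one-row data.frame `concentration`, `evaluable`,
#'   `negative_difference`.
#' @export
#' @examples
#' deconvolute_isomers(10, 4)  # 6
#' deconvolute_isomers(3, 4)   # 0, flagged
deconvolute_isomers <- function(sum_conc, unique_conc) {
  if (!is.finite(sum_conc) || !is.finite(unique_conc)) {
    return(data.frame(concentration = NA_real_, evaluable = FALSE,
                      negative_difference = NA))
  }
  diff <- sum_conc - unique_conc
  data.frame(concentration = max(diff, 0), evaluable = TRUE,
             negative_difference = diff < 0)
}
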