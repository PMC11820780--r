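#' Trueness report against certified reference values
#'
#' Trueness is the agreement of a measured concentration with a certified
#' reference value, reported as the integer percentage
#' `round(100 * measured / certified)` (ties away from zero, matching the
#' usual printed convention).  Analytes without a measured value (below the
#' LOD in the assay) are not evaluable and are excluded from the summary
#' count of analytes falling within the 70-130% acceptance band.
#'
#' @param compound compound names.
#' @param certified certified concentrations (ug/L, > 0).
#' @param measured measured concentrations (ug/L; `NA` = below LOD /
#'   not evaluable).
#' @param band acceptance band in percent (default `c(70, 130)`).
#' @return object of class `trueness_report`: data.frame with columns
#'   `compound`, `certified`, `measured`, `trueness`, `within_band`,
#'   `evaluable`, and attributes `n_within`, `n_evaluable`.
#' @export
#' @examples
#' trueness_report("methionine", 3325, 2146)$trueness  # 65
trueness_report <- function(compound, certified, measured,
                            band = c(70, 130)) {
  assert_num(certified, "certified", positive = TRUE)
  if (length(compound) != length(certified) ||
      length(certified) != length(measured)) {
    stop("compound, certified and measured differ in length")
  }
  evaluable <- is.finite(measured)
  trueness <- ifelse(evaluable,
                     round_half_away(100 * measured / certified), NA_real_)
  within <- evaluable & trueness >= band[1] & trueness <= band[2]
  out <- data.frame(compound = compound, certified = certified,
                    measured = measured, trueness = trueness,
                    within_band = within, evaluable = evaluable,
                    stringsAsFactors = FALSE)
  attr(out, "n_within") <- sum(within)
  attr(out, "n_evaluable") <- sum(evaluable)
  attr(out, "band") <- band
  class(out) <- c("trueness_report", "data.frame")
  out
}

#' @export
print.trueness_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("\n%d of %d evaluable metabolites within %g-%g%% of certified\n",
              attr(x, "n_within"), attr(x, "n_evaluable"),
              attr(x, "band")[1], attr(x, "band")[2]))
  invisible(x)
}

#' Certified and measured concentrations for NIST SRM 1950 plasma
#'
#' Loads the bundled table of certified metabolite concentrations in the
#' NIST SRM 1950 ("Metabolites in Frozen Human Plasma") reference material
#' together with the concentrations measured by the dual HILIC/RP assay.
#' Two metabolites (cholecalciferol, calciferol) were below the assay LODs
#' and carry `NA` measured values.
#'
#' @return data.frame with columns `compound`, `certified_ugL`,
#'   `measured_ugL`.
#' @export
nist_reference_values <- function() {
  path <- system.file("extdata", "nist_srm1950_trueness.csv",
                      package = "srmquant")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
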