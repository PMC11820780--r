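#' Define an LC gradient program
#'
#' A gradient program is an ordered list of segments `(time_min, percent_b,
#' flow_ul_min)`.  Segment times must be strictly increasing and start at 0;
#' the mobile-phase composition `percent_b` is constrained to \[0, 100\].
#'
#' @param method `"HILIC"` or `"RP"`.
#' @param time_min numeric vector of segment times, minutes, strictly
#'   increasing, first element 0.
#' @param percent_b percentage of mobile phase B at each segment time.
#' @param flow_ul_min flow rate at each segment time, microlitres/min.
#' @param oven_temp_c column oven temperature, degrees Celsius.
#' @param injection_volume_ul injection volume, microlitres.
#' @return object of class `gradient_program`.
#' @seealso [rp_gradient()], [hilic_gradient()], [run_duration()]
#' @export
gradient_program <- function(method, time_min, percent_b, flow_ul_min,
                             oven_temp_c = NA_real_,
                             injection_volume_ul = 1) {
  method <- match.arg(method, c("HILIC", "RP"))
  if (length(time_min) == 0) stop("gradient program has no segments")
  if (length(percent_b) != length(time_min) ||
      length(flow_ul_min) != length(time_min)) {
    stop("segment vectors must have equal length")
  }
  assert_num(time_min, "time_min", nonneg = TRUE)
  if (time_min[1] != 0) stop("first segment must be at time 0")
  if (any(diff(time_min) <= 0)) stop("segment times must strictly increase")
  if (any(percent_b < 0 | percent_b > 100)) {
    stop("percent_b must lie in [0, 100]")
  }
  assert_num(flow_ul_min, "flow_ul_min", positive = TRUE)
  structure(list(
    method = method,
    segments = data.frame(time_min = time_min, percent_b = percent_b,
                          flow_ul_min = flow_ul_min),
    oven_temp_c = oven_temp_c,
    injection_volume_ul = injection_volume_ul
  ), class = "gradient_program")
}

#' Built-in reversed-phase gradient
#'
#' C18 gradient: 5% B held to 0.5 min, linear ramp to 100% B at 8.0 min,
#' isocratic wash at 100% B to 19.5 min (flow doubled to 800 uL/min from
#' 9.5 min), re-equilibration at 5% B from 19.5 to 23.0 min.  Oven 50 degC,
#' 1 uL injection.
#'
#' @return `gradient_program` for the RP method (23.0 min run).
#' @export
rp_gradient <- function() {
  gradient_program(
    "RP",
    time_min    = c(0, 0.5, 8.0, 9.5, 19.5, 23.0),
    percent_b   = c(5, 5, 100, 100, 100, 5),
    flow_ul_min = c(400, 400, 400, 800, 800, 400),
    oven_temp_c = 50, injection_volume_ul = 1
  )
}

#' Built-in HILIC gradient
#'
#' Bare-silica HILIC gradient expressed as % B where B is the aqueous phase:
#' 0% B to 0.5 min, ramp to 36.8% B at 6.5 min, steeper ramp to 57.9% B at
#' 6.8 min, isocratic wash to 12.0 min, return to 0% B at 12.8 min,
#' re-equilibration to 16.5 min (flow raised to 1000 uL/min between 13.3 and
#' 15.8 min).  Oven 40 degC, 1 uL injection.
#'
#' @return `gradient_program` for the HILIC method (16.5 min run).
#' @export
hilic_gradient <- function() {
  gradient_program(
    "HILIC",
    time_min    = c(0, 0.5, 6.5, 6.8, 12.0, 12.8, 13.3, 15.8, 16.5),
    percent_b   = c(0, 0, 36.8, 57.9, 57.9, 0, 0, 0, 0),
    flow_ul_min = c(400, 400, 400, 400, 400, 400, 1000, 1000, 400),
    oven_temp_c = 40, injection_volume_ul = 1
  )
}

#' Total run duration of a gradient program
#'
#' The run ends with the last programmed segment (end of re-equilibration),
#' so the duration is the final — equivalently the maximum — segment time.
#'
#' @param program a `gradient_program`.
#' @return run duration in minutes.
#' @export
#' @examples
#' run_duration(rp_gradient())     # 23.0
#' run_duration(hilic_gradient())  # 16.5
run_duration <- function(program) {
  stopifnot(inherits(program, "gradient_program"))
  if (nrow(program$segments) == 0) stop("gradient program has no segments")
  max(program$segments$time_min)
}

#' Polarity index of a solvent mixture
#'
#' The Snyder-style polarity index of a mixture is the volume-fraction
#' weighted mean of the component indices.  Used when screening
#' reconstitution solvents of decreasing polarity for the uptake of
#' hydrophobic metabolites.
#'
#' @param polarity_index numeric vector of component polarity indices
#'   (e.g. acetonitrile 6.2, isopropanol 4.3).
#' @param volume_fraction volume fractions of the components; must sum to 1
#'   within 1e-9.
#' @param digits decimals in the reported value (default 1, the convention
#'   for printed indices); use `raw = TRUE` for the unrounded value.
#' @param raw if `TRUE`, return the unrounded weighted mean.
#' @return the mixture polarity index.
#' @export
#' @examples
#' mixture_polarity_index(4.3, 1)                 # pure IPA: 4.3
#' mixture_polarity_index(c(6.2, 4.3), c(.5, .5)) # ACN/IPA 50/50: 5.3
mixture_polarity_index <- function(polarity_index, volume_fraction,
                                   digits = 1, raw = FALSE) {
  assert_num(polarity_index, "polarity_index")
  assert_num(volume_fraction, "volume_fraction", nonneg = TRUE)
  if (length(polarity_index) != length(volume_fraction)) {
    stop("component vectors must have equal length")
  }
  if (abs(sum(volume_fraction) - 1) > 1e-9) {
    stop("volume fractions must sum to 1")
  }
  idx <- sum(polarity_index * volume_fraction)
  if (raw) idx else round_half_away(idx, digits)
}
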