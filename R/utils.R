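#' Round half away from zero
#'
#' Reporting convention used throughout the package wherever a percentage or
#' index is printed: ties are rounded away from zero (so 84.5 -> 85,
#' -84.5 -> -85), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep (default 0).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.45, -0.5))
#' round_half_away(5.25, 1)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop unless all values are finite numbers
assert_num <- function(x, what, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", what), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("`%s` must be > 0", what), call. = FALSE)
  }
  if (nonneg && any(x < 0)) {
    stop(sprintf("`%s` must be >= 0", what), call. = FALSE)
  }
  invisible(x)
}
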