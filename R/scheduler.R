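#' Cycle configuration for scheduled SRM
#'
#' Acquisition-cycle parameters of a triple quadrupole running scheduled SRM
#' with fast polarity switching.  Defaults follow common practice for modern
#' QqQ instruments: a 1000 ms target cycle, 5 ms inter-transition pause,
#' 15 ms settling per polarity switch, and a 3 ms minimum usable dwell.
#'
#' @param target_cycle_ms target duty-cycle length, ms.
#' @param pause_ms inter-transition pause, ms, charged once per transition.
#' @param settling_ms settling time per polarity switch, ms.
#' @param dwell_floor_ms smallest dwell the instrument can use, ms.
#' @param time_grid_step_s evaluation grid step along the run, seconds.
#' @return object of class `cycle_config`.
#' @export
cycle_config <- function(target_cycle_ms = 1000, pause_ms = 5,
                         settling_ms = 15, dwell_floor_ms = 3,
                         time_grid_step_s = 1) {
  assert_num(target_cycle_ms, "target_cycle_ms", positive = TRUE)
  assert_num(pause_ms, "pause_ms", positive = TRUE)
  assert_num(settling_ms, "settling_ms", positive = TRUE)
  assert_num(dwell_floor_ms, "dwell_floor_ms", positive = TRUE)
  assert_num(time_grid_step_s, "time_grid_step_s", positive = TRUE)
  if (dwell_floor_ms > target_cycle_ms) {
    stop("dwell_floor_ms cannot exceed target_cycle_ms")
  }
  structure(list(target_cycle_ms = target_cycle_ms, pause_ms = pause_ms,
                 settling_ms = settling_ms, dwell_floor_ms = dwell_floor_ms,
                 time_grid_step_s = time_grid_step_s),
            class = "cycle_config")
}

#' Scheduled-SRM concurrency along the run
#'
#' A transition with retention time `rt_min` and detection-window width
#' `window_s` is monitored (active) at run time `t` iff
#' `|t - rt| <= window_s / 2`; windows are closed intervals.  The profile
#' counts active transitions per polarity on a regular time grid from 0 to
#' the end of the last window.
#'
#' @param registry an `srm_registry`.
#' @param method `"HILIC"` or `"RP"`; only that method's transitions are
#'   scheduled (the two methods run as separate injections).
#' @param config a [cycle_config()].
#' @return data.frame with `time_s`, `n_pos`, `n_neg` and a list-column
#'   `active` of active transition row indices (into the method subset).
#' @export
concurrency_profile <- function(registry, method, config = cycle_config()) {
  stopifnot(inherits(registry, "srm_registry"),
            inherits(config, "cycle_config"))
  method <- match.arg(method, c("HILIC", "RP"))
  tr <- registry$transitions[registry$transitions$method == method, ]
  if (nrow(tr) == 0) stop("no transitions for method ", method)
  start_s <- tr$rt_min * 60 - tr$window_s / 2
  end_s <- tr$rt_min * 60 + tr$window_s / 2
  grid <- seq(0, max(end_s), by = config$time_grid_step_s)
  pos <- tr$polarity == "positive"
  active <- lapply(grid, function(t) which(start_s <= t & t <= end_s))
  n_pos <- vapply(active, function(i) sum(pos[i]), integer(1))
  n_neg <- vapply(active, function(i) sum(!pos[i]), integer(1))
  out <- data.frame(time_s = grid, n_pos = n_pos, n_neg = n_neg)
  out$active <- active
  attr(out, "method") <- method
  out
}

#' Allocate dwell times under the cycle budget
#'
#' At a grid point with `n = n_pos + n_neg > 0` active transitions the cycle
#' overhead is two polarity-switch settling events when both polarities are
#' present (enter positive, enter negative) and zero otherwise.  The
#' remaining budget is split equally:
#' `dwell = (target_cycle - overhead - n * pause) / n`,
#' floored at the instrument's minimum dwell.  When the floor binds, the
#' realized cycle stretches to `overhead + n * (dwell_floor + pause)` and
#' the point is flagged infeasible (the target cycle time cannot be held).
#' Grid points with no active transition keep the target cycle and `NA`
#' dwell.
#'
#' @param profile output of [concurrency_profile()].
#' @param config a [cycle_config()].
#' @return the profile with added columns `dwell_ms`, `cycle_ms`,
#'   `feasible`.
#' @export
allocate_dwell <- function(profile, config = cycle_config()) {
  stopifnot(inherits(config, "cycle_config"),
            all(c("n_pos", "n_neg") %in% names(profile)))
  n <- profile$n_pos + profile$n_neg
  overhead <- ifelse(profile$n_pos > 0 & profile$n_neg > 0,
                     2 * config$settling_ms, 0)
  dwell_raw <- ifelse(n > 0,
                      (config$target_cycle_ms - overhead - n * config$pause_ms) / n,
                      NA_real_)
  floored <- !is.na(dwell_raw) & dwell_raw < config$dwell_floor_ms
  dwell <- ifelse(floored, config$dwell_floor_ms, dwell_raw)
  cycle <- ifelse(n > 0, overhead + n * (dwell + config$pause_ms),
                  config$target_cycle_ms)
  profile$dwell_ms <- dwell
  profile$cycle_ms <- cycle
  profile$feasible <- !floored
  profile
}

#' Chromatographic data points per peak
#'
#' Number of acquisition cycles fitting into one chromatographic peak:
#' `peak_width_s * 1000 / realized_cycle_ms`.  Quantification quality
#' degrades below roughly 8-10 points per peak.
#'
#' @param peak_width_s peak base width, seconds.
#' @param realized_cycle_ms realized cycle time, ms.
#' @return points per peak (numeric, possibly fractional).
#' @export
#' @examples
#' points_per_peak(10, 1000)  # 10
points_per_peak <- function(peak_width_s, realized_cycle_ms) {
  assert_num(peak_width_s, "peak_width_s", positive = TRUE)
  assert_num(realized_cycle_ms, "realized_cycle_ms", positive = TRUE)
  peak_width_s * 1000 / realized_cycle_ms
}
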