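# Independent oracles and fixture builders shared across tests.

# Weighted least squares by explicit normal equations (independent of lm).
wls_oracle <- function(conc, area, quadratic = FALSE) {
  keep <- conc > 0
  x <- conc[keep]; y <- area[keep]
  X <- if (quadratic) cbind(1, x, x^2) else cbind(1, x)
  W <- diag(1 / x)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  fitted <- as.vector(X %*% beta)
  w <- 1 / x
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
  list(coefficients = as.vector(beta), r2 = r2)
}

# Brute-force dwell recomputation at a single grid point, straight from the
# scheduling rules (membership test + budget arithmetic), independent of
# concurrency_profile()/allocate_dwell() internals.
dwell_oracle_at <- function(t_s, transitions, config) {
  act <- abs(t_s - transitions$rt_min * 60) <= transitions$window_s / 2
  n_pos <- sum(act & transitions$polarity == "positive")
  n_neg <- sum(act & transitions$polarity == "negative")
  n <- n_pos + n_neg
  if (n == 0) {
    return(list(n_pos = 0L, n_neg = 0L, dwell = NA_real_,
                cycle = config$target_cycle_ms, feasible = TRUE))
  }
  overhead <- if (n_pos > 0 && n_neg > 0) 2 * config$settling_ms else 0
  dwell <- (config$target_cycle_ms - overhead - n * config$pause_ms) / n
  feasible <- dwell >= config$dwell_floor_ms
  if (!feasible) dwell <- config$dwell_floor_ms
  list(n_pos = n_pos, n_neg = n_neg, dwell = dwell,
       cycle = overhead + n * (dwell + config$pause_ms), feasible = feasible)
}

# Build an srm_registry through the public CSV interface.
make_registry <- function(transitions) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(transitions, path, row.names = FALSE, quote = FALSE,
                   na = "")
  on.exit(unlink(path))
  read_transition_registry(path)
}

# One transition row with defaults; override any field.
tr_row <- function(analyte_id, role = "quantifier", method = "HILIC",
                   polarity = "positive", rt_min = 5, window_s = 30,
                   precursor_mz = 150.1, product_mz = 90.1,
                   name = analyte_id, class = "amino acids",
                   calib_set = "HILIC", flags = "") {
  data.frame(analyte_id = analyte_id, name = name, class = class,
             method = method, polarity = polarity,
             precursor_mz = precursor_mz, product_mz = product_mz,
             role = role, rt_min = rt_min, window_s = window_s,
             calib_set = calib_set, flags = flags, stringsAsFactors = FALSE)
}

# Random valid registry: n_analytes with 2 transitions each, one method.
random_registry <- function(n_analytes, method = "HILIC", rt_max_min = 16) {
  rows <- do.call(rbind, lapply(seq_len(n_analytes), function(i) {
    rt <- stats::runif(1, 0, rt_max_min)
    win <- sample(c(30, 60), 1)
    pol <- sample(c("positive", "negative"), 1)
    rbind(
      tr_row(sprintf("r%03d", i), "quantifier", method, pol, rt, win),
      tr_row(sprintf("r%03d", i), "qualifier", method, pol, rt, win,
             product_mz = 70.1)
    )
  }))
  make_registry(rows)
}

# Small four-analyte clean fixture used by several registry tests.
fixture_registry_4 <- function() {
  rows <- do.call(rbind, lapply(1:4, function(i) {
    rbind(
      tr_row(sprintf("a%d", i), "quantifier", rt_min = i),
      tr_row(sprintf("a%d", i), "qualifier", rt_min = i, product_mz = 60.1)
    )
  }))
  make_registry(rows)
}
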