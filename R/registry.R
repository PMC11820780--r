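#' @title Transition registry
#'
#' @description
#' The assay definition is a flat, row-per-transition table.  Each row is one
#' SRM transition; analyte-level metadata (compound class, calibration set,
#' deconvolution flags) is denormalized onto the rows so the table can be
#' pasted straight into vendor acquisition software.  The documented CSV
#' header is
#'
#' `analyte_id,name,class,method,polarity,precursor_mz,product_mz,role,rt_min,window_s,calib_set,flags`
#'
#' where `method` is `HILIC` or `RP`, `polarity` is `positive` or `negative`,
#' `role` is `quantifier` or `qualifier`, `rt_min` is the expected retention
#' time in minutes, `window_s` the scheduled detection-window width in
#' seconds, `calib_set` one of `HILIC`, `RP_Aqu`, `RP_Hep`, and `flags` a
#' semicolon-separated list of tokens among `single_transition`,
#' `both_polarity`, `report_as_sum`, `sum_partner:<analyte_id>` and
#' `unique_partner:<analyte_id>`.
#'
#' @name srm_registry
NULL

REGISTRY_COLUMNS <- c(
  "analyte_id", "name", "class", "method", "polarity", "precursor_mz",
  "product_mz", "role", "rt_min", "window_s", "calib_set", "flags"
)

# internal: split the flags column into a list of tokens
parse_flags <- function(flags) {
  strsplit(ifelse(is.na(flags) | flags == "", "", flags), ";", fixed = TRUE)
}

has_flag <- function(flags, token) {
  vapply(parse_flags(flags), function(f) token %in% f, logical(1))
}

flag_value <- function(flags, key) {
  vapply(parse_flags(flags), function(f) {
    hit <- grep(paste0("^", key, ":"), f, value = TRUE)
    if (length(hit)) sub(paste0("^", key, ":"), "", hit[1]) else NA_character_
  }, character(1))
}

# internal constructor: validates the transition table and derives the
# analyte-level view
new_srm_registry <- function(transitions) {
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(transitions))
  if (length(missing_cols)) {
    stop("registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  transitions <- transitions[, REGISTRY_COLUMNS]
  for (col in c("precursor_mz", "product_mz", "rt_min", "window_s")) {
    if (!is.numeric(transitions[[col]])) {
      stop(sprintf("registry column `%s` must be numeric", col), call. = FALSE)
    }
  }
  if (any(transitions$precursor_mz <= 0) || any(transitions$product_mz <= 0)) {
    bad <- unique(transitions$analyte_id[
      transitions$precursor_mz <= 0 | transitions$product_mz <= 0])
    stop("non-positive m/z for analyte(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(transitions$rt_min < 0)) {
    stop("negative retention time in registry", call. = FALSE)
  }
  if (any(transitions$window_s <= 0)) {
    stop("non-positive detection-window width in registry", call. = FALSE)
  }
  bad_method <- setdiff(unique(transitions$method), c("HILIC", "RP"))
  if (length(bad_method)) {
    stop("unknown method(s): ", paste(bad_method, collapse = ", "),
         call. = FALSE)
  }
  bad_pol <- setdiff(unique(transitions$polarity), c("positive", "negative"))
  if (length(bad_pol)) {
    stop("unknown polarity value(s): ", paste(bad_pol, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(transitions$role), c("quantifier", "qualifier"))
  if (length(bad_role)) {
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }

  # transition counts: 1 or 2 per analyte; exactly 1 requires the
  # single_transition flag
  n_by_analyte <- table(transitions$analyte_id)
  single_flagged <- tapply(has_flag(transitions$flags, "single_transition"),
                           transitions$analyte_id, any)
  too_many <- names(n_by_analyte)[n_by_analyte > 2]
  lone <- names(n_by_analyte)[n_by_analyte == 1]
  lone_unflagged <- lone[!single_flagged[lone]]
  if (length(too_many) || length(lone_unflagged)) {
    stop("analyte(s) with an invalid transition count: ",
         paste(c(too_many, lone_unflagged), collapse = ", "), call. = FALSE)
  }

  # both-polarity analytes carry one transition per polarity
  both_pol <- tapply(has_flag(transitions$flags, "both_polarity"),
                     transitions$analyte_id, any)
  for (id in names(both_pol)[both_pol]) {
    pol <- transitions$polarity[transitions$analyte_id == id]
    if (!setequal(pol, c("positive", "negative"))) {
      stop("both-polarity analyte `", id,
           "` does not have one transition per polarity", call. = FALSE)
    }
  }

  first <- !duplicated(transitions$analyte_id)
  analytes <- data.frame(
    analyte_id = transitions$analyte_id[first],
    name = transitions$name[first],
    class = transitions$class[first],
    calib_set = transitions$calib_set[first],
    n_transitions = as.integer(n_by_analyte[transitions$analyte_id[first]]),
    single_transition = unname(single_flagged[transitions$analyte_id[first]]),
    both_polarity = unname(both_pol[transitions$analyte_id[first]]),
    report_as_sum = unname(tapply(has_flag(transitions$flags, "report_as_sum"),
                                  transitions$analyte_id,
                                  any)[transitions$analyte_id[first]]),
    sum_partner = flag_value(transitions$flags[first], "sum_partner"),
    unique_partner = flag_value(transitions$flags[first], "unique_partner"),
    stringsAsFactors = FALSE
  )
  rownames(analytes) <- NULL
  rownames(transitions) <- NULL
  structure(list(analytes = analytes, transitions = transitions),
            class = "srm_registry")
}

#' Read a transition registry from CSV
#'
#' Reads and validates a row-per-transition registry file (see
#' [srm_registry] for the dialect).  Validation failures — missing columns,
#' non-positive m/z, analytes with 0 or more than 2 transitions that are not
#' flagged `single_transition`, duplicate quantifiers — raise errors naming
#' the offending column or analyte.
#'
#' @param path path to a UTF-8 comma-separated registry file.
#' @return An object of class `srm_registry`: a list with elements
#'   `transitions` (one row per SRM transition) and `analytes` (one row per
#'   analyte with derived metadata).
#' @seealso [write_transition_registry()], [validate_registry()],
#'   [registry_counts()]
#' @export
#' @examples
#' path <- system.file("extdata", "transition_registry.csv",
#'                     package = "srmquant")
#' reg <- read_transition_registry(path)
#' registry_counts(reg)
read_transition_registry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(flags = "character"))
  new_srm_registry(tab)
}

#' Write a transition registry to CSV
#'
#' Inverse of [read_transition_registry()]; writing and re-reading
#' round-trips the registry exactly on the documented dialect.
#'
#' @param registry an `srm_registry` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transition_registry <- function(registry, path) {
  stopifnot(inherits(registry, "srm_registry"))
  utils::write.csv(registry$transitions, path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Tally a registry
#'
#' @param registry an `srm_registry` object.
#' @return list with `n_analytes`, `n_transitions`, and per-method /
#'   per-polarity transition counts.
#' @export
registry_counts <- function(registry) {
  stopifnot(inherits(registry, "srm_registry"))
  tr <- registry$transitions
  list(
    n_analytes = nrow(registry$analytes),
    n_transitions = nrow(tr),
    by_method = table(tr$method),
    by_polarity = table(tr$polarity)
  )
}

#' @export
print.srm_registry <- function(x, ...) {
  ct <- registry_counts(x)
  cat(sprintf("SRM transition registry: %d analytes, %d transitions\n",
              ct$n_analytes, ct$n_transitions))
  cat("  by method:  ",
      paste(sprintf("%s=%d", names(ct$by_method), ct$by_method),
            collapse = ", "), "\n")
  cat("  by polarity:",
      paste(sprintf("%s=%d", names(ct$by_polarity), ct$by_polarity),
            collapse = ", "), "\n")
  invisible(x)
}

#' Screen a registry for quality issues
#'
#' Unlike the structural checks in [read_transition_registry()] (which raise
#' errors), this returns issues as data so a whole registry can be reviewed
#' at once.  Severities: `"error"` (duplicate quantifier, missing quantifier),
#' `"warning"` (qualifier without quantifier pairing oddities), `"info"`
#' (wide detection windows, e.g. the 60 s windows used for phospholipids
#' whose plasma isomer envelopes shift retention time).
#'
#' @param registry an `srm_registry` object.
#' @param wide_window_s windows wider than this (seconds) are reported as
#'   informational issues; default 30.
#' @return data.frame with columns `severity`, `analyte_id`, `message`;
#'   zero rows means clean.
#' @export
validate_registry <- function(registry, wide_window_s = 30) {
  stopifnot(inherits(registry, "srm_registry"))
  tr <- registry$transitions
  issues <- data.frame(severity = character(), analyte_id = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(severity, analyte_id, message) {
    rbind(issues, data.frame(severity = severity, analyte_id = analyte_id,
                             message = message, stringsAsFactors = FALSE))
  }
  # every (analyte, method) needs exactly one quantifier
  for (id in unique(tr$analyte_id)) {
    sub <- tr[tr$analyte_id == id, ]
    for (m in unique(sub$method)) {
      nq <- sum(sub$role == "quantifier" & sub$method == m)
      if (nq == 0) {
        issues <- add("error", id,
                      sprintf("no quantifier transition in method %s", m))
      } else if (nq > 1) {
        issues <- add("error", id,
                      sprintf("%d quantifier transitions in method %s", nq, m))
      }
    }
  }
  wide <- tr$window_s > wide_window_s
  for (i in which(wide)) {
    issues <- add("info", tr$analyte_id[i],
                  sprintf("detection window %.0f s exceeds the usual %.0f s",
                          tr$window_s[i], wide_window_s))
  }
  rownames(issues) <- NULL
  issues
}
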