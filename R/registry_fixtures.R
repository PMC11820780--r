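COMPOUND_CLASSES <- c(
  "amino acids", "biogenic amines", "amino acid related", "bile acids",
  "carboxylic acids", "carnitines", "ceramides", "cholesterol esters",
  "eicosanoids", "ethanolamides", "fatty acids", "glycerides",
  "nucleotides", "nucleosides", "phospholipids", "sterols", "sugars"
)

#' Build a synthetic full-scale transition registry
#'
#' Constructs a complete 235-analyte dual-method registry with the
#' structural features of a full plasma panel: two SRM transitions
#' (quantifier + qualifier) per analyte, except three single-transition
#' analytes (cholesteryl myristate, cholesteryl palmitoleate,
#' 3-hydroxyphenylacetic acid, for which only one reliable transition
#' exists) — giving 235 x 2 - 3 = 467 transitions in total.  Six analytes
#' (serine, myo-inositol and four bile acids) are measured in both
#' polarities, one transition per polarity.  Retention times, windows and
#' m/z values are deterministic placeholders; the object is synthetic and
#' intended for scheduling and bookkeeping exercises, not for acquisition.
#'
#' @param n_analytes total number of analytes (default 235).
#' @return an `srm_registry`.
#' @export
#' @examples
#' reg <- synthetic_full_registry()
#' registry_counts(reg)$n_transitions  # 467
synthetic_full_registry <- function(n_analytes = 235) {
  single_tr <- c("cholesteryl myristate", "cholesteryl palmitoleate",
                 "3-hydroxyphenylacetic acid")
  both_pol <- c("serine", "myo-inositol", "cholic acid",
                "chenodeoxycholic acid", "glycocholic acid",
                "taurocholic acid")
  n_named <- length(single_tr) + length(both_pol)
  if (n_analytes < n_named) stop("n_analytes too small")
  ids <- sprintf("a%03d", seq_len(n_analytes))
  name <- c(single_tr, both_pol,
            sprintf("metabolite %03d", seq_len(n_analytes - n_named)))
  class <- COMPOUND_CLASSES[(seq_len(n_analytes) - 1) %% 17 + 1]
  # roughly half the panel per LC method; named lipids go to RP,
  # serine/myo-inositol to HILIC
  method <- ifelse(seq_len(n_analytes) %% 2 == 0, "HILIC", "RP")
  method[1:2] <- "RP"; method[3] <- "RP"
  method[4:5] <- "HILIC"; method[6:9] <- "RP"
  calib_set <- ifelse(method == "HILIC", "HILIC",
                      ifelse(seq_len(n_analytes) %% 4 < 2, "RP_Aqu", "RP_Hep"))
  rt <- ifelse(method == "HILIC",
               1 + 7 * (seq_len(n_analytes) %% 97) / 96,
               2 + 13 * (seq_len(n_analytes) %% 89) / 88)
  prec <- 90 + (seq_len(n_analytes) * 7) %% 700 + 0.1
  polarity <- ifelse(seq_len(n_analytes) %% 3 == 0, "negative", "positive")

  rows <- lapply(seq_len(n_analytes), function(i) {
    is_single <- name[i] %in% single_tr
    is_both <- name[i] %in% both_pol
    flags <- paste(c(if (is_single) "single_transition",
                     if (is_both) "both_polarity"), collapse = ";")
    base <- data.frame(
      analyte_id = ids[i], name = name[i], class = class[i],
      method = method[i], polarity = polarity[i],
      precursor_mz = prec[i], product_mz = prec[i] - 30 - (i %% 50),
      role = "quantifier", rt_min = round(rt[i], 2), window_s = 30,
      calib_set = calib_set[i], flags = flags, stringsAsFactors = FALSE
    )
    if (is_single) return(base)
    qual <- base
    qual$role <- "qualifier"
    qual$product_mz <- base$product_mz - 18
    if (is_both) {
      qual$polarity <- ifelse(base$polarity == "positive",
                              "negative", "positive")
    }
    rbind(base, qual)
  })
  new_srm_registry(do.call(rbind, rows))
}
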