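# Full-blood-count index registry: which indices exist, their support
# (positive or proportion), adjustment scale, whether the analyzer measures
# them directly or they are derived, and the derivation formulas.

# evaluation order matters: parents before children
.derivations <- list(
  WBC       = function(d) d$NEUT + d$EO + d$BASO + d$MONO + d$LYMPH,
  GRAN      = function(d) d$NEUT + d$EO + d$BASO,
  HCT       = function(d) d$RBC * d$MCV / 10,
  MCH       = function(d) 10 * d$HGB / d$RBC,
  MCHC      = function(d) 100 * d$HGB / d$HCT,
  PCT       = function(d) d$PLT * d$MPV / 1e4,
  RET       = function(d) d$RET_PCT * d$RBC * 10,
  NEUT_PCT  = function(d) 100 * d$NEUT / d$WBC,
  EO_PCT    = function(d) 100 * d$EO / d$WBC,
  BASO_PCT  = function(d) 100 * d$BASO / d$WBC,
  MONO_PCT  = function(d) 100 * d$MONO / d$WBC,
  LYMPH_PCT = function(d) 100 * d$LYMPH / d$WBC
)

# immediate inputs of each derivation (note MCHC and the percentages consume
# derived parents, which .derivations computes first)
.derivation_parents <- list(
  WBC = c("NEUT", "EO", "BASO", "MONO", "LYMPH"),
  GRAN = c("NEUT", "EO", "BASO"),
  HCT = c("RBC", "MCV"),
  MCH = c("HGB", "RBC"),
  MCHC = c("HGB", "HCT"),
  PCT = c("PLT", "MPV"),
  RET = c("RET_PCT", "RBC"),
  NEUT_PCT = c("NEUT", "WBC"),
  EO_PCT = c("EO", "WBC"),
  BASO_PCT = c("BASO", "WBC"),
  MONO_PCT = c("MONO", "WBC"),
  LYMPH_PCT = c("LYMPH", "WBC")
)

#' Registry of blood cell indices
#'
#' One row per index with its cell class, support (`positive` indices are
#' modelled on the log scale, `proportion` indices on the logit scale), role
#' (`measured` by the analyzer or deterministically `derived` from measured
#' indices), derivation formula, physical unit, and the population baseline
#' and between-person SD (on the adjustment scale) used by the cohort
#' simulator. The measured subset is the canonical minimal set from which the
#' full index set can be recomputed: the five white-cell counts, RBC#, MCV,
#' HGB, RDW, RET%, PLT#, MPV and PDW.
#'
#' @param indices optional character vector restricting the registry to the
#'   given indices together with every measured ancestor they need.
#' @return a tibble with columns `index`, `index_class`, `support`,
#'   `adjustment_scale`, `role`, `derivation`, `unit`, `baseline`, `sd_a`.
#' @examples
#' blood_index_registry()
#' @export
blood_index_registry <- function(indices = NULL) {
  reg <- tribble(
    ~index,      ~index_class,   ~support,     ~role,      ~derivation,               ~unit,       ~baseline, ~sd_a,
    "RBC",       "mature-RBC",   "positive",   "measured", NA,                        "10^12/L",   4.9,   0.10,
    "MCV",       "mature-RBC",   "positive",   "measured", NA,                        "fL",        90,    0.05,
    "HGB",       "mature-RBC",   "positive",   "measured", NA,                        "g/dL",      14.5,  0.09,
    "RDW",       "mature-RBC",   "positive",   "measured", NA,                        "%CV",       13.5,  0.07,
    "RET_PCT",   "immature-RBC", "proportion", "measured", NA,                        "%",         1.3,   0.45,
    "PLT",       "platelet",     "positive",   "measured", NA,                        "10^9/L",    250,   0.25,
    "MPV",       "platelet",     "positive",   "measured", NA,                        "fL",        10.2,  0.08,
    "PDW",       "platelet",     "positive",   "measured", NA,                        "fL",        12.5,  0.12,
    "NEUT",      "myeloid-WBC",  "positive",   "measured", NA,                        "10^9/L",    4.2,   0.35,
    "EO",        "myeloid-WBC",  "positive",   "measured", NA,                        "10^9/L",    0.17,  0.65,
    "BASO",      "myeloid-WBC",  "positive",   "measured", NA,                        "10^9/L",    0.04,  0.60,
    "MONO",      "myeloid-WBC",  "positive",   "measured", NA,                        "10^9/L",    0.45,  0.35,
    "LYMPH",     "lymphoid-WBC", "positive",   "measured", NA,                        "10^9/L",    1.9,   0.30,
    "WBC",       "compound-WBC", "positive",   "derived",  "NEUT+EO+BASO+MONO+LYMPH", "10^9/L",    NA,    NA,
    "GRAN",      "myeloid-WBC",  "positive",   "derived",  "NEUT+EO+BASO",            "10^9/L",    NA,    NA,
    "HCT",       "mature-RBC",   "proportion", "derived",  "RBC*MCV/10",              "%",         NA,    NA,
    "MCH",       "mature-RBC",   "positive",   "derived",  "10*HGB/RBC",              "pg",        NA,    NA,
    "MCHC",      "mature-RBC",   "positive",   "derived",  "100*HGB/HCT",             "g/dL",      NA,    NA,
    "PCT",       "platelet",     "proportion", "derived",  "PLT*MPV/1e4",             "%",         NA,    NA,
    "RET",       "immature-RBC", "positive",   "derived",  "RET_PCT*RBC*10",          "10^9/L",    NA,    NA,
    "NEUT_PCT",  "myeloid-WBC",  "proportion", "derived",  "100*NEUT/WBC",            "%",         NA,    NA,
    "EO_PCT",    "myeloid-WBC",  "proportion", "derived",  "100*EO/WBC",              "%",         NA,    NA,
    "BASO_PCT",  "myeloid-WBC",  "proportion", "derived",  "100*BASO/WBC",            "%",         NA,    NA,
    "MONO_PCT",  "myeloid-WBC",  "proportion", "derived",  "100*MONO/WBC",            "%",         NA,    NA,
    "LYMPH_PCT", "lymphoid-WBC", "proportion", "derived",  "100*LYMPH/WBC",           "%",         NA,    NA
  )
  reg$adjustment_scale <- ifelse(reg$support == "positive", "log", "logit")
  if (!is.null(indices)) {
    unknown <- setdiff(indices, reg$index)
    if (length(unknown)) {
      abort(paste0("Unknown indices: ", paste(unknown, collapse = ", ")))
    }
    need <- unique(c(indices, unlist(lapply(indices, .index_parents))))
    reg <- reg[reg$index %in% need, ]
  }
  reg
}

# measured ancestors of an index (itself if measured)
.index_parents <- function(index) {
  direct <- list(
    WBC = c("NEUT", "EO", "BASO", "MONO", "LYMPH"),
    GRAN = c("NEUT", "EO", "BASO"),
    HCT = c("RBC", "MCV"), MCH = c("HGB", "RBC"),
    MCHC = c("HGB", "RBC", "MCV"), PCT = c("PLT", "MPV"),
    RET = c("RET_PCT", "RBC"),
    NEUT_PCT = c("NEUT", "EO", "BASO", "MONO", "LYMPH"),
    EO_PCT = c("NEUT", "EO", "BASO", "MONO", "LYMPH"),
    BASO_PCT = c("NEUT", "EO", "BASO", "MONO", "LYMPH"),
    MONO_PCT = c("NEUT", "EO", "BASO", "MONO", "LYMPH"),
    LYMPH_PCT = c("NEUT", "EO", "BASO", "MONO", "LYMPH")
  )
  direct[[index]] %||% index
}

#' Number of independent measurements behind a set of indices
#'
#' Counts the distinct measured ancestors required to compute the given
#' indices -- the intrinsic dimension of the set, and the chi-square degrees
#' of freedom appropriate for multivariate outlier scoring when only a
#' subset of an outlier group is available.
#'
#' @param indices character vector of index names.
#' @return integer count.
#' @export
independent_measurements <- function(indices) {
  length(unique(unlist(lapply(indices, .index_parents))))
}

#' Outlier groups of indices and their intrinsic dimension
#'
#' Index groups used for multivariate outlier screening, each with `d`, the
#' number of independent analyzer measurements required to compute every
#' member of the group (the chi-square degrees of freedom of the group's
#' whitened PC-score statistic).
#'
#' @return tibble with columns `group`, `indices` (list-column), `d`.
#' @export
index_outlier_groups <- function() {
  reg <- blood_index_registry()
  tribble(
    ~group, ~indices, ~d,
    "platelet", list(c("PLT", "MPV", "PDW", "PCT")), 3L,
    "red", list(c("RBC", "MCV", "HGB", "RDW", "HCT", "MCH", "MCHC",
                  "RET_PCT", "RET")), 5L,
    "immature-red", list(c("RET_PCT", "RET")), 2L,
    "white", list(c("WBC", "NEUT", "EO", "BASO", "MONO", "LYMPH", "GRAN",
                    "NEUT_PCT", "EO_PCT", "BASO_PCT", "MONO_PCT",
                    "LYMPH_PCT")), 5L,
    "myeloid", list(c("NEUT", "EO", "BASO", "MONO", "GRAN")), 4L,
    "all", list(reg$index), 13L
  ) |>
    mutate(indices = purrr::map(.data$indices, 1L))
}

#' Study reference table
#'
#' Post-QC sample sizes and the default genomic-control inflation factors of
#' the three-study design the package emulates (study A: UK Biobank-like,
#' B: INTERVAL-like, C: BiLEVE-like analyzers).
#'
#' @return tibble with columns `study`, `analyzer`, `n_postqc`.
#' @export
study_reference <- function() {
  tribble(
    ~study, ~analyzer, ~n_postqc,
    "A", "coulter", 87265L,
    "B", "sysmex", 40521L,
    "C", "coulter", 45694L
  )
}
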