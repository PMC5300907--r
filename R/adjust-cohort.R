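# End-to-end phenotype preparation for one study: the two-stage adjustment,
# exclusion rules, outlier removal and stratified inverse-normal transform.

#' Prepare analysis-ready phenotypes for a cohort
#'
#' Runs the full phenotype pipeline on one study: (1) stage-1 technical and
#' seasonal adjustment of every measured index ([technical_adjust()]),
#' recomputing derived indices afterwards; (2) technical sample exclusions
#' ([sample_filters()]: 36 h venipuncture-delay rule and the
#' analyzer-specific platelet rules); (3) stage-2 environmental and sex
#' adjustment of measured and derived indices ([environmental_adjust()]);
#' (4) raw-vs-adjusted difference outliers on the adjustment scale
#' ([adjustment_difference_outliers()]); (5) univariate (4.5 MAD) and
#' grouped multivariate chi-square outlier removal
#' ([multivariate_outlier_scores()]); (6) stratified quantile inverse-normal
#' transformation within analyzer x sex/menopause strata
#' ([inverse_normal_transform()]).
#'
#' @param cohort a `cohort_dataset`.
#' @param indices indices to carry through (default: all in the cohort).
#' @param knots stage-1 basis dimensions, see [technical_adjust()].
#' @param env_knots stage-2 basis dimensions, see [environmental_terms()].
#' @param thresholds list of rule thresholds (defaults: `central_k` 3.5,
#'   `univariate_k` 4.5, `z_max` 8, `min_cell_n` 10, `tail_p` 1e-7,
#'   `max_delay_h` 36, `mpv_limit` 13, `mpv_quantile` 0.96).
#' @return list with `phenotypes` (tibble: `sample_id`, strata, one
#'   normal-scored column per index), `exclusions` (long tibble with reason
#'   codes), `technical_fits`, `environmental_fits`, `filters`.
#' @export
adjust_cohort <- function(cohort, indices = NULL,
                          knots = list(drift = 50, bivariate = 30,
                                       seasonal = 30),
                          env_knots = list(age = 30, body = 30,
                                           packyears = 10, alcohol = 30,
                                           period = 30),
                          thresholds = list()) {
  th <- utils::modifyList(
    list(central_k = 3.5, univariate_k = 4.5, z_max = 8, min_cell_n = 10,
         tail_p = 1e-7, max_delay_h = 36, mpv_limit = 13,
         mpv_quantile = 0.96), thresholds)
  reg <- cohort$registry
  present <- intersect(reg$index, names(cohort$samples))
  if (!is.null(indices)) present <- intersect(present, indices)

  # stage 1: technical adjustment of measured indices, derived recomputed
  st1 <- technical_adjust_cohort(cohort,
                                 indices = intersect(
                                   present, reg$index[reg$role == "measured"]),
                                 knots = knots, central_k = th$central_k,
                                 min_cell_n = th$min_cell_n, z_max = th$z_max)
  work <- st1$cohort
  exclusions <- st1$exclusions

  # technical sample exclusions (36 h rule, platelet contamination)
  filt <- sample_filters(work, adjusted_mpv = work$samples$MPV,
                         max_delay_h = th$max_delay_h,
                         mpv_limit = th$mpv_limit,
                         mpv_quantile = th$mpv_quantile)
  platelet_idx <- intersect(reg$index[reg$index_class == "platelet"], present)
  for (idx in present) {
    v <- work$samples[[idx]]
    v[filt$exclude_all] <- NA_real_
    if (idx %in% platelet_idx) v[filt$null_platelet] <- NA_real_
    work$samples[[idx]] <- v
  }
  exclusions <- bind_rows(
    exclusions,
    filt |> filter(!is.na(.data$reason)) |>
      transmute(sample_id = .data$sample_id, index = NA_character_,
                stage = "sample_filter", reason = .data$reason))

  # stage 2: environmental adjustment of measured AND derived indices
  terms <- environmental_terms(
    if (cohort$study_id %in% c("A", "B", "C")) cohort$study_id else "A",
    knots = env_knots)
  env_fits <- list()
  a_adj <- list()
  for (idx in present) {
    ef <- environmental_adjust(work, idx, terms = terms,
                               central_k = th$central_k)
    env_fits[[idx]] <- ef
    a_adj[[idx]] <- ef$adjusted$a_adjusted
  }

  # raw-vs-adjusted difference outliers, per index on the adjustment scale
  for (idx in present) {
    scl <- reg$adjustment_scale[reg$index == idx]
    a_raw <- to_adjustment_scale(cohort$samples[[idx]], scl)
    mask <- adjustment_difference_outliers(a_raw, a_adj[[idx]],
                                           k = th$central_k)
    a_adj[[idx]][mask] <- NA_real_
    if (any(mask)) {
      exclusions <- bind_rows(exclusions, tibble(
        sample_id = cohort$samples$sample_id[mask], index = idx,
        stage = "difference_outlier", reason = "adjustment_difference"))
    }
  }
  amat <- as_tibble(a_adj)

  # grouped multivariate outliers (after the univariate 4.5 MAD screen)
  for (grp in seq_len(nrow(index_outlier_groups()))) {
    ginfo <- index_outlier_groups()[grp, ]
    members <- intersect(ginfo$indices[[1]], names(amat))
    if (length(members) < 2) next
    # with only part of the group simulated, the intrinsic dimension is the
    # number of distinct measured ancestors actually present
    d_eff <- min(ginfo$d, independent_measurements(members), length(members))
    sc <- multivariate_outlier_scores(amat[members], d = d_eff,
                                      univariate_k = th$univariate_k,
                                      tail_p = th$tail_p)
    bad <- which(sc$excluded)
    for (idx in members) amat[[idx]][bad] <- NA_real_
    if (length(bad)) {
      exclusions <- bind_rows(exclusions, tibble(
        sample_id = rep(cohort$samples$sample_id[bad], length(members)),
        index = rep(members, each = length(bad)),
        stage = "multivariate_outlier",
        reason = rep(sc$reason[bad], length(members))))
    }
  }

  # final stratified inverse-normal transform (analyzer x sex/menopause)
  strata <- paste(cohort$analyzer, cohort$samples$sexmeno, sep = ":")
  pheno <- amat
  for (idx in present) {
    pheno[[idx]] <- inverse_normal_transform(amat[[idx]], strata)
  }
  phenotypes <- bind_cols(
    tibble(sample_id = cohort$samples$sample_id,
           study = cohort$study_id, stratum = strata),
    pheno)
  list(phenotypes = phenotypes, exclusions = exclusions,
       technical_fits = st1$fits, environmental_fits = env_fits,
       filters = filt)
}
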