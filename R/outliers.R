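# Sample-level exclusion rules, robust outlier screens and the final
# stratified quantile-inverse-normal transformation.

#' Technical sample exclusion flags
#'
#' Applies the sample-ageing and platelet-contamination rules: (a) all
#' indices excluded when the venipuncture-to-acquisition delay exceeds
#' `max_delay_h` (36 h); (b) Sysmex-type analyzers: platelet indices nulled
#' when MPV > `mpv_limit` (13 fL); (c) Coulter-type analyzers: platelet
#' indices nulled when the technically adjusted MPV exceeds the
#' `mpv_quantile` (96th) percentile. Strict inequalities throughout (a delay
#' of exactly 36 h, an MPV of exactly 13, or an adjusted MPV at the 96th
#' percentile are retained).
#'
#' @param cohort a `cohort_dataset` (uses `analyzer`, timestamps, `MPV`).
#' @param adjusted_mpv technically adjusted MPV values for the Coulter rule;
#'   defaults to the cohort's current MPV column.
#' @param max_delay_h,mpv_limit,mpv_quantile rule thresholds.
#' @return tibble `sample_id`, `delay_h`, `exclude_all`, `null_platelet`,
#'   `reason` (`NA` when no rule fires; samples with missing timestamps are
#'   flagged `unexcludable`).
#' @export
sample_filters <- function(cohort, adjusted_mpv = NULL,
                           max_delay_h = 36, mpv_limit = 13,
                           mpv_quantile = 0.96) {
  s <- cohort$samples
  delay_h <- as.numeric(difftime(s$acq_time, s$ven_time, units = "hours"))
  no_ts <- is.na(delay_h)
  exclude_all <- !no_ts & delay_h > max_delay_h
  null_platelet <- rep(FALSE, nrow(s))
  if (cohort$analyzer == "sysmex" && "MPV" %in% names(s)) {
    null_platelet <- !is.na(s$MPV) & s$MPV > mpv_limit
  } else if (cohort$analyzer == "coulter") {
    mpv <- adjusted_mpv %||% s$MPV
    if (!is.null(mpv)) {
      thr <- quantile(mpv, mpv_quantile, na.rm = TRUE, names = FALSE)
      null_platelet <- !is.na(mpv) & mpv > thr
    }
  }
  tibble(sample_id = s$sample_id, delay_h = delay_h,
         exclude_all = exclude_all, null_platelet = null_platelet,
         reason = dplyr::case_when(
           no_ts ~ "unexcludable_missing_timestamp",
           exclude_all ~ "delay_gt_36h",
           null_platelet ~ "platelet_contamination",
           TRUE ~ NA_character_))
}

#' Raw-vs-adjusted difference outliers
#'
#' Flags observations whose adjustment-scale difference between raw and
#' adjusted values deviates more than `k` scaled MADs from the median
#' difference.
#'
#' @param raw,adjusted paired values on the adjustment scale.
#' @param k threshold in scaled MADs (default 3.5).
#' @param mad_constant MAD consistency factor.
#' @return logical exclusion mask (`NA` pairs are `FALSE`).
#' @export
adjustment_difference_outliers <- function(raw, adjusted, k = 3.5,
                                           mad_constant = 1.4826) {
  d <- raw - adjusted
  m <- median(d, na.rm = TRUE)
  s <- scaled_mad(d, mad_constant)
  if (!is.finite(s) || s == 0) {
    warn("MAD of raw-adjusted differences is zero; no exclusions.")
    return(rep(FALSE, length(d)))
  }
  out <- !is.na(d) & abs(d - m) > k * s
  out
}

#' Multivariate outlier scores for an index group
#'
#' Standardizes each index of the group on the adjustment scale, removes
#' univariate outliers beyond `univariate_k` scaled MADs, performs a PCA on
#' the complete remaining rows, and scores each sample by the sum of squares
#' of its leading `d` whitened PC scores (each PC score divided by its SD, so
#' the statistic is chi-square with `d` degrees of freedom for well-behaved
#' data). Samples whose score falls strictly into the upper `tail_p` tail of
#' the chi-square are flagged.
#'
#' @param values data frame/matrix of adjusted index values on the adjustment
#'   scale (columns = group members). Rows with any missing member are
#'   skipped (score `NA`).
#' @param d number of leading components (the group's independent-measurement
#'   count); must not exceed the group size.
#' @param univariate_k univariate screen threshold (default 4.5 scaled MADs).
#' @param tail_p chi-square upper tail probability (default 1e-7).
#' @param mad_constant MAD consistency factor.
#' @return tibble `score`, `excluded`, `reason` (one row per input row).
#' @export
multivariate_outlier_scores <- function(values, d, univariate_k = 4.5,
                                        tail_p = 1e-7,
                                        mad_constant = 1.4826) {
  x <- as.matrix(values)
  if (d > ncol(x)) {
    abort(sprintf("d (%d) exceeds the group size (%d).", d, ncol(x)))
  }
  uni_out <- rep(FALSE, nrow(x))
  for (j in seq_len(ncol(x))) {
    mj <- median(x[, j], na.rm = TRUE)
    sj <- scaled_mad(x[, j], mad_constant)
    if (is.finite(sj) && sj > 0) {
      uni_out <- uni_out | (!is.na(x[, j]) & abs(x[, j] - mj) > univariate_k * sj)
    }
  }
  complete <- complete.cases(x)
  fit_rows <- complete & !uni_out
  z <- scale(x[fit_rows, , drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  keep <- seq_len(d)
  sdev <- pc$sdev[keep]
  # (near-)zero-variance PCs are numerical artifacts of derived-index
  # collinearity and must not be whitened into huge scores
  sdev[sdev < 1e-6 * max(pc$sdev)] <- Inf
  white <- sweep(pc$x[, keep, drop = FALSE], 2, sdev, "/")
  sc <- rowSums(white^2)
  score <- rep(NA_real_, nrow(x))
  score[fit_rows] <- sc
  thr <- qchisq(tail_p, df = d, lower.tail = FALSE)
  excluded <- !is.na(score) & score > thr
  excluded[uni_out] <- TRUE
  tibble(score = score,
         excluded = excluded,
         reason = dplyr::case_when(
           uni_out ~ "univariate_outlier",
           excluded ~ "multivariate_outlier",
           !complete ~ "incomplete_group",
           TRUE ~ NA_character_))
}

#' Stratified quantile inverse-normal transformation
#'
#' Within each stratum (analyzer crossed with sex/menopause category in the
#' full pipeline), maps value ranks through the normal quantile function,
#' `qnorm((rank - 0.5) / n)`, with ties receiving average ranks. Strata of
#' size one are set missing with a warning.
#'
#' @param values numeric vector.
#' @param strata stratum labels (factor/character), recycled to `values`;
#'   default a single stratum.
#' @return numeric vector of normal scores; `NA` preserved.
#' @export
inverse_normal_transform <- function(values, strata = NULL) {
  strata <- strata %||% rep("all", length(values))
  strata <- rep_len(as.character(strata), length(values))
  out <- rep(NA_real_, length(values))
  for (st in unique(strata)) {
    i <- which(strata == st & !is.na(values))
    if (length(i) == 0) next
    if (length(i) < 2) {
      warn(sprintf("Stratum '%s' has a single observation; set missing.", st))
      next
    }
    r <- rank(values[i], ties.method = "average")
    out[i] <- qnorm((r - 0.5) / length(i))
  }
  out
}
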