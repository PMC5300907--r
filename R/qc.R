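# Sample-level genetic QC scores and imputation accuracy metrics.

#' Variance-weighted genetic distance from a reference centroid
#'
#' `d(i) = sum_m E_m (P_im - C_m)^2` over the leading `m` principal
#' components, where `E_m` are the PC eigenvalues (variances), `P_im` the
#' sample's PC scores and `C_m` the reference (e.g. ancestry-cluster) score
#' medians. Samples with `d > threshold` (50) are flagged as ancestry
#' outliers.
#'
#' @param scores samples x m matrix of PC scores (m = 15 in the reference
#'   analysis; any m is accepted, but the three inputs must agree).
#' @param eigenvalues per-PC variances, length m, non-negative.
#' @param reference_medians per-PC reference score medians, length m.
#' @param threshold exclusion flag threshold (default 50).
#' @return tibble `distance`, `flagged` (one row per sample).
#' @export
genetic_distance <- function(scores, eigenvalues, reference_medians,
                             threshold = 50) {
  scores <- as.matrix(scores)
  m <- ncol(scores)
  if (length(eigenvalues) != m || length(reference_medians) != m) {
    abort("`eigenvalues` and `reference_medians` must match ncol(scores).")
  }
  if (any(eigenvalues < 0)) abort("Eigenvalues must be non-negative.")
  delta <- sweep(scores, 2, reference_medians)
  d <- drop(delta^2 %*% eigenvalues)
  tibble(distance = d, flagged = d > threshold)
}

# hard-call dosages at 0.5/1.5
hard_call <- function(dosage) {
  calls <- matrix(1L, nrow(as.matrix(dosage)), ncol(as.matrix(dosage)))
  d <- as.matrix(dosage)
  calls[d < 0.5] <- 0L
  calls[d > 1.5] <- 2L
  dimnames(calls) <- dimnames(d)
  calls
}

#' Imputation accuracy: non-reference concordance and precision
#'
#' Compares imputed genotype calls with sequencing truth on a shared
#' sample x variant grid. Non-reference concordance is the fraction of the
#' truth's non-reference calls (heterozygotes and alternate homozygotes)
#' recovered exactly by imputation; precision is the fraction of the imputed
#' non-reference calls that are correct per the truth. Dosages are
#' hard-called at 0.5/1.5. Either metric is reported missing when its
#' denominator is empty.
#'
#' @param imputed,truth matrices of genotype calls in \{0, 1, 2\} or dosages
#'   in \[0, 2\] (hard-called), same dimensions.
#' @param maf optional per-variant MAF for binned reporting.
#' @param bins MAF bin edges (common/low-frequency/rare cut at 0.05, 0.01).
#' @return tibble with `bin`, `n_truth_nonref`, `n_imputed_nonref`,
#'   `concordance`, `precision`; first row is the overall grid.
#' @export
imputation_accuracy <- function(imputed, truth, maf = NULL,
                                bins = c(0, 0.01, 0.05, 0.5)) {
  gi <- hard_call(imputed)
  gt <- hard_call(truth)
  if (!all(dim(gi) == dim(gt))) {
    abort("`imputed` and `truth` must share the same sample x variant grid.")
  }
  one <- function(cols) {
    ii <- gi[, cols, drop = FALSE]
    tt <- gt[, cols, drop = FALSE]
    truth_nr <- tt != 0L
    imp_nr <- ii != 0L
    conc <- if (sum(truth_nr) == 0) NA_real_ else
      sum(truth_nr & ii == tt) / sum(truth_nr)
    prec <- if (sum(imp_nr) == 0) NA_real_ else
      sum(imp_nr & ii == tt) / sum(imp_nr)
    tibble(n_truth_nonref = sum(truth_nr), n_imputed_nonref = sum(imp_nr),
           concordance = conc, precision = prec)
  }
  out <- bind_cols(tibble(bin = "all"), one(seq_len(ncol(gi))))
  if (!is.null(maf)) {
    labs <- c("rare", "low-frequency", "common")
    grp <- cut(maf, bins, labels = labs, include.lowest = TRUE)
    for (b in labs) {
      cols <- which(grp == b)
      if (length(cols)) {
        out <- bind_rows(out, bind_cols(tibble(bin = b), one(cols)))
      }
    }
  }
  out
}

#' Heterozygosity-rate outliers
#'
#' Flags samples whose autosomal heterozygosity rate deviates more than `k`
#' standard deviations from the cohort mean.
#'
#' @param het_rate per-sample heterozygosity rates (>= 2 samples).
#' @param k SD multiplier (default 3).
#' @return logical mask; all-`FALSE` when the rates have zero variance.
#' @export
heterozygosity_outliers <- function(het_rate, k = 3) {
  if (length(het_rate) < 2) abort("Need at least two samples.")
  s <- sd(het_rate, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(het_rate)))
  !is.na(het_rate) & abs(het_rate - mean(het_rate, na.rm = TRUE)) > k * s
}
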