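# Multivariable Mendelian randomization of blood indices on disease
# outcomes: index pruning, IVW estimation, realigned multivariable Egger,
# Bonferroni accounting and sensitivity exclusions.

#' Default index priority order for pruning
#'
#' The thirteen sentinel indices retained by the reference analysis, in
#' priority order; used as the default retention order by [prune_indices()].
#'
#' @return character vector of index names.
#' @export
mr_index_priority <- function() {
  c("PLT", "MPV", "PDW", "HCT", "MCH", "RDW", "RET", "IRF",
    "MONO", "NEUT", "EO", "BASO", "LYMPH")
}

#' Prune genetically correlated indices
#'
#' Greedy retention in priority order: an index is dropped iff its squared
#' correlation with an already-retained index exceeds `threshold` (0.8), so
#' every dropped index has a retained representative.
#'
#' @param corr symmetric index-by-index genetic correlation matrix with unit
#'   diagonal (correlations `r`; they are squared internally).
#' @param threshold r-squared threshold (default 0.8, strict `>`).
#' @param priority retention order; defaults to [mr_index_priority()]
#'   members present in `corr`, followed by any remaining indices in column
#'   order.
#' @return character vector of retained index names.
#' @export
prune_indices <- function(corr, threshold = 0.8, priority = NULL) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    abort("Correlation matrix must be symmetric.")
  }
  nm <- colnames(corr) %||% paste0("IDX", seq_len(ncol(corr)))
  dimnames(corr) <- list(nm, nm)
  priority <- priority %||% c(intersect(mr_index_priority(), nm),
                              setdiff(nm, mr_index_priority()))
  priority <- intersect(priority, nm)
  retained <- character(0)
  for (idx in priority) {
    if (!length(retained) ||
        all(corr[idx, retained]^2 <= threshold)) {
      retained <- c(retained, idx)
    }
  }
  retained
}

# weighted least squares core shared by IVW and Egger
.mvmr_wls <- function(x, y, w, overdispersion = FALSE, labels = colnames(x)) {
  sw <- sqrt(w)
  xs <- x * sw
  qx <- qr(xs)
  if (qx$rank < ncol(xs)) {
    bad <- labels[qx$pivot[(qx$rank + 1):ncol(xs)]]
    abort(paste0("Exposure matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  theta <- qr.coef(qx, y * sw)
  xtx_inv <- chol2inv(qr.R(qx))
  df <- length(y) - ncol(xs)
  sigma2 <- sum((y * sw - xs %*% theta)^2) / df
  scale2 <- if (overdispersion) max(1, sigma2) else 1
  se <- sqrt(diag(xtx_inv) * scale2)
  list(theta = drop(theta), se = se, sigma2 = sigma2, df = df)
}

#' Multivariable inverse-variance-weighted Mendelian randomization
#'
#' Regresses variant-disease effects on the variant-index effect columns
#' without an intercept, weighted by the inverse variance of the disease
#' effects: `theta = (Bx' W Bx)^-1 Bx' W by`, `W = diag(1/sey^2)`. Standard
#' errors come from the fixed-effect weighted-least-squares covariance
#' `(Bx' W Bx)^-1` (optionally scaled by an overdispersion factor floored at
#' 1); only the disease-side SEs enter the weights. Estimates are causal
#' log-odds of disease per SD of each index, conditional on the other
#' indices.
#'
#' @param data an `mr_dataset` (see [simulate_mr_summaries()] /
#'   [read_mr_dataset()]).
#' @param overdispersion scale SEs by `max(1, sigma_hat^2)` (default off:
#'   fixed-effect).
#' @return an `mr_result` tibble: `index`, `theta`, `se`, `p`, `or`,
#'   `or_lo`, `or_hi`; attributes `n_instruments`, `sigma2`, `method`.
#' @export
mvmr_ivw <- function(data, overdispersion = FALSE) {
  w <- 1 / data$sey^2
  fit <- .mvmr_wls(data$Bx, data$by, w, overdispersion,
                   labels = data$index_names)
  .mr_result(data$index_names, fit, method = "mvmr_ivw",
             n_instruments = nrow(data$Bx))
}

.mr_result <- function(index, fit, method, n_instruments,
                       intercept = NULL) {
  fit$theta <- unname(fit$theta)
  fit$se <- unname(fit$se)
  z <- fit$theta / fit$se
  out <- tibble(index = index, theta = fit$theta, se = fit$se,
                p = 2 * pnorm(-abs(z)),
                or = exp(fit$theta),
                or_lo = exp(fit$theta - 1.96 * fit$se),
                or_hi = exp(fit$theta + 1.96 * fit$se))
  structure(out, class = c("mr_result", class(out)),
            method = method, n_instruments = n_instruments,
            sigma2 = fit$sigma2, intercept = intercept)
}

#' Realigned multivariable MR-Egger
#'
#' For the alignment index `align_index` (k), every instrument row is
#' sign-flipped so its effect on index k is non-negative (the disease effect
#' and all other index effects flip with it), and the weighted regression is
#' rerun with a free intercept. The intercept estimates the unbalanced
#' directional pleiotropy with respect to index k; the procedure is run
#' separately for each k of interest. Outputs are invariant to sign flips of
#' input rows.
#'
#' @inheritParams mvmr_ivw
#' @param align_index index name or column number to realign on.
#' @return an `mr_result` tibble of the slopes, with the intercept row in
#'   attribute `"intercept"` (tibble: `estimate`, `se`, `p`).
#' @export
mvmr_egger <- function(data, align_index = 1, overdispersion = FALSE) {
  k <- if (is.character(align_index)) match(align_index, data$index_names)
  else align_index
  if (is.na(k) || k < 1 || k > ncol(data$Bx)) {
    abort("`align_index` not found among the dataset's indices.")
  }
  s <- sign(data$Bx[, k])
  s[s == 0] <- 1
  bx <- data$Bx * s
  by <- data$by * s
  x <- cbind(`(intercept)` = 1, bx)
  fit <- .mvmr_wls(x, by, 1 / data$sey^2, overdispersion,
                   labels = colnames(x))
  int <- tibble(estimate = fit$theta[1], se = fit$se[1],
                p = 2 * pnorm(-abs(fit$theta[1] / fit$se[1])))
  slope_fit <- list(theta = fit$theta[-1], se = fit$se[-1],
                    sigma2 = fit$sigma2)
  .mr_result(data$index_names, slope_fit,
             method = sprintf("mvmr_egger[align=%s]", data$index_names[k]),
             n_instruments = nrow(bx), intercept = int)
}

#' Egger intercepts for every alignment index
#'
#' @inheritParams mvmr_ivw
#' @return tibble `align_index`, `intercept`, `se`, `p`.
#' @export
mvmr_egger_intercepts <- function(data, overdispersion = FALSE) {
  purrr::map_dfr(seq_along(data$index_names), function(k) {
    int <- attr(mvmr_egger(data, k, overdispersion), "intercept")
    tibble(align_index = data$index_names[k], intercept = int$estimate,
           se = int$se, p = int$p)
  })
}

#' Bonferroni accounting for the index-by-disease test grid
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_indices,n_diseases grid dimensions.
#' @return list with `n_tests` and `threshold` (`alpha / n_tests`).
#' @examples
#' bonferroni_threshold(0.05, 13, 14)   # 182 tests, 2.747e-4
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_indices = 13,
                                 n_diseases = 14) {
  stop_if_not_scalar_count(n_indices, "n_indices")
  stop_if_not_scalar_count(n_diseases, "n_diseases")
  n_tests <- as.integer(n_indices) * as.integer(n_diseases)
  list(n_tests = n_tests, threshold = alpha / n_tests)
}

#' Sensitivity exclusions for MR instruments
#'
#' Removes instrument rows by mode: `"mhc"` drops variants in
#' chr6:20,000,000-40,000,000; `"known_disease_loci"` drops variants flagged
#' as known disease-associated; `"pleiotropic_clumps"` drops variants whose
#' clump is univariately associated with all five index classes. The pruned
#' dataset is re-checked for column rank.
#'
#' @param data an `mr_dataset` with `variants` annotations (`chrom`, `pos`,
#'   `known_disease`, `n_index_classes`).
#' @param mode one of `"mhc"`, `"known_disease_loci"`,
#'   `"pleiotropic_clumps"`.
#' @param mhc_range MHC interval (inclusive).
#' @return the filtered `mr_dataset`.
#' @export
sensitivity_filter <- function(data,
                               mode = c("mhc", "known_disease_loci",
                                        "pleiotropic_clumps"),
                               mhc_range = c(20e6, 40e6)) {
  mode <- match.arg(mode)
  v <- data$variants
  drop <- switch(mode,
    mhc = v$chrom == "6" & v$pos >= mhc_range[1] & v$pos <= mhc_range[2],
    known_disease_loci = isTRUE_vec(v$known_disease),
    pleiotropic_clumps = !is.na(v$n_index_classes) & v$n_index_classes >= 5)
  keep <- !drop
  if (!any(keep)) abort("Sensitivity filter removed every instrument.")
  out <- data
  out$variants <- v[keep, ]
  out$Bx <- data$Bx[keep, , drop = FALSE]
  out$SEx <- data$SEx[keep, , drop = FALSE]
  out$by <- data$by[keep]
  out$sey <- data$sey[keep]
  if (qr(out$Bx)$rank < ncol(out$Bx)) {
    abort("Filtered exposure matrix is rank deficient.")
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write / read an MR dataset as TSV tables
#'
#' The index-effect table holds one row per instrument with `beta_<index>` /
#' `se_<index>` column pairs plus the disease effect (`by`, `sey`) and
#' variant annotations.
#'
#' @param data an `mr_dataset`; `path` file path.
#' @export
write_mr_dataset <- function(data, path) {
  bx <- as_tibble(data$Bx)
  names(bx) <- paste0("beta_", data$index_names)
  sx <- as_tibble(data$SEx)
  names(sx) <- paste0("se_", data$index_names)
  tab <- bind_cols(data$variants, bx, sx,
                   tibble(by = data$by, sey = data$sey))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_mr_dataset
#' @export
read_mr_dataset <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  bcols <- grep("^beta_", names(tab), value = TRUE)
  idx <- sub("^beta_", "", bcols)
  bx <- as.matrix(tab[bcols]); colnames(bx) <- idx
  sx <- as.matrix(tab[paste0("se_", idx)]); colnames(sx) <- idx
  vcols <- setdiff(names(tab), c(bcols, paste0("se_", idx), "by", "sey"))
  v <- tab[vcols]
  v$chrom <- as.character(v$chrom)
  structure(list(variants = as_tibble(v), Bx = bx, SEx = sx,
                 by = tab$by, sey = tab$sey, index_names = idx,
                 truth = NULL),
            class = "mr_dataset")
}
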