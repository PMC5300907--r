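#' Simulate summary statistics for multivariable Mendelian randomization
#'
#' Draws variant-index effect matrices and variant-disease effects under the
#' linear causal model by = Bx theta + pleiotropy + noise, with the ground
#' truth retained for calibration tests.
#'
#' @param n_variants number of instruments (must exceed the number of
#'   indices).
#' @param causal_theta named (or unnamed) numeric vector of per-index causal
#'   log-odds effects; its length sets K.
#' @param pleiotropy per-variant direct effects on disease (scalar recycled;
#'   default 0).
#' @param pleiotropy_aligned_to optional index name (or column number): the
#'   pleiotropic effects are made directional with respect to that index by
#'   multiplying them by the sign of the variant's effect on it, emulating
#'   unbalanced pleiotropy that a realigned Egger intercept should recover.
#' @param se_scales length-2 positive reals: typical SE of the index effects
#'   (`SEx`) and of the disease effects (`sey`).
#' @param bx_sd SD of the true index effects; `bx_corr` equicorrelation of
#'   effect columns across indices.
#' @param mhc_fraction fraction of variants placed inside the MHC region
#'   (chr6:20-40 Mb) for sensitivity-analysis tests.
#' @param seed integer seed.
#' @return an `mr_dataset`: list with `variants` (tibble: `variant_id`,
#'   `chrom`, `pos`, `mhc`, `known_disease`, `n_index_classes`), `Bx`, `SEx`
#'   (variants x K), `by`, `sey`, `index_names`, and `truth`
#'   (`theta`, `pleiotropy`).
#' @examples
#' d <- simulate_mr_summaries(100, c(PLT = 0.2, MCH = -0.1), seed = 1)
#' @export
simulate_mr_summaries <- function(n_variants, causal_theta,
                                  pleiotropy = 0,
                                  pleiotropy_aligned_to = NULL,
                                  se_scales = c(0.01, 0.02),
                                  bx_sd = 0.05, bx_corr = 0.2,
                                  mhc_fraction = 0, seed = 1L) {
  stop_if_not_scalar_count(n_variants, "n_variants")
  k <- length(causal_theta)
  if (k < 1) abort("`causal_theta` must name at least one index.")
  if (n_variants <= k) {
    abort(sprintf(
      "Rank deficiency: n_variants (%d) must exceed the number of indices (%d).",
      n_variants, k))
  }
  if (any(se_scales <= 0)) abort("`se_scales` must be positive.")
  idx_names <- names(causal_theta) %||% paste0("IDX", seq_len(k))
  withr::with_seed(seed, {
    sig <- matrix(bx_corr, k, k); diag(sig) <- 1
    z <- matrix(rnorm(n_variants * k), n_variants, k)
    bx <- z %*% chol(sig) * bx_sd
    sex <- matrix(abs(rnorm(n_variants * k, se_scales[1], se_scales[1] / 5)),
                  n_variants, k)
    sey <- abs(rnorm(n_variants, se_scales[2], se_scales[2] / 5))
    plei <- rep_len(pleiotropy, n_variants)
    if (!is.null(pleiotropy_aligned_to)) {
      ka <- if (is.character(pleiotropy_aligned_to))
        match(pleiotropy_aligned_to, idx_names) else pleiotropy_aligned_to
      if (is.na(ka)) abort("`pleiotropy_aligned_to` index not found.")
      sgn <- sign(bx[, ka]); sgn[sgn == 0] <- 1
      plei <- plei * sgn
    }
    by <- drop(bx %*% causal_theta) + plei + rnorm(n_variants, 0, sey)
    mhc <- runif(n_variants) < mhc_fraction
  })
  colnames(bx) <- colnames(sex) <- idx_names
  variants <- tibble(
    variant_id = sprintf("ins%04d", seq_len(n_variants)),
    chrom = ifelse(mhc, "6", "2"),
    pos = ifelse(mhc,
                 as.integer(seq(20e6, 40e6, length.out = n_variants)),
                 as.integer(seq(1e6, 200e6, length.out = n_variants))),
    mhc = mhc,
    known_disease = FALSE,
    n_index_classes = 1L
  )
  structure(list(variants = variants, Bx = bx, SEx = sex, by = by, sey = sey,
                 index_names = idx_names,
                 truth = list(theta = setNames(as.numeric(causal_theta),
                                               idx_names),
                              pleiotropy = plei)),
            class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("<mr_dataset> %d instruments x %d indices\n",
              nrow(x$Bx), ncol(x$Bx)))
  invisible(x)
}
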