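# Per-study additive association testing (OLS with covariates projected
# out), inclusion filters, genomic control and inverse-variance-weighted
# meta-analysis with double genomic control.

NULL_CHISQ_MEDIAN <- qchisq(0.5, df = 1)   # 0.4549364

#' Per-variant additive association scan
#'
#' Ordinary least squares of the (inverse-normal transformed) phenotype on
#' each variant's imputed allele dosage, with covariates (principal
#' components, centre dummies) projected out of both sides
#' (Frisch-Waugh-Lovell, exactly equivalent to the joint fit). Wald p-values
#' use the normal approximation, `p = 2 * pnorm(-|beta/se|)`.
#'
#' @param genotypes a `genotype_matrix` (or dosage matrix with variant ids as
#'   column names).
#' @param phenotype numeric vector, one value per sample; missing values drop
#'   the sample from the scan.
#' @param covariates optional data frame / matrix of covariates (an intercept
#'   is always included). Must be full rank.
#' @return a `study_sumstats` tibble: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `maf`, `info`, `n`.
#' @examples
#' g <- simulate_genotypes(500, 50, seed = 1)
#' y <- rnorm(500)
#' head(run_gwas(g, y))
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL) {
  if (inherits(genotypes, "genotype_matrix")) {
    dosage <- genotypes$dosage
    variants <- genotypes$variants
  } else {
    dosage <- as.matrix(genotypes)
    variants <- tibble(variant_id = colnames(dosage) %||%
                         paste0("var", seq_len(ncol(dosage))),
                       chrom = NA_character_, pos = NA_integer_,
                       effect_allele = NA_character_,
                       other_allele = NA_character_,
                       maf = pmin(colMeans(dosage) / 2,
                                  1 - colMeans(dosage) / 2),
                       info = NA_real_)
  }
  keep <- !is.na(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & complete.cases(covariates)
  }
  y <- phenotype[keep]
  g <- dosage[keep, , drop = FALSE]
  n <- length(y)
  if (is.null(covariates)) {
    x <- matrix(1, n, 1)
  } else {
    x <- stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("Covariates are rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  yr <- qr.resid(qx, y)
  gr <- qr.resid(qx, g)
  gg <- unname(colSums(gr^2))
  gy <- unname(drop(crossprod(gr, yr)))
  beta <- gy / gg
  df <- n - ncol(x) - 1
  rss <- sum(yr^2) - beta^2 * gg
  se <- sqrt(pmax(rss, 0) / df / gg)
  z <- beta / se
  out <- variants |>
    select(any_of(c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "maf", "info"))) |>
    mutate(beta = beta, se = se, p = 2 * pnorm(-abs(z)), n = n) |>
    relocate("beta", "se", "p", .after = "other_allele")
  class(out) <- c("study_sumstats", class(out))
  out
}

#' Meta-analysis inclusion filter
#'
#' A variant is retained iff, in every study, its MAF exceeds `maf_min`
#' (0.01%), its imputation info score exceeds `info_min` (0.4), and its
#' effect size and standard error are non-missing. Strict inequalities.
#'
#' @param stats_list list of per-study `study_sumstats` tibbles aligned on
#'   `variant_id`.
#' @param maf_min,info_min thresholds.
#' @return logical mask along the first study's variants.
#' @export
variant_inclusion_filter <- function(stats_list, maf_min = 1e-4,
                                     info_min = 0.4) {
  ids <- stats_list[[1]]$variant_id
  mask <- rep(TRUE, length(ids))
  for (st in stats_list) {
    st <- st[match(ids, st$variant_id), ]
    ok <- !is.na(st$variant_id) & !is.na(st$beta) & !is.na(st$se) &
      !is.na(st$maf) & st$maf > maf_min
    if (!all(is.na(st$info))) {        # info unavailable => condition waived
      ok <- ok & !is.na(st$info) & st$info > info_min
    }
    mask <- mask & ok
  }
  mask
}

#' Genomic-control inflation factor
#'
#' Ratio of the median observed association chi-square statistic,
#' `(beta/se)^2`, to the median of the chi-square(1) distribution (0.4549).
#'
#' @param stats a `study_sumstats` tibble (or numeric vector of z scores).
#' @return scalar lambda.
#' @export
gc_lambda <- function(stats) {
  z <- if (is.data.frame(stats)) stats$beta / stats$se else as.numeric(stats)
  z <- z[is.finite(z)]
  if (!length(z)) abort("No finite test statistics to estimate lambda from.")
  median(z^2) / NULL_CHISQ_MEDIAN
}

#' Apply genomic control to summary statistics
#'
#' Multiplies standard errors by `sqrt(max(lambda, 1))` (no deflation below
#' 1) and recomputes Wald p-values.
#'
#' @param stats a `study_sumstats`/meta tibble with `beta`, `se`.
#' @param lambda inflation factor; default estimated via [gc_lambda()].
#' @return the stats tibble with corrected `se` and `p`, and the applied
#'   lambda in attribute `"lambda"`.
#' @export
gc_correct <- function(stats, lambda = gc_lambda(stats)) {
  infl <- sqrt(max(lambda, 1))
  stats$se <- stats$se * infl
  stats$p <- 2 * pnorm(-abs(stats$beta / stats$se))
  attr(stats, "lambda") <- lambda
  stats
}

# harmonize a study's rows onto the reference effect alleles; returns the
# study tibble with flipped betas, or NA rows where unresolvable
.harmonize_alleles <- function(ref, st, ambiguous_maf = 0.4) {
  st <- st[match(ref$variant_id, st$variant_id), ]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  same <- !is.na(st$effect_allele) & st$effect_allele == ref$effect_allele &
    st$other_allele == ref$other_allele
  flipped <- !is.na(st$effect_allele) & st$effect_allele == ref$other_allele &
    st$other_allele == ref$effect_allele
  strand <- !same & !flipped & !is.na(st$effect_allele) &
    comp[st$effect_allele] == ref$effect_allele &
    comp[st$other_allele] == ref$other_allele
  strand_flip <- !same & !flipped & !is.na(st$effect_allele) &
    comp[st$effect_allele] == ref$other_allele &
    comp[st$other_allele] == ref$effect_allele
  ambiguous <- !is.na(st$effect_allele) &
    st$effect_allele == comp[st$other_allele] &
    !is.na(st$maf) & st$maf > ambiguous_maf
  if (any(ambiguous)) {
    warn(sprintf(
      "%d strand-ambiguous (A/T or C/G) variant(s) with MAF > %.2f dropped.",
      sum(ambiguous), ambiguous_maf))
  }
  st$beta[flipped | strand_flip] <- -st$beta[flipped | strand_flip]
  unresolved <- !(same | flipped | strand | strand_flip)
  drop <- (unresolved & !is.na(st$effect_allele)) | ambiguous
  st$beta[drop] <- NA_real_
  st$se[drop] <- NA_real_
  st
}

#' Inverse-variance-weighted meta-analysis with double genomic control
#'
#' Harmonizes study effect alleles to the first study, applies the inclusion
#' filter, applies per-study genomic control (standard errors inflated by
#' `sqrt(max(lambda, 1))`), pools with inverse-variance weights
#' (`beta = sum(w_i b_i) / sum(w_i)`, `w = 1/se^2`,
#' `se = 1/sqrt(sum(w_i))`), then applies a second genomic-control pass to
#' the pooled statistics and computes Wald p-values.
#'
#' @param stats_list list of per-study `study_sumstats` tibbles (typically
#'   three).
#' @param apply_gc apply the double genomic control (default `TRUE`).
#' @param maf_min,info_min inclusion-filter thresholds.
#' @param alpha genome-wide significance level used for the `significant`
#'   flag (default 8.31e-9).
#' @return a `meta_sumstats` tibble: variant metadata, pooled `beta`, `se`,
#'   `p`, `significant`, `included`, and per-study `beta_s<i>` / `se_s<i>`
#'   columns (GC-corrected, retained for heterogeneity scoring). Attributes
#'   `lambda_pre` (per study) and `lambda_meta` carry the inflation factors.
#' @export
ivw_meta <- function(stats_list, apply_gc = TRUE, maf_min = 1e-4,
                     info_min = 0.4, alpha = 8.31e-9) {
  stopifnot(length(stats_list) >= 2)
  ref <- stats_list[[1]]
  harmonized <- c(list(ref),
                  lapply(stats_list[-1], .harmonize_alleles, ref = ref))
  included <- variant_inclusion_filter(harmonized, maf_min, info_min)
  lambda_pre <- vapply(harmonized, function(st) {
    if (!any(included)) NA_real_ else gc_lambda(st[included, ])
  }, numeric(1))
  if (apply_gc && !any(included)) {
    warn("No variant passes the inclusion filter; genomic control skipped.")
    apply_gc <- FALSE
  }
  if (apply_gc) {
    harmonized <- purrr::map2(harmonized, lambda_pre,
                              function(st, l) gc_correct(st, l))
  }
  bmat <- do.call(cbind, lapply(harmonized, function(st) st$beta))
  smat <- do.call(cbind, lapply(harmonized, function(st) st$se))
  w <- 1 / smat^2
  beta <- rowSums(bmat * w) / rowSums(w)
  se <- 1 / sqrt(rowSums(w))
  out <- ref |>
    select(any_of(c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "maf", "info"))) |>
    mutate(beta = beta, se = se,
           p = 2 * pnorm(-abs(beta / se)), included = included)
  lambda_meta <- if (!any(included)) NA_real_ else gc_lambda(out[included, ])
  if (apply_gc) out <- gc_correct(out, lambda_meta)
  out$significant <- out$included & !is.na(out$p) & out$p < alpha
  for (i in seq_along(harmonized)) {
    out[[paste0("beta_s", i)]] <- bmat[, i]
    out[[paste0("se_s", i)]] <- smat[, i]
  }
  attr(out, "lambda_pre") <- lambda_pre
  attr(out, "lambda_meta") <- lambda_meta
  class(out) <- c("meta_sumstats", class(out))
  out
}

#' Minimum detectable per-allele effect
#'
#' Converts a trait-variance fraction to the per-allele additive effect at a
#' given allele frequency via `beta = sqrt(R2 / (2 p (1 - p)))` (SD units).
#'
#' @param r2 trait-variance fraction, in (0, 1).
#' @param maf minor allele frequency, in (0, 0.5].
#' @return effect size in phenotype SD units.
#' @examples
#' min_detectable_effect(0.000265, 0.5)    # ~0.023 SD
#' min_detectable_effect(0.000265, 1e-4)   # ~1.15 SD
#' @export
min_detectable_effect <- function(r2, maf) {
  if (any(r2 <= 0 | r2 >= 1)) abort("`r2` must be in (0, 1).")
  if (any(maf <= 0 | maf > 0.5)) abort("`maf` must be in (0, 0.5].")
  sqrt(r2 / (2 * maf * (1 - maf)))
}

#' Trait-variance fraction detectable at given power
#'
#' Solves, via the non-central chi-square(1) distribution, for the variance
#' fraction R2 such that a Wald test at level `alpha` on `n` samples attains
#' the requested power; the non-centrality is `n * R2 / (1 - R2)`.
#'
#' @param n sample size.
#' @param alpha test level.
#' @param power target power.
#' @return the detectable variance fraction.
#' @export
min_detectable_r2 <- function(n, alpha = 8.31e-9, power = 0.8) {
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  f <- function(ncp) pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE) - power
  ncp <- stats::uniroot(f, c(1e-6, 1e4))$root
  ncp / (n + ncp)
}
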