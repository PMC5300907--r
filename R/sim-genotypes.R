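# Synthetic genotype matrices: LD blocks via a shared latent Gaussian factor
# per haplotype copy, thresholded to allele indicators so margins are exactly
# Bernoulli(MAF).

#' Simulate a genotype dosage matrix with LD blocks
#'
#' Variants are laid out along one chromosome at regular spacing and grouped
#' into consecutive LD blocks of `ld_block_size` variants. For each of the two
#' haplotype copies of each sample, a block-level latent Gaussian factor is
#' shared across the block's variants with loading `sqrt(block_rho)`; each
#' allele indicator is the latent value thresholded at the allele-frequency
#' quantile, so marginal frequencies match the target spectrum exactly and
#' within-block dosage correlation is controlled by `block_rho`. Blocks are
#' independent, so `ld_block_size = 1` gives independent variants.
#'
#' @param n_samples,n_variants dimensions.
#' @param maf_spectrum target minor-allele-frequency distribution, one of
#'   `list(type = "uniform", min =, max =)`,
#'   `list(type = "beta", shape1 =, shape2 =, min =, max =)` (samples are
#'   rescaled into `[min, max]`), or `list(type = "fixed", maf =)` (recycled).
#'   Bounds must satisfy `0 < min <= max <= 0.5`.
#' @param ld_block_size variants per LD block (last block may be shorter).
#' @param block_rho latent-factor loading controlling within-block LD; the
#'   dosage correlation between two common variants in a block is close to
#'   (slightly below) `block_rho`.
#' @param chrom chromosome label; `spacing_bp` distance between variants.
#' @param info_range range of simulated imputation info scores.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a `genotype_matrix`: list with `dosage` (samples x variants,
#'   values in \[0, 2\]), `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf` (empirical, folded), `maf_target`,
#'   `info`, `block`), `sample_ids`.
#' @examples
#' g <- simulate_genotypes(100, 20, ld_block_size = 5, seed = 1)
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_spectrum = list(type = "uniform",
                                                   min = 0.01, max = 0.5),
                               ld_block_size = 10, block_rho = 0.9,
                               chrom = "1", spacing_bp = 25000L,
                               info_range = c(0.85, 1), seed = 1L) {
  stop_if_not_scalar_count(n_samples, "n_samples")
  stop_if_not_scalar_count(n_variants, "n_variants")
  stop_if_not_scalar_count(ld_block_size, "ld_block_size")
  if (block_rho < 0 || block_rho >= 1) abort("`block_rho` must be in [0, 1).")
  withr::with_seed(seed, {
    maf <- .draw_maf(maf_spectrum, n_variants)
    blocks <- rep(seq_len(ceiling(n_variants / ld_block_size)),
                  each = ld_block_size)[seq_len(n_variants)]
    dosage <- matrix(0L, n_samples, n_variants)
    for (copy in 1:2) {
      for (b in unique(blocks)) {
        j <- which(blocks == b)
        u <- rnorm(n_samples)
        z <- sqrt(block_rho) * u +
          matrix(rnorm(n_samples * length(j)), n_samples) * sqrt(1 - block_rho)
        thr <- qnorm(maf[j])
        dosage[, j] <- dosage[, j] + (z < rep(thr, each = n_samples))
      }
    }
    info <- runif(n_variants, info_range[1], info_range[2])
  })
  storage.mode(dosage) <- "double"
  ids <- sprintf("var%04d", seq_len(n_variants))
  dimnames(dosage) <- list(sprintf("S%05d", seq_len(n_samples)), ids)
  emp <- unname(colMeans(dosage) / 2)
  emp_folded <- pmin(pmax(emp, 0.5 / (2 * n_samples)), 1 - 0.5 / (2 * n_samples))
  emp_folded <- pmin(emp_folded, 1 - emp_folded)
  variants <- tibble(
    variant_id = ids, chrom = chrom,
    pos = as.integer(seq_len(n_variants)) * as.integer(spacing_bp),
    effect_allele = "A", other_allele = "G",
    maf = emp_folded, maf_target = maf, info = info, block = blocks
  )
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = rownames(dosage)),
            class = "genotype_matrix")
}

.draw_maf <- function(spec, n) {
  type <- spec$type %||% "uniform"
  out <- switch(type,
    uniform = {
      lo <- spec$min %||% 0.01; hi <- spec$max %||% 0.5
      .check_maf_bounds(lo, hi)
      runif(n, lo, hi)
    },
    beta = {
      lo <- spec$min %||% 0.001; hi <- spec$max %||% 0.5
      .check_maf_bounds(lo, hi)
      lo + (hi - lo) * stats::rbeta(n, spec$shape1 %||% 0.5, spec$shape2 %||% 2)
    },
    fixed = {
      maf <- rep_len(spec$maf, n)
      .check_maf_bounds(min(maf), max(maf))
      maf
    },
    abort(sprintf("Unknown maf_spectrum type '%s'.", type))
  )
  out
}

.check_maf_bounds <- function(lo, hi) {
  if (!(lo > 0 && hi <= 0.5 && lo <= hi)) {
    abort("MAF spectrum bounds must satisfy 0 < min <= max <= 0.5.")
  }
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants, %d LD block(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$block))))
  invisible(x)
}

#' Pairwise dosage r-squared
#'
#' Squared Pearson correlation of dosages for the given variants, the LD
#' measure used for clumping.
#'
#' @param genotypes a `genotype_matrix`.
#' @param variant_ids subset of variant ids (default all).
#' @return symmetric matrix of r-squared values.
#' @export
dosage_r2 <- function(genotypes, variant_ids = NULL) {
  d <- genotypes$dosage
  if (!is.null(variant_ids)) d <- d[, variant_ids, drop = FALSE]
  cor(d)^2
}

#' Write / read a genotype matrix as a TSV dosage table
#'
#' Long-free wide layout: variant metadata columns then one dosage column per
#' sample.
#'
#' @param genotypes a `genotype_matrix`; `path` file path.
#' @return `write_genotypes_tsv` returns `path` invisibly;
#'   `read_genotypes_tsv` returns a `genotype_matrix`.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  meta <- genotypes$variants
  tab <- bind_cols(meta, as_tibble(t(genotypes$dosage)))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "maf", "maf_target", "info", "block")
  meta_cols <- intersect(meta_cols, names(tab))
  meta <- tab[meta_cols]
  dosage <- t(as.matrix(tab[setdiff(names(tab), meta_cols)]))
  colnames(dosage) <- meta$variant_id
  meta$chrom <- as.character(meta$chrom)
  structure(list(dosage = dosage, variants = as_tibble(meta),
                 sample_ids = rownames(dosage)),
            class = "genotype_matrix")
}

#' Write / read genotype dosages as VCF (DS FORMAT field)
#'
#' Minimal VCFv4.2 with a per-sample `DS` (dosage) field, readable by
#' standard tools. Reading uses the VariantAnnotation package when available.
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed allele dosage\">",
    sprintf("##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS",
            sprintf("INFO=%.4f", v$info[j]), "DS",
            sprintf("%.3f", genotypes$dosage[, j])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("read_genotypes_vcf() needs the VariantAnnotation package.")
  }
  vcf <- VariantAnnotation::readVcf(path)
  ds <- VariantAnnotation::geno(vcf)$DS
  dosage <- t(apply(ds, c(1, 2), as.numeric))
  rd <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)$INFO
  n <- nrow(dosage)
  variants <- tibble(
    variant_id = colnames(dosage),
    chrom = as.character(GenomicRanges::seqnames(rd)),
    pos = GenomicRanges::start(rd),
    effect_allele = as.character(unlist(rd$ALT)),
    other_allele = as.character(rd$REF),
    maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2),
    info = if (is.null(info)) NA_real_ else as.numeric(info)
  )
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = rownames(dosage)),
            class = "genotype_matrix")
}
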