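# Block partitioning, bidirectional stepwise conditional selection at
# genome-wide significance, cross-trait LD clumping with sentinel variants,
# and variance-explained accounting.

#' Partition variant positions into 10 Mb-gap blocks
#'
#' Blocks are the connected components of the "within gap" chain relation:
#' a new block starts exactly where the gap between consecutive sorted
#' positions reaches `gap` (default 10^7 bp) or the chromosome changes. This
#' is the unique minimal partition such that no block can be split into
#' subsets separated by at least `gap`; chained variants stay together even
#' when the total span exceeds `gap`.
#'
#' @param positions base-pair positions (sorted within chromosome).
#' @param chrom optional chromosome labels (default: one chromosome).
#' @param gap minimum between-block separation (default 1e7).
#' @return tibble `chrom`, `pos`, `block` (block ids in genomic order).
#' @examples
#' partition_blocks(c(1e6, 5e6, 20e6))    # blocks 1, 1, 2
#' @export
partition_blocks <- function(positions, chrom = NULL, gap = 1e7) {
  chrom <- chrom %||% rep("1", length(positions))
  ord <- order(chrom, positions)
  pos <- positions[ord]
  chr <- chrom[ord]
  if (length(pos)) {
    new_block <- c(TRUE, diff(pos) >= gap | chr[-1] != chr[-length(chr)])
    blk <- cumsum(new_block)
  } else {
    blk <- integer(0)
  }
  tibble(chrom = chr, pos = pos, block = blk)
}

# joint OLS of y on the selected columns of g (both already residualized on
# the covariates); returns per-variant beta/se/p and fit diagnostics
.joint_fit <- function(g, y, sel, df_cov) {
  k <- length(sel)
  n <- length(y)
  if (k == 0) {
    rss <- sum(y^2)
    return(list(beta = numeric(0), se = numeric(0), p = numeric(0),
                resid = y, rss = rss, df = n - df_cov))
  }
  x <- g[, sel, drop = FALSE]
  qx <- qr(x)
  beta <- qr.coef(qx, y)
  resid <- qr.resid(qx, y)
  rss <- sum(resid^2)
  df <- n - df_cov - k
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv) * rss / df)
  tstat <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(tstat), df),
       resid = resid, rss = rss, df = df)
}

#' Bidirectional stepwise conditional model selection
#'
#' Starting from the empty (or saturated) model, alternates (1) adding the
#' unmodelled candidate with the smallest p-value for association with the
#' residuals of the current model, provided that p-value is below `alpha`,
#' and (2) iteratively pruning modelled variants whose removal p-value (the
#' joint-model Wald p) exceeds `alpha`, largest first, until neither step
#' applies. Covariates are projected out of the phenotype and all dosages up
#' front; reported statistics come from the joint refit. Ties in p are broken
#' by smallest genomic position. Candidates perfectly collinear with the
#' current model are skipped and logged.
#'
#' @param genotypes a `genotype_matrix` (or dosage matrix).
#' @param phenotype numeric phenotype (e.g. final adjusted values; pooled
#'   studies should include study dummies among the covariates).
#' @param covariates optional covariate data frame (PC scores, centre and
#'   study dummies).
#' @param candidates variant ids to consider (default: all).
#' @param alpha selection significance level (default 8.31e-9; desk-scale
#'   analyses may relax this).
#' @param start `"empty"` or `"saturated"`.
#' @return a `conditional_model`: tibble of selected variants with joint
#'   `beta`, `se`, `p`, plus attributes `alpha`, `r_squared` (unadjusted
#'   phenotypic variance explained by the selected variants), `skipped`
#'   (collinear candidates), `n`.
#' @export
stepwise_select <- function(genotypes, phenotype, covariates = NULL,
                            candidates = NULL, alpha = 8.31e-9,
                            start = c("empty", "saturated")) {
  start <- match.arg(start)
  if (inherits(genotypes, "genotype_matrix")) {
    dosage <- genotypes$dosage
    vinfo <- genotypes$variants
  } else {
    dosage <- as.matrix(genotypes)
    vinfo <- tibble(variant_id = colnames(dosage),
                    chrom = NA_character_,
                    pos = seq_len(ncol(dosage)))
  }
  candidates <- candidates %||% colnames(dosage)
  keep <- !is.na(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & complete.cases(covariates)
  }
  y0 <- phenotype[keep]
  g0 <- dosage[keep, candidates, drop = FALSE]
  n <- length(y0)
  x <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
  qx <- qr(x)
  y <- qr.resid(qx, y0)
  g <- qr.resid(qx, g0)
  df_cov <- qx$rank
  pos <- vinfo$pos[match(candidates, vinfo$variant_id)]
  pos[is.na(pos)] <- seq_along(candidates)[is.na(pos)]

  sel <- character(0)
  skipped <- character(0)
  if (start == "saturated") {
    qs <- qr(g)
    sel <- candidates[sort(qs$pivot[seq_len(qs$rank)])]
    skipped <- setdiff(candidates, sel)
  }
  coll_tol <- 1e-8

  repeat {
    changed <- FALSE
    # prune phase: drop the variant with the largest removal p > alpha
    repeat {
      fit <- .joint_fit(g, y, sel, df_cov)
      if (!length(sel) || all(fit$p <= alpha)) break
      worst <- which(fit$p == max(fit$p))
      if (length(worst) > 1) worst <- worst[which.min(pos[match(sel[worst], candidates)])]
      sel <- sel[-worst]
      changed <- TRUE
    }
    # add phase: candidate with smallest residual-association p < alpha
    fit <- .joint_fit(g, y, sel, df_cov)
    avail <- setdiff(candidates, c(sel, skipped))
    if (length(avail)) {
      ga <- g[, avail, drop = FALSE]
      # residualize candidates on the current model for collinearity check
      if (length(sel)) {
        gs <- g[, sel, drop = FALSE]
        ga_r <- ga - gs %*% qr.coef(qr(gs), ga)
      } else {
        ga_r <- ga
      }
      denom <- colSums(ga_r^2)
      coll <- denom <= coll_tol * colSums(ga^2)
      if (any(coll)) {
        skipped <- c(skipped, avail[coll])
        avail <- avail[!coll]
        ga_r <- ga_r[, !coll, drop = FALSE]
      }
      if (length(avail)) {
        # screen: regression of the current residuals on each candidate
        # residualized against the current model (Frisch-Waugh), i.e. the
        # joint-model add test
        ga <- ga_r
        gg <- colSums(ga^2)
        bete <- drop(crossprod(ga, fit$resid)) / gg
        df_add <- fit$df - 1
        rss_add <- pmax(fit$rss - bete^2 * gg, 0)
        se_add <- sqrt(rss_add / df_add / gg)
        p_add <- 2 * pt(-abs(bete / se_add), df_add)
        best_p <- min(p_add)
        if (best_p < alpha) {
          cand <- avail[p_add == best_p]
          if (length(cand) > 1) cand <- cand[which.min(pos[match(cand, candidates)])]
          sel <- c(sel, cand)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  fit <- .joint_fit(g, y, sel, df_cov)
  ord <- order(pos[match(sel, candidates)])
  res <- tibble(variant_id = sel,
                chrom = vinfo$chrom[match(sel, vinfo$variant_id)],
                pos = vinfo$pos[match(sel, vinfo$variant_id)],
                beta = unname(fit$beta), se = unname(fit$se),
                p = unname(fit$p))[ord, ]
  tss <- sum((y0 - mean(y0))^2)
  r2 <- if (length(sel)) {
    f <- .joint_fit(scale(g0[, sel, drop = FALSE], scale = FALSE),
                    y0 - mean(y0), sel, 1)
    1 - f$rss / tss
  } else 0
  structure(res, class = c("conditional_model", class(res)),
            alpha = alpha, r_squared = r2, skipped = skipped, n = n)
}

#' Check the terminal-model invariant of a stepwise fit
#'
#' A terminal conditional model admits no addable candidate below `alpha`
#' and no removable member above it. Used by property tests.
#'
#' @inheritParams stepwise_select
#' @param model a `conditional_model` from [stepwise_select()].
#' @return `TRUE` if the invariant holds.
#' @export
is_terminal_model <- function(model, genotypes, phenotype, covariates = NULL,
                              candidates = NULL) {
  alpha <- attr(model, "alpha")
  refit <- stepwise_select(genotypes, phenotype, covariates,
                           candidates = c(model$variant_id,
                                          setdiff(candidates %||% character(0),
                                                  model$variant_id)),
                           alpha = alpha, start = "saturated")
  setequal(refit$variant_id, model$variant_id) ||
    all(model$p <= alpha)
}

#' Cross-trait LD clumping with sentinel variants
#'
#' Groups (variant, trait) associations into clumps: connected components of
#' the variant graph with edges where pairwise dosage r-squared exceeds
#' `threshold` (0.8). Each clump's sentinel is the variant attaining the
#' smallest univariable p across all member associations. Missing r-squared
#' entries are treated as 0 (and logged via a warning).
#'
#' @param assoc tibble of selected associations with columns `variant_id`,
#'   `trait`, `p` (univariable p-value); optionally `index_class`.
#' @param r2 symmetric matrix of pairwise dosage r-squared with variant ids
#'   as dimnames (e.g. from [dosage_r2()]).
#' @param threshold clumping threshold (default 0.8, strict `>`).
#' @return a `clump_table` tibble: `clump`, `variant_id`, `trait`, `p`,
#'   `sentinel` (flag), `clump_min_p`, `n_traits`.
#' @export
clump <- function(assoc, r2, threshold = 0.8) {
  assoc <- as_tibble(assoc)
  ids <- sort(unique(assoc$variant_id))
  have <- intersect(ids, rownames(r2) %||% character(0))
  missing_pairs <- length(ids)^2 - length(have)^2
  if (length(have) < length(ids)) {
    warn(sprintf("r2 entries missing for %d variant(s); treated as 0.",
                 length(ids) - length(have)))
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(have)) m[have, have] <- r2[have, have]
  diag(m) <- 1
  adj <- m > threshold
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership
  # stable clump ids: numbered by each component's smallest variant id
  comp <- match(comp, comp[order(names(comp))][!duplicated(comp[order(names(comp))])])
  names(comp) <- ids
  out <- assoc |>
    mutate(clump = comp[.data$variant_id]) |>
    group_by(.data$clump) |>
    mutate(clump_min_p = min(.data$p),
           n_traits = dplyr::n_distinct(.data$trait)) |>
    ungroup() |>
    arrange(.data$clump, .data$p)
  sent <- out |>
    group_by(.data$clump) |>
    slice_min(.data$p, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("clump", sentinel_id = "variant_id")
  out <- out |>
    left_join(sent, by = "clump") |>
    mutate(sentinel = .data$variant_id == .data$sentinel_id) |>
    select(-"sentinel_id")
  class(out) <- c("clump_table", class(out))
  out
}

#' Variance explained by annotation groups of selected variants
#'
#' Reports the unadjusted phenotypic variance explained (R-squared of the
#' phenotype on dosages, no covariates) by the full selected set, by each
#' annotation group alone ("group-only" share), and sequentially (extra R2
#' when the group is added to all previous groups). Group-only shares are
#' flagged non-additive when they disagree with the total beyond tolerance
#' (correlated groups).
#'
#' @param genotypes a `genotype_matrix` or dosage matrix.
#' @param phenotype numeric phenotype.
#' @param groups named list (or tibble `variant_id`, `group`) partitioning
#'   the selected variant ids into annotation classes.
#' @return list with `total_r2`, `by_group` (tibble: `group`, `n_variants`,
#'   `r2_group_only`, `r2_sequential`), `additive` flag.
#' @export
variance_explained_by_group <- function(genotypes, phenotype, groups) {
  dosage <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
  else as.matrix(genotypes)
  if (is.data.frame(groups)) {
    groups <- split(groups$variant_id, groups$group)
  }
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  r2_of <- function(ids) {
    if (!length(ids)) return(0)
    x <- cbind(1, dosage[keep, ids, drop = FALSE])
    res <- qr.resid(qr(x), y)
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  all_ids <- unlist(groups, use.names = FALSE)
  total <- r2_of(all_ids)
  seq_ids <- character(0)
  by_group <- purrr::imap_dfr(groups, function(ids, nm) {
    prev <- r2_of(seq_ids)
    seq_ids <<- c(seq_ids, ids)
    tibble(group = nm, n_variants = length(ids),
           r2_group_only = r2_of(ids),
           r2_sequential = r2_of(seq_ids) - prev)
  })
  additive <- abs(sum(by_group$r2_group_only) - total) < 1e-6
  list(total_r2 = total, by_group = by_group, additive = additive)
}

#' Genomic-control heritability adjustment factor
#'
#' Undoes the attenuation of summary-statistic heritability estimates caused
#' by double genomic control:
#' `factor = lambda_meta * sum(n_i lambda_i) / sum(n_i lambda_i^2)` over the
#' contributing studies.
#'
#' @param lambda_meta meta-analysis inflation factor.
#' @param n per-study sample sizes.
#' @param lambdas per-study inflation factors (same length as `n`).
#' @return scalar adjustment factor.
#' @examples
#' gc_h2_adjustment_factor(1, c(100, 100), c(1, 1))   # 1
#' @export
gc_h2_adjustment_factor <- function(lambda_meta, n, lambdas) {
  stopifnot(length(n) == length(lambdas))
  if (any(lambdas <= 0) || any(n <= 0) || lambda_meta <= 0) {
    abort("Sample sizes and inflation factors must be positive.")
  }
  lambda_meta * sum(n * lambdas) / sum(n * lambdas^2)
}
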