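# Cross-study effect-size heterogeneity: standardized distance from the
# three-study effect vector to a double-pyramid (double-cone) tolerance
# region with faces normal to n1 = (1, -1/4, -1/4) and its permutations.

.pyramid_normals <- function() {
  rbind(c(1, -0.25, -0.25),
        c(-0.25, 1, -0.25),
        c(-0.25, -0.25, 1))
}

#' Does a three-study effect vector lie in the tolerance double-pyramid?
#'
#' The region is the union of the cone `{x : n_i . x >= 0 for all i}` and its
#' negation, with normals `n1 = (1, -1/4, -1/4)`, `n2 = (-1/4, 1, -1/4)`,
#' `n3 = (-1/4, -1/4, 1)`: directionally concordant effect vectors whose
#' coordinates are not too disparate.
#'
#' @param betas numeric 3-vector (or 3-column matrix, row-wise).
#' @param tol feasibility tolerance.
#' @return logical (vector).
#' @examples
#' pyramid_contains(c(1, 1, 1))   # TRUE
#' pyramid_contains(c(1, 0, 0))   # FALSE
#' @export
pyramid_contains <- function(betas, tol = 1e-12) {
  b <- if (is.matrix(betas)) betas else matrix(betas, nrow = 1)
  stopifnot(ncol(b) == 3)
  s <- b %*% t(.pyramid_normals())
  drop(apply(s >= -tol, 1, all) | apply(s <= tol, 1, all))
}

# squared SE-standardized distance from beta to the single cone {N x >= 0},
# by enumerating the cone's faces and edges in whitened coordinates
.dist2_to_cone <- function(b_w, a, tol = 1e-9) {
  if (all(a %*% b_w >= -tol)) return(0)
  best <- sum(b_w^2)                     # vertex (origin) always feasible
  for (i in 1:3) {                       # single active face
    ai <- a[i, ]
    u <- b_w - ai * sum(ai * b_w) / sum(ai^2)
    if (all(a %*% u >= -tol)) best <- min(best, sum((b_w - u)^2))
  }
  cross3 <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                             x[3] * y[1] - x[1] * y[3],
                             x[1] * y[2] - x[2] * y[1])
  for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {  # edges: two active faces
    v <- cross3(a[ij[1], ], a[ij[2], ])
    u <- v * sum(v * b_w) / sum(v^2)
    if (all(a %*% u >= -tol)) best <- min(best, sum((b_w - u)^2))
  }
  best
}

#' Double-pyramid heterogeneity score
#'
#' Zero when the effect vector lies in the tolerance region; otherwise the
#' SE-standardized Euclidean distance (diagonal covariance) from the vector
#' to the nearest point of the region,
#' `sqrt(min over x in region of sum_i (beta_i - x_i)^2 / se_i^2)` --
#' the radius of the smallest confidence ellipsoid touching the region. The
#' minimization is solved exactly by enumerating the cone's faces and edges
#' in SE-whitened coordinates. Scores above `threshold` (5.2) fail the
#' filter.
#'
#' @param betas 3-vector or 3-column matrix of per-study effects.
#' @param ses matching positive standard errors.
#' @return numeric score (vectorized over rows).
#' @examples
#' het_score(c(1, 0, 0), c(1, 1, 1))   # sqrt(2/11)
#' @export
het_score <- function(betas, ses) {
  b <- if (is.matrix(betas)) betas else matrix(betas, nrow = 1)
  s <- if (is.matrix(ses)) ses else matrix(ses, nrow = 1, ncol = 3)
  if (ncol(s) != 3 && length(s) == nrow(b) * 3) s <- matrix(s, ncol = 3)
  if (any(!is.na(s) & s <= 0)) abort("Standard errors must be positive.")
  n <- .pyramid_normals()
  vapply(seq_len(nrow(b)), function(i) {
    bi <- b[i, ]; si <- s[i, ]
    if (any(is.na(bi)) || any(is.na(si))) return(NA_real_)
    # whiten: u = x / se turns the metric Euclidean; the cone constraint
    # N x >= 0 becomes A u >= 0 with A = N diag(se)
    a <- n %*% diag(si)
    bw <- bi / si
    sqrt(min(.dist2_to_cone(bw, a), .dist2_to_cone(-bw, a)))
  }, numeric(1))
}

#' Add heterogeneity score and pass flag to a meta table
#'
#' Computes [het_score()] from the retained per-study effect/SE columns of an
#' [ivw_meta()] result and flags variant-index pairs with score above
#' `threshold` (5.2) for removal.
#'
#' @param meta a `meta_sumstats` tibble with `beta_s1..3`, `se_s1..3`.
#' @param threshold filter threshold (default 5.2).
#' @return the tibble with `het_score` and `het_pass` columns added.
#' @export
het_filter <- function(meta, threshold = 5.2) {
  b <- as.matrix(meta[paste0("beta_s", 1:3)])
  s <- as.matrix(meta[paste0("se_s", 1:3)])
  meta$het_score <- het_score(b, s)
  meta$het_pass <- !is.na(meta$het_score) & meta$het_score <= threshold
  meta
}
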