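# Independent oracles used by property tests. These deliberately avoid the
# implementation's algorithms (face/edge enumeration, rank screening, ...).

# Heterogeneity score via Dykstra's alternating projection onto the three
# half-spaces of each cone, in SE-whitened coordinates. Converges to the
# exact Euclidean projection onto the polyhedral cone.
dykstra_het_score <- function(beta, se, iters = 400) {
  n <- rbind(c(1, -0.25, -0.25), c(-0.25, 1, -0.25), c(-0.25, -0.25, 1))
  a <- n %*% diag(se)                      # constraint rows in u = x/se space
  proj_half <- function(u, ai) {           # projection onto {ai . u >= 0}
    s <- sum(ai * u)
    if (s >= 0) u else u - ai * s / sum(ai^2)
  }
  dist_cone <- function(b) {
    u <- b
    inc <- vector("list", 3)
    for (j in 1:3) inc[[j]] <- rep(0, 3)
    for (it in seq_len(iters)) {
      for (j in 1:3) {
        v <- u + inc[[j]]
        u_new <- proj_half(v, a[j, ])
        inc[[j]] <- v - u_new
        u <- u_new
      }
    }
    sqrt(sum((b - u)^2))
  }
  bw <- beta / se
  min(dist_cone(bw), dist_cone(-bw))
}

# marginal thresholding: variants whose simple-regression p (after the same
# covariate projection) is below alpha
marginal_select <- function(g, y, alpha) {
  n <- length(y)
  ps <- apply(g, 2, function(x) {
    f <- summary(stats::lm(y ~ x))
    f$coefficients[2, 4]
  })
  colnames(g)[ps < alpha]
}

# independent stepwise implementation using lm() refits at every step
# (usable only for small candidate sets)
stepwise_oracle <- function(d, y, alpha) {
  sel <- character(0)
  repeat {
    changed <- FALSE
    while (length(sel)) {
      p <- summary(lm(y ~ d[, sel, drop = FALSE]))$coefficients[-1, 4]
      if (max(p) > alpha) {
        sel <- sel[-which.max(p)]
        changed <- TRUE
      } else break
    }
    avail <- setdiff(colnames(d), sel)
    if (length(avail)) {
      padd <- vapply(avail, function(j) {
        cf <- summary(lm(y ~ d[, c(sel, j), drop = FALSE]))$coefficients
        cf[nrow(cf), 4]
      }, numeric(1))
      if (min(padd) < alpha) {
        sel <- c(sel, avail[which.min(padd)])
        changed <- TRUE
      }
    }
    if (!changed) return(sort(sel))
  }
}

# P(both conditional Wald tests pass) for two equal planted effects with
# genotype correlation r, via the bivariate normal of the two z statistics
both_pass_power <- function(beta, maf, n, r, alpha) {
  mu <- beta * sqrt(n * 2 * maf * (1 - maf) * (1 - r^2))
  thr <- qnorm(alpha / 2, lower.tail = FALSE)
  rho <- -r                                  # cov of joint OLS coefficients
  # z2 | z1 = mu + u is N(mu + rho u, 1 - rho^2); integrate over u = z1 - mu
  integrand <- function(u) {
    dnorm(u) * pnorm(((mu + rho * u) - thr) / sqrt(1 - rho^2))
  }
  integrate(integrand, thr - mu, Inf)$value
}

# direct normal-scores computation for one stratum
normal_scores_oracle <- function(x) {
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.5) / length(x))
}

# brute-force confusion-count imputation metrics
accuracy_oracle <- function(imp, tru) {
  conc_num <- 0; conc_den <- 0; prec_num <- 0; prec_den <- 0
  for (i in seq_len(nrow(imp))) {
    for (j in seq_len(ncol(imp))) {
      ti <- tru[i, j]; im <- imp[i, j]
      if (ti != 0) {
        conc_den <- conc_den + 1
        if (im == ti) conc_num <- conc_num + 1
      }
      if (im != 0) {
        prec_den <- prec_den + 1
        if (im == ti) prec_num <- prec_num + 1
      }
    }
  }
  c(concordance = if (conc_den) conc_num / conc_den else NA_real_,
    precision = if (prec_den) prec_num / prec_den else NA_real_)
}

# small per-study summary-stats table for meta tests
make_sumstats <- function(beta, se, variant_id = paste0("v", seq_along(beta)),
                          maf = 0.3, info = 0.99, n = 1000,
                          effect_allele = "A", other_allele = "G") {
  tibble::tibble(variant_id = variant_id, chrom = "1",
                 pos = seq_along(beta) * 1000L,
                 effect_allele = effect_allele, other_allele = other_allele,
                 beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
                 maf = maf, info = info, n = n)
}
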