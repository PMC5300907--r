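test_that("single-variant scan equals the textbook simple regression", {
  withr::with_seed(41, {
    g <- matrix(rbinom(300, 2, 0.3), ncol = 1,
                dimnames = list(NULL, "v1"))
    y <- 0.2 * g[, 1] + rnorm(300)
  })
  ss <- run_gwas(g, y)
  ref <- summary(lm(y ~ g[, 1]))$coefficients
  expect_equal(ss$beta, ref[2, 1])
  expect_equal(ss$se, ref[2, 2])
  expect_equal(ss$p, 2 * pnorm(-abs(ss$beta / ss$se)))
})

test_that("covariates are projected out exactly (Frisch-Waugh)", {
  withr::with_seed(42, {
    g <- simulate_genotypes(400, 5, seed = 1)
    cov <- data.frame(pc1 = rnorm(400), center = sample(c("a", "b"), 400,
                                                        replace = TRUE))
    y <- 0.3 * g$dosage[, 2] + 0.5 * cov$pc1 + rnorm(400)
  })
  ss <- run_gwas(g, y, cov)
  ref <- summary(lm(y ~ g$dosage[, 2] + cov$pc1 + cov$center))$coefficients
  expect_equal(ss$beta[2], ref[2, 1])
  expect_equal(ss$se[2], ref[2, 2], tolerance = 1e-12)
  # rank-deficient covariates are refused with the collinear column named
  cov$dup <- cov$pc1
  expect_error(run_gwas(g, y, cov), "dup")
})

test_that("null genome scans are calibrated (lambda near 1)", {
  g <- simulate_genotypes(2000, 5000, ld_block_size = 1, seed = 43)
  withr::with_seed(44, y <- rnorm(2000))
  ss <- run_gwas(g, y)
  expect_gt(gc_lambda(ss), 0.95)
  expect_lt(gc_lambda(ss), 1.05)
})

test_that("planted effects are estimated with near-nominal 2-SE coverage", {
  n <- 5000
  withr::with_seed(45, {
    hits <- vapply(1:200, function(i) {
      g <- matrix(rbinom(n, 2, 0.2), ncol = 1, dimnames = list(NULL, "v"))
      y <- 0.15 * g[, 1] + rnorm(n)
      ss <- run_gwas(g, y)
      abs(ss$beta - 0.15) < 2 * ss$se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.99)
})

test_that("inclusion filter enforces MAF, info and completeness strictly", {
  base <- make_sumstats(c(0.1, 0.1, 0.1), c(0.02, 0.02, 0.02))
  s2 <- base; s2$info[1] <- 0.39             # not > 0.4
  s3 <- base; s3$maf[2] <- 9e-5              # not > 1e-4
  mask <- variant_inclusion_filter(list(base, s2, s3))
  expect_equal(mask, c(FALSE, FALSE, TRUE))
  s4 <- base; s4$beta[3] <- NA
  expect_equal(variant_inclusion_filter(list(base, s4)), c(TRUE, TRUE, FALSE))
  # boundary: exactly at the thresholds fails (strict inequalities)
  s5 <- base; s5$info[3] <- 0.4; s5$maf[1] <- 1e-4
  expect_equal(variant_inclusion_filter(list(s5)), c(FALSE, TRUE, FALSE))
})

test_that("genomic control lambda identities hold", {
  chi_med <- qchisq(0.5, 1)
  z <- sqrt(rep(chi_med, 101))
  expect_equal(gc_lambda(z), 1)
  expect_equal(gc_lambda(sqrt(2) * z), 2)
  # deflation is capped: lambda < 1 leaves the statistics untouched
  st <- make_sumstats(rep(0.01, 5), rep(0.1, 5))
  corr <- gc_correct(st, lambda = 0.9)
  expect_equal(corr$se, st$se)
  expect_equal(attr(corr, "lambda"), 0.9)
  # applying GC twice at lambda = 1 is the identity
  once <- gc_correct(st, lambda = 1)
  twice <- gc_correct(once, lambda = 1)
  expect_equal(twice$se, st$se)
  expect_equal(twice$p, st$p)
  expect_error(gc_lambda(numeric(0)), "No finite")
})

test_that("IVW pooling matches its closed form and is order invariant", {
  s1 <- make_sumstats(0.1, 0.1); s2 <- make_sumstats(0.2, 0.1)
  s3 <- make_sumstats(0.3, 0.2)
  m <- ivw_meta(list(s1, s2, s3), apply_gc = FALSE)
  expect_equal(m$beta, 0.1667, tolerance = 1e-3)
  expect_equal(m$se, 0.0667, tolerance = 1e-3)
  # equal ses pool to the simple mean
  me <- ivw_meta(list(make_sumstats(0.1, 0.05), make_sumstats(0.3, 0.05)),
                 apply_gc = FALSE)
  expect_equal(me$beta, 0.2)
  # a study with enormous se carries no weight
  mi <- ivw_meta(list(make_sumstats(0.1, 0.05), make_sumstats(9, 1e6)),
                 apply_gc = FALSE)
  expect_equal(mi$beta, 0.1, tolerance = 1e-6)
  # order invariance
  m_perm <- ivw_meta(list(s3, s1, s2), apply_gc = FALSE)
  expect_equal(m_perm$beta, m$beta)
  expect_equal(m_perm$se, m$se)
  # pooled se never exceeds the best study's se
  expect_lte(m$se, min(s1$se, s2$se, s3$se))
})

test_that("alleles are harmonized by flipping, ambiguous variants dropped", {
  s1 <- make_sumstats(c(0.1, 0.2), c(0.05, 0.05))
  s2 <- s1
  # swapped effect/other alleles: beta flips back to agreement
  s2$effect_allele <- "G"; s2$other_allele <- "A"; s2$beta <- -s1$beta
  m <- ivw_meta(list(s1, s2), apply_gc = FALSE)
  expect_equal(m$beta, s1$beta)
  # A/T high-MAF strand-ambiguous variant is dropped with a warning
  s3 <- make_sumstats(0.1, 0.05, effect_allele = "A", other_allele = "T",
                      maf = 0.45)
  expect_warning(m2 <- ivw_meta(list(s3, s3), apply_gc = FALSE),
                 "ambiguous")
  expect_false(m2$included[1])
})

test_that("double genomic control inflates both stages as specified", {
  withr::with_seed(46, {
    # three independent null studies, each inflated by a factor 1.3
    mk <- function() make_sumstats(rnorm(2000) * sqrt(1.3) * 0.05,
                                   rep(0.05, 2000),
                                   variant_id = sprintf("v%04d", 1:2000))
    m <- ivw_meta(list(mk(), mk(), mk()))
  })
  expect_equal(unname(attr(m, "lambda_pre")), rep(1.3, 3), tolerance = 0.1)
  # after per-study correction the pooled statistics are calibrated again
  expect_lt(attr(m, "lambda_meta"), 1.1)
  expect_gt(attr(m, "lambda_meta"), 0.9)
})

test_that("power arithmetic converts variance fractions to allele effects", {
  expect_equal(min_detectable_effect(0.000265, 0.5), 0.023, tolerance = 2e-3)
  expect_equal(min_detectable_effect(0.000265, 1e-4), 1.1511, tolerance = 1e-3)
  # round trip: 2 p (1 - p) beta^2 recovers r2
  p <- 0.17; b <- min_detectable_effect(3e-4, p)
  expect_equal(2 * p * (1 - p) * b^2, 3e-4)
  expect_error(min_detectable_effect(0, 0.3), "r2")
  expect_error(min_detectable_effect(1e-4, 0.6), "maf")
  # NCP-based solver: detectable fraction shrinks with n, grows with power
  r2a <- min_detectable_r2(173480)
  expect_gt(r2a, 1e-4); expect_lt(r2a, 4e-4)
  expect_lt(min_detectable_r2(400000), r2a)
  # verify the solved fraction really yields the requested power
  ncp <- 173480 * r2a / (1 - r2a)
  pow <- pchisq(qchisq(8.31e-9, 1, lower.tail = FALSE), 1, ncp,
                lower.tail = FALSE)
  expect_equal(pow, 0.8, tolerance = 1e-4)
})
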