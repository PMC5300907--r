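test_that("block partitioning splits exactly at 10 Mb gaps", {
  b <- partition_blocks(c(1e6, 5e6, 20e6))
  expect_equal(b$block, c(1, 1, 2))
  expect_equal(partition_blocks(7e6)$block, 1)
  # chained gaps below 10 Mb merge despite an 18 Mb total span
  expect_equal(partition_blocks(c(0, 9e6, 18e6))$block, c(1, 1, 1))
  # boundary: a gap of exactly 10 Mb splits
  expect_equal(partition_blocks(c(0, 1e7))$block, c(1, 2))
  # chromosomes never share a block
  bc <- partition_blocks(c(1e6, 2e6, 1e6), chrom = c("1", "1", "2"))
  expect_equal(length(unique(bc$block)), 2)
})

test_that("block partitions satisfy the minimal-partition characterization", {
  withr::with_seed(61, {
    for (i in 1:20) {
      pos <- sort(sample(seq(1, 3e8, by = 1e5), 30))
      b <- partition_blocks(pos)
      sp <- split(b$pos, b$block)
      # within a block, consecutive gaps are all below the threshold
      expect_true(all(unlist(lapply(sp, function(p) diff(p) < 1e7))))
      # adjacent blocks are separated by at least the threshold
      if (length(sp) > 1) {
        ends <- vapply(sp, max, 1); starts <- vapply(sp, min, 1)
        expect_true(all(starts[-1] - ends[-length(ends)] >= 1e7))
      }
    }
  })
})

test_that("orthogonal planted signals are both selected with marginal betas", {
  withr::with_seed(62, {
    n <- 3000
    g <- cbind(v1 = rbinom(n, 2, 0.5), v2 = rbinom(n, 2, 0.5))
    y <- 0.2 * g[, 1] + 0.15 * g[, 2] + rnorm(n)
  })
  cm <- stepwise_select(g, y, alpha = 1e-4)
  expect_setequal(cm$variant_id, c("v1", "v2"))
  marg1 <- coef(lm(y ~ g[, 1]))[2]
  expect_equal(cm$beta[cm$variant_id == "v1"], unname(marg1),
               tolerance = 0.05)
})

test_that("a duplicated variant is selected exactly once", {
  withr::with_seed(63, {
    n <- 2000
    v <- rbinom(n, 2, 0.3)
    g <- cbind(a = v, b = v)
    y <- 0.3 * v + rnorm(n)
  })
  cm <- stepwise_select(g, y, alpha = 1e-4)
  expect_equal(nrow(cm), 1)
  expect_true(length(attr(cm, "skipped")) >= 1)
})

test_that("stepwise equals marginal thresholding on orthogonal designs", {
  withr::with_seed(64, {
    for (rep in 1:5) {
      n <- 400
      q <- qr.Q(qr(matrix(rnorm(n * 8), n)))   # exactly orthogonal columns
      colnames(q) <- paste0("v", 1:8)
      beta <- c(2, 0, 1.5, 0, 0, 1, 0, 0) * 0.5
      y <- drop(q %*% beta) + rnorm(n, sd = 0.5)
      alpha <- 1e-4
      cm <- stepwise_select(q, y, alpha = alpha)
      expect_setequal(cm$variant_id, marginal_select(q, y, alpha))
    }
  })
})

test_that("correlated causal pairs: stepwise equals the lm oracle and the
           recovery rate matches its closed-form power", {
  out <- withr::with_seed(65, {
    lapply(1:100, function(i) {
      g <- simulate_genotypes(5000, 2, ld_block_size = 2, block_rho = 0.9,
                              maf_spectrum = list(type = "fixed", maf = 0.3),
                              seed = sample.int(1e6, 1))
      y <- 0.15 * g$dosage[, 1] + 0.15 * g$dosage[, 2] + rnorm(5000)
      cm <- stepwise_select(g, y, alpha = 1e-4)
      list(sel = sort(cm$variant_id),
           oracle = stepwise_oracle(g$dosage, y, 1e-4),
           r = sqrt(dosage_r2(g)[1, 2]))
    })
  })
  # path equivalence with the independent lm()-based implementation
  agree <- vapply(out, function(o) identical(o$sel, o$oracle), logical(1))
  expect_gte(mean(agree), 0.99)
  # recovery of both variants tracks the bivariate-normal power of the two
  # conditional Wald tests (approx. 0.7 in this stated world, not higher)
  recovered <- vapply(out, function(o) length(o$sel) == 2, logical(1))
  pow <- both_pass_power(0.15, 0.3, 5000, mean(sapply(out, `[[`, "r")),
                         alpha = 1e-4)
  expect_lt(abs(mean(recovered) - pow),
            3 * sqrt(pow * (1 - pow) / 100) + 0.02)
})

test_that("terminal models admit no further additions or removals", {
  withr::with_seed(66, {
    g <- simulate_genotypes(3000, 30, ld_block_size = 3, block_rho = 0.8,
                            seed = 11)
    y <- 0.2 * g$dosage[, 5] - 0.25 * g$dosage[, 17] + rnorm(3000)
  })
  alpha <- 1e-4
  cm <- stepwise_select(g, y, alpha = alpha)
  expect_true(all(cm$p <= alpha))          # no removable member
  # no addable candidate: residual screen on the terminal model
  expect_true(is_terminal_model(cm, g, y,
                                candidates = colnames(g$dosage)))
  # saturated start converges to a terminal model too
  cm2 <- stepwise_select(g, y, alpha = alpha, start = "saturated")
  expect_true(all(cm2$p <= alpha))
})

test_that("clumping groups by connected components with min-p sentinels", {
  r2 <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  r2["A", "B"] <- r2["B", "A"] <- 0.9
  r2["B", "C"] <- r2["C", "B"] <- 0.85
  r2["A", "C"] <- r2["C", "A"] <- 0.5
  diag(r2) <- 1
  assoc <- tibble::tibble(variant_id = c("A", "B", "C", "D"),
                          trait = c("MCV", "MCV", "PLT", "PLT"),
                          p = c(1e-10, 1e-12, 1e-9, 1e-15))
  cl <- clump(assoc, r2)
  # chain A-B-C is one clump despite r2(A,C) = 0.5; D is a singleton
  expect_equal(dplyr::n_distinct(cl$clump), 2)
  abc <- cl[cl$variant_id %in% c("A", "B", "C"), ]
  expect_equal(dplyr::n_distinct(abc$clump), 1)
  # sentinel attains the smallest univariable p (B at 1e-12)
  expect_equal(unique(abc$variant_id[abc$sentinel]), "B")
  expect_true(all(cl$sentinel[cl$variant_id == "D"]))
})

test_that("clump output is independent of input ordering", {
  withr::with_seed(67, {
    g <- simulate_genotypes(800, 12, ld_block_size = 4, block_rho = 0.98,
                            maf_spectrum = list(type = "fixed", maf = 0.4),
                            seed = 5)
    r2 <- dosage_r2(g)
    assoc <- tibble::tibble(variant_id = colnames(g$dosage),
                            trait = "MCV", p = runif(12, 1e-20, 1e-8))
  })
  c1 <- clump(assoc, r2)
  c2 <- clump(assoc[sample(nrow(assoc)), ], r2)
  key <- function(cl) {
    cl |> dplyr::group_by(clump) |>
      dplyr::summarise(members = paste(sort(variant_id), collapse = "+"),
                       sentinel = variant_id[sentinel][1]) |>
      dplyr::arrange(members)
  }
  expect_equal(key(c1)[c("members", "sentinel")],
               key(c2)[c("members", "sentinel")])
  # missing r2 entries are treated as zero, with a warning
  expect_warning(clump(assoc, r2[1:6, 1:6]), "treated as 0")
})

test_that("variance-explained accounting matches regression R-squared", {
  withr::with_seed(68, {
    n <- 2000
    g <- simulate_genotypes(n, 6, ld_block_size = 1, seed = 8)
    y <- 0.3 * g$dosage[, 1] + 0.2 * g$dosage[, 4] + rnorm(n)
  })
  # single variant: R2 equals its squared correlation with the phenotype
  ve1 <- variance_explained_by_group(g, y, list(one = "var0001"))
  expect_equal(ve1$total_r2, cor(y, g$dosage[, 1])^2)
  p <- mean(g$dosage[, 1]) / 2
  expect_equal(ve1$total_r2, 2 * p * (1 - p) * 0.3^2 / var(y),
               tolerance = 0.15)
  # independent (finite-sample near-orthogonal) groups: shares nearly sum
  ve <- variance_explained_by_group(g, y, list(a = "var0001", b = "var0004"))
  expect_equal(sum(ve$by_group$r2_group_only), ve$total_r2, tolerance = 0.05)
  expect_equal(sum(ve$by_group$r2_sequential), ve$total_r2, tolerance = 1e-12)
  # exactly orthogonal groups: group-only shares sum to the total exactly
  withr::with_seed(69, {
    q <- qr.Q(qr(cbind(1, matrix(rnorm(500 * 4), 500))))[, -1]
    colnames(q) <- paste0("o", 1:4)   # centred, mutually orthogonal
    yo <- drop(q %*% c(1, 0.5, -0.7, 0.2)) + rnorm(500, sd = 0.3)
  })
  veo <- variance_explained_by_group(q, yo, list(g1 = c("o1", "o2"),
                                                 g2 = c("o3", "o4")))
  expect_equal(sum(veo$by_group$r2_group_only), veo$total_r2,
               tolerance = 1e-6)
  expect_true(veo$additive)
})

test_that("the heritability GC adjustment factor obeys its identities", {
  expect_equal(gc_h2_adjustment_factor(1, c(10, 20), c(1, 1)), 1)
  # common inflation cancels entirely
  expect_equal(gc_h2_adjustment_factor(1.3, c(10, 20, 30), rep(1.3, 3)), 1)
  expect_equal(gc_h2_adjustment_factor(1.1, c(40521, 45694, 87265),
                                       c(1.05, 1.08, 1.12)),
               1.0056, tolerance = 1e-4)
  expect_error(gc_h2_adjustment_factor(1, c(-1, 2), c(1, 1)), "positive")
})
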