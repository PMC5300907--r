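test_that("index pruning keeps one representative per correlated cluster", {
  # identity correlation retains everything
  id <- diag(4); dimnames(id) <- list(letters[1:4], letters[1:4])
  expect_setequal(prune_indices(id), letters[1:4])
  # a pair with r^2 = 0.9 collapses to the higher-priority member
  cr <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2,
               dimnames = list(c("PLT", "PCT"), c("PLT", "PCT")))
  expect_equal(prune_indices(cr), "PLT")
  # boundary: r^2 exactly at the threshold is retained (strict >)
  cb <- matrix(c(1, sqrt(0.8), sqrt(0.8), 1), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_setequal(prune_indices(cb), c("x", "y"))
  expect_error(prune_indices(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
})

test_that("a 36-index block structure prunes to its 13 representatives", {
  reps <- mr_index_priority()
  extras <- paste0("D", 1:23)
  blocks <- rep(seq_along(reps), length.out = 23)
  nm <- c(reps, extras)
  cr <- diag(36); dimnames(cr) <- list(nm, nm)
  for (i in seq_along(extras)) {
    j <- match(reps[blocks[i]], nm); k <- match(extras[i], nm)
    cr[j, k] <- cr[k, j] <- 0.95
    same <- which(blocks == blocks[i])
    for (i2 in same) {
      k2 <- match(extras[i2], nm)
      if (k2 != k) cr[k, k2] <- cr[k2, k] <- 0.95
    }
  }
  expect_setequal(prune_indices(cr), reps)
  expect_length(prune_indices(cr), 13)
})

test_that("K = 1 multivariable IVW reduces to weighted regression through the origin", {
  d <- simulate_mr_summaries(150, c(PLT = 0.25), seed = 71)
  est <- tidy(mvmr_ivw(d))
  w <- 1 / d$sey^2
  theta_ref <- sum(w * d$Bx[, 1] * d$by) / sum(w * d$Bx[, 1]^2)
  se_ref <- 1 / sqrt(sum(w * d$Bx[, 1]^2))
  expect_equal(est$theta, theta_ref)
  expect_equal(est$se, se_ref)
})

test_that("multivariable IVW recovers planted effects and scales correctly", {
  d <- simulate_mr_summaries(200, c(PLT = 0.2, MCH = -0.1), seed = 72)
  est <- tidy(mvmr_ivw(d))
  expect_lt(abs(est$theta[1] - 0.2), 2 * est$se[1])
  expect_lt(abs(est$theta[2] + 0.1), 2 * est$se[2])
  # rescaling an exposure column scales its estimate inversely
  d2 <- d; d2$Bx[, 1] <- d$Bx[, 1] * 10
  est2 <- tidy(mvmr_ivw(d2))
  expect_equal(est2$theta[1], est$theta[1] / 10)
  expect_equal(est2$theta[2], est$theta[2])
  # collinear exposures are refused with the offending index named
  d3 <- d; d3$Bx[, 2] <- 2 * d3$Bx[, 1]
  expect_error(mvmr_ivw(d3), "MCH")
})

test_that("orthogonal exposures make multivariable match univariable", {
  withr::with_seed(73, {
    k <- 3; nv <- 90
    bx <- matrix(0, nv, k, dimnames = list(NULL, c("A", "B", "C")))
    for (j in 1:k) bx[seq((j - 1) * 30 + 1, j * 30), j] <- rnorm(30, 0, 0.08)
    sey <- rep(0.02, nv)
    by <- drop(bx %*% c(0.3, -0.2, 0.1)) + rnorm(nv, 0, sey)
  })
  d <- structure(list(variants = tibble::tibble(variant_id = 1:nv,
                                                chrom = "2", pos = 1:nv,
                                                mhc = FALSE,
                                                known_disease = FALSE,
                                                n_index_classes = 1L),
                      Bx = bx, SEx = bx * 0 + 0.01, by = by, sey = sey,
                      index_names = c("A", "B", "C"), truth = NULL),
                 class = "mr_dataset")
  multi <- tidy(mvmr_ivw(d))
  w <- 1 / sey^2
  uni <- vapply(1:3, function(j) sum(w * bx[, j] * by) / sum(w * bx[, j]^2),
                numeric(1))
  expect_equal(multi$theta, uni, tolerance = 1e-10)
})

test_that("realigned Egger estimates directional pleiotropy and is flip invariant", {
  d <- simulate_mr_summaries(400, c(PLT = 0.2), pleiotropy = 0.05,
                             pleiotropy_aligned_to = "PLT", seed = 74)
  eg <- mvmr_egger(d, "PLT")
  int <- attr(eg, "intercept")
  expect_lt(abs(int$estimate - 0.05), 2.5 * int$se)
  # flipping the signs of arbitrary input rows changes nothing
  d2 <- d
  withr::with_seed(75, flip <- sample(c(-1, 1), 400, replace = TRUE))
  d2$Bx <- d$Bx * flip; d2$by <- d$by * flip
  eg2 <- mvmr_egger(d2, "PLT")
  expect_equal(tidy(eg2)$theta[1], tidy(eg)$theta[1])
  expect_equal(attr(eg2, "intercept")$estimate, int$estimate)
  # without pleiotropy the intercept is consistent with zero
  d0 <- simulate_mr_summaries(400, c(PLT = 0.2), seed = 76)
  int0 <- attr(mvmr_egger(d0, "PLT"), "intercept")
  expect_lt(abs(int0$estimate), 3 * int0$se)
  ints <- mvmr_egger_intercepts(d0)
  expect_equal(nrow(ints), 1)
})

test_that("Bonferroni accounting multiplies the grid and divides the level", {
  b <- bonferroni_threshold(0.05, 13, 14)
  expect_equal(b$n_tests, 182)
  expect_equal(b$threshold, 0.05 / 182)
  b1 <- bonferroni_threshold(0.05, 1, 1)
  expect_equal(b1, list(n_tests = 1, threshold = 0.05))
  expect_equal(b$threshold * b$n_tests, 0.05)
})

test_that("sensitivity filters drop the right instruments", {
  d <- simulate_mr_summaries(50, c(PLT = 0.2, MCH = 0.1), seed = 77)
  d$variants$chrom[1:8] <- "6"
  d$variants$pos[1:8] <- c(25e6, 41e6, 20e6, 40e6, 19.9e6, 30e6, 35e6, 40.1e6)
  d$variants$mhc <- NULL
  f <- sensitivity_filter(d, "mhc")
  kept6 <- f$variants$pos[f$variants$chrom == "6"]
  expect_setequal(kept6, c(41e6, 19.9e6, 40.1e6))   # outside 20-40 Mb kept
  expect_equal(nrow(f$Bx), nrow(f$variants))
  # pleiotropic clumps: variants hitting all five index classes removed
  d$variants$n_index_classes[3:5] <- 5L
  fp <- sensitivity_filter(d, "pleiotropic_clumps")
  expect_equal(nrow(fp$variants), 47)
  # known-disease flags
  d$variants$known_disease[10] <- TRUE
  fk <- sensitivity_filter(d, "known_disease_loci")
  expect_equal(nrow(fk$variants), 49)
  # removing everything is an informative error
  d$variants$n_index_classes <- 5L
  expect_error(sensitivity_filter(d, "pleiotropic_clumps"), "every")
})

test_that("MR dataset TSV round trip preserves the estimates", {
  d <- simulate_mr_summaries(60, c(PLT = 0.2, MCH = -0.1), seed = 78)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mr_dataset(d, path)
  d2 <- read_mr_dataset(path)
  expect_equal(d2$index_names, d$index_names)
  expect_equal(tidy(mvmr_ivw(d2))$theta, tidy(mvmr_ivw(d))$theta)
})
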