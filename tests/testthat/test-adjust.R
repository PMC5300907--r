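test_that("aberrant day scores follow the standardized-deviation formula", {
  # symmetric construction: global median 0, raw MAD 1; the probed cell holds
  # n = 16 values all equal to 5 (a mirror cell at -5 keeps the global stats)
  vals <- c(rep(c(-1, 1), 500), rep(5, 16), rep(-5, 16))
  day <- c(rep(1:50, each = 20), rep(99, 16), rep(98, 16))
  instr <- rep("M1", length(vals))
  sc <- aberrant_day_scores(vals, day, instr)
  cell <- sc[sc$day == 99, ]
  expect_equal(cell$z, sqrt(16) * 5 / 1)   # z = 20 under the sqrt(n) scaling
  expect_true(cell$excluded)
  # literal cardinality option
  sc_n <- aberrant_day_scores(vals, day, instr, scale = "n")
  expect_equal(sc_n$z[sc_n$day == 99], 16 * 5)
  # a cell whose mean equals the global median scores zero
  expect_equal(sc$z[sc$day == 1], 0)
})

test_that("cells with fewer than 10 points are excluded regardless of z", {
  vals <- c(rep(c(-1, 1), 50), rep(0, 9))
  day <- c(rep(1:10, each = 10), rep(99, 9))
  sc <- aberrant_day_scores(vals, day, rep("M1", length(vals)))
  small <- sc[sc$day == 99, ]
  expect_equal(small$z, 0)
  expect_true(small$excluded)
  expect_equal(small$reason, "cell_too_small")
})

test_that("stage-1 adjustment removes planted drift and calibration jumps", {
  s <- fx_cohort$samples
  adj <- fx_tf$adjusted
  ok <- !adj$excluded
  # planted M1 drift of +0.2 over the window flattens after adjustment
  m1 <- ok & s$instrument == "M1"
  raw_slope <- coef(lm(adj$a_raw[m1] ~ s$day[m1]))[2] * 730
  adj_slope <- coef(lm(adj$a_adjusted[m1] ~ s$day[m1]))[2] * 730
  expect_gt(raw_slope, 0.15)
  expect_lt(abs(adj_slope), 0.02)
  # planted M2 discontinuity at day 366 vanishes after adjustment
  m2 <- ok & s$instrument == "M2"
  pre <- m2 & s$day >= 250 & s$day < 366
  post <- m2 & s$day >= 366 & s$day < 480
  raw_jump <- mean(adj$a_raw[post]) - mean(adj$a_raw[pre])
  adj_jump <- mean(adj$a_adjusted[post]) - mean(adj$a_adjusted[pre])
  expect_gt(raw_jump, 0.04)               # drift(-0.08) partially offsets +0.12
  # qualitative elimination: the discontinuity shrinks into the noise floor
  expect_lt(abs(adj_jump), 0.03)
  expect_lt(abs(adj_jump), 0.4 * raw_jump)
})

test_that("the planted aberrant day-instrument cell is caught and excluded", {
  bad <- fx_tf$aberrant[fx_tf$aberrant$excluded &
                          fx_tf$aberrant$reason == "aberrant_day", ]
  expect_true(nrow(bad) >= 1)
  expect_true(any(bad$instrument == "M1" & bad$day == fx_active_days[5]))
  s <- fx_cohort$samples
  hit <- s$instrument == "M1" & s$day == fx_active_days[5]
  expect_true(all(fx_tf$adjusted$excluded[hit]))
})

test_that("with no artifacts the adjustment is close to a no-op", {
  tf <- technical_adjust(fx_quiet, "MCV", knots = fx_knots)
  ok <- !tf$adjusted$excluded
  expect_gt(cor(tf$adjusted$a_raw[ok], tf$adjusted$a_adjusted[ok]), 0.99)
})

test_that("instruments without enough distinct days lose their drift term", {
  ch <- fx_quiet
  ch$samples <- ch$samples |>
    dplyr::mutate(instrument = ifelse(.data$instrument == "M3" &
                                        .data$day != fx_active_days[2],
                                      "M1", .data$instrument))
  # both fitting passes emit the warning
  w <- testthat::capture_warnings(technical_adjust(ch, "MCV",
                                                   knots = fx_knots))
  expect_true(any(grepl("Drift term dropped", w)))
})

test_that("derived indices are recomputed from adjusted measured indices", {
  st1 <- suppressWarnings(
    technical_adjust_cohort(fx_cohort, indices = c("RBC", "MCV"),
                            knots = fx_knots))
  s <- st1$cohort$samples
  expect_equal(s$HCT, s$RBC * s$MCV / 10)
  expect_false(isTRUE(all.equal(s$RBC, fx_cohort$samples$RBC)))
})

test_that("technical sample exclusions apply the 36 h and MPV rules strictly", {
  mk <- function(analyzer, delay_h, mpv) {
    n <- length(delay_h)
    acq <- as.POSIXct("2020-06-01 12:00:00", tz = "UTC") + seq_len(n) * 60
    structure(list(
      study_id = "A", analyzer = analyzer,
      samples = tibble::tibble(sample_id = paste0("s", seq_len(n)),
                               acq_time = acq,
                               ven_time = acq - delay_h * 3600,
                               MPV = mpv),
      registry = blood_index_registry()), class = "cohort_dataset")
  }
  f <- sample_filters(mk("sysmex", c(37, 36, 10, 10), c(10, 10, 13.5, 13)))
  expect_equal(f$exclude_all, c(TRUE, FALSE, FALSE, FALSE))  # > 36 h, strict
  expect_equal(f$null_platelet, c(FALSE, FALSE, TRUE, FALSE)) # MPV > 13, strict
  # Coulter: adjusted MPV above the 96th percentile nulled, at it retained
  mpv <- seq(8, 12, length.out = 100)
  fc <- sample_filters(mk("coulter", rep(10, 100), mpv))
  q96 <- quantile(mpv, 0.96, names = FALSE)
  expect_equal(fc$null_platelet, mpv > q96)
  expect_equal(sum(fc$null_platelet), 4)
  # missing timestamps are reported unexcludable
  ch <- mk("sysmex", c(10, NA), c(10, 10))
  ch$samples$ven_time[2] <- NA
  fm <- sample_filters(ch)
  expect_equal(fm$reason[2], "unexcludable_missing_timestamp")
  expect_false(fm$exclude_all[2])
})

test_that("raw-vs-adjusted difference outliers use the 3.5 scaled-MAD rule", {
  # symmetric differences: median 0, raw MAD 1, scaled MAD 1.4826, so the
  # 3.5-scaled-MAD threshold sits at 5.189
  diffs <- c(rep(c(-1, 1), 60), 4.9, -4.9, 5.3, -5.3)
  mask <- adjustment_difference_outliers(diffs, rep(0, length(diffs)))
  expect_false(mask[121])                 # 4.9 < 3.5 * 1.4826
  expect_false(mask[122])
  expect_true(mask[123])                  # 5.3 > 3.5 * 1.4826
  expect_true(mask[124])
  expect_warning(adjustment_difference_outliers(rep(1, 10), rep(0, 10)),
                 "zero")
  # identical pairs: zero MAD, warned, nothing excluded
  expect_equal(sum(suppressWarnings(
    adjustment_difference_outliers(rep(c(0, 1), 10), rep(c(0, 1), 10)))), 0)
})

test_that("multivariate outlier scores are chi-square distributed under the null", {
  withr::with_seed(21, {
    x <- matrix(rnorm(1e5 * 3), ncol = 3)
  })
  sc <- multivariate_outlier_scores(x, d = 3)
  ks <- suppressWarnings(ks.test(sc$score[!is.na(sc$score)], pchisq, df = 3))
  expect_gt(ks$p.value, 0.01)
  # essentially no exclusions at the 1e-7 tail
  expect_lt(sum(sc$excluded), 5)
})

test_that("univariate 4.5-MAD outliers are removed before the PCA", {
  withr::with_seed(22, x <- matrix(rnorm(500 * 3), ncol = 3))
  med <- median(x[, 1]); s <- scaled_mad(x[, 1])
  x[1, 1] <- med + 4.6 * s
  sc <- multivariate_outlier_scores(x, d = 3)
  expect_true(sc$excluded[1])
  expect_equal(sc$reason[1], "univariate_outlier")
  expect_error(multivariate_outlier_scores(x, d = 4), "exceeds")
})

test_that("stratified inverse-normal transform yields exact normal scores", {
  withr::with_seed(23, {
    v <- rnorm(500)
    strata <- sample(c("a", "b", "c"), 500, replace = TRUE)
  })
  z <- inverse_normal_transform(v, strata)
  for (st in unique(strata)) {
    i <- strata == st
    expect_equal(sort(z[i]), normal_scores_oracle(sort(v[i])))
    expect_lt(abs(mean(z[i])), 1e-12)
    expect_equal(cor(z[i], v[i], method = "spearman"), 1)
  }
  # ties share the average-rank score
  zt <- inverse_normal_transform(c(1, 2, 2, 3))
  expect_equal(zt[2], zt[3])
  expect_equal(zt, normal_scores_oracle(c(1, 2, 2, 3)))
  expect_warning(out <- inverse_normal_transform(c(1, 5, 6), c("a", "b", "b")),
                 "single")
  expect_true(is.na(out[1]))
  expect_false(anyNA(out[2:3]))
})

test_that("stage-2 adjustment removes the planted age effect", {
  st1 <- suppressWarnings(
    technical_adjust_cohort(fx_cohort, indices = "MCV", knots = fx_knots))
  ef <- suppressWarnings(
    environmental_adjust(st1$cohort, "MCV",
                         terms = environmental_terms("A", knots = list(
                           age = 10, body = 10, packyears = 6,
                           alcohol = 6, period = 6))))
  adj <- ef$adjusted$a_adjusted
  s <- fx_cohort$samples
  ok <- !is.na(adj)
  raw_cor <- cor(ef$adjusted$a_input[ok], s$age[ok])
  expect_gt(abs(raw_cor), 4 / sqrt(sum(ok)))   # the planted effect is visible
  expect_lt(abs(cor(adj[ok], s$age[ok])), 4 / sqrt(sum(ok)))
})

test_that("the days-since-period smooth never touches male samples", {
  g <- simulate_genotypes(800, 5, seed = 31)
  ch <- simulate_cohort(g, study_id = "B", analyzer = "sysmex",
                        indices = "PLT", seed = 32)
  ef <- suppressWarnings(
    environmental_adjust(ch, "PLT",
                         terms = environmental_terms("B", knots = list(
                           age = 10, body = 10, packyears = 6,
                           alcohol = 6, period = 6))))
  tl <- predict(ef$fit, type = "terms")
  dsp_col <- grep("dsp", colnames(tl), value = TRUE)
  expect_length(dsp_col, 1)
  male <- ef$fit$model$is_pre == 0
  expect_lt(max(abs(tl[male, dsp_col])), 1e-10)
})

test_that("an all-missing covariate degrades to a missingness dummy", {
  ch <- fx_quiet
  ch$samples$pack_years <- NA_real_
  ef <- suppressWarnings(environmental_adjust(ch, "MCV"))
  expect_s3_class(ef, "environmental_fit")
  expect_false(any(grepl("pack_years", rownames(summary(ef$fit)$s.table))))
})
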