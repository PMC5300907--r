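# Shared fixtures, built once per test run. Sizes are desk-scale on purpose;
# every random draw is seeded.

fx_n <- 1200
# active measurement days are deterministic given n and batch size
fx_active_days <- unique(round(seq(0, 729, length.out = ceiling(fx_n / 60))))

fx_geno <- simulate_genotypes(fx_n, 30, ld_block_size = 5, seed = 42)

fx_artifacts <- technical_artifacts(
  drift_slope = c(M1 = 0.2, M2 = -0.08, M3 = 0.03),
  calibration_jumps = tibble::tibble(instrument = "M2", day = 366L,
                                     size = 0.12),
  seasonal_amplitude = 0.04,
  aberrant_days = tibble::tibble(day = fx_active_days[5], instrument = "M1",
                                 shift = 0.6))

fx_cohort <- simulate_cohort(
  fx_geno,
  architecture = architecture_spec(
    effects = tibble::tibble(variant_id = "var0003", index = "MCV",
                             beta = 0.3),
    h2_poly = c(MCV = 0.2)),
  artifacts = fx_artifacts,
  indices = c("RBC", "MCV", "HGB", "PLT", "MPV"),
  seed = 43)

fx_quiet <- simulate_cohort(
  fx_geno,
  artifacts = technical_artifacts(
    drift_slope = 0, tod_amplitude = 0, delay_slope = 0,
    weekday_effects = rep(0, 7), seasonal_amplitude = 0, noise_sd = 1e-4),
  indices = c("MCV", "PLT"),
  seed = 44)

fx_knots <- list(drift = 12, bivariate = 10, seasonal = 8)
fx_tf <- technical_adjust(fx_cohort, "MCV", knots = fx_knots)
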