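# Synthetic full-blood-count cohorts with planted genetic effects, covariate
# effects and instrument-level technical artifacts, all composed additively on
# each index's adjustment scale with retrievable ground truth.

#' Genetic architecture specification
#'
#' Planted causal effects and polygenic background for the cohort simulator.
#' Effects are per-allele additive effects in phenotype SD units; each
#' variant's variance contribution is 2 p (1 - p) beta^2 and, together with
#' the polygenic fraction, contributions must sum below 1 per index.
#'
#' @param effects tibble with columns `variant_id`, `index`, `beta`.
#' @param h2_poly named numeric vector of polygenic variance fractions per
#'   index (indices absent default to `0`).
#' @return an `architecture_spec` object.
#' @export
architecture_spec <- function(effects = tibble(variant_id = character(),
                                               index = character(),
                                               beta = double()),
                              h2_poly = c()) {
  effects <- as_tibble(effects)
  stopifnot(all(c("variant_id", "index", "beta") %in% names(effects)))
  structure(list(effects = effects, h2_poly = h2_poly),
            class = "architecture_spec")
}

#' Technical artifact specification
#'
#' Instrument-level measurement artifacts, all expressed additively on the
#' adjustment scale: continuous drift per instrument (linear in study time
#' plus calibration step-discontinuities), a sinusoidal time-of-day effect, a
#' linear venipuncture-delay effect, weekday offsets, a seasonal sinusoid
#' shared across instruments, aberrant (day, instrument) shifts, and white
#' measurement noise. Defaults emulate artifact shares of a few percent of
#' index variance, in line with the up-to-16% technical variance seen on real
#' analyzers.
#'
#' @param drift_slope named vector, adjustment-scale drift per instrument over
#'   the full recruitment window (recycled to instruments if unnamed scalar).
#' @param calibration_jumps tibble `instrument`, `day`, `size` of step changes.
#' @param tod_amplitude amplitude of the within-day sinusoid.
#' @param delay_slope effect per hour of venipuncture-to-acquisition delay.
#' @param weekday_effects length-7 vector of offsets (Mon..Sun).
#' @param seasonal_amplitude,seasonal_phase seasonal sinusoid amplitude and
#'   phase (day of year of the maximum).
#' @param aberrant_days tibble `day`, `instrument`, `shift` of aberrant cells.
#' @param noise_sd technical noise SD, scalar or named per index.
#' @return a `technical_artifacts` object.
#' @export
technical_artifacts <- function(drift_slope = 0.05,
                                calibration_jumps = tibble(
                                  instrument = character(), day = integer(),
                                  size = double()),
                                tod_amplitude = 0.01,
                                delay_slope = 0.0025,
                                weekday_effects = c(0, 0.004, 0.002, 0,
                                                    -0.002, -0.004, 0),
                                seasonal_amplitude = 0.02,
                                seasonal_phase = 180,
                                aberrant_days = tibble(day = integer(),
                                                       instrument = character(),
                                                       shift = double()),
                                noise_sd = 0.02) {
  structure(list(drift_slope = drift_slope,
                 calibration_jumps = as_tibble(calibration_jumps),
                 tod_amplitude = tod_amplitude, delay_slope = delay_slope,
                 weekday_effects = rep_len(weekday_effects, 7),
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_phase = seasonal_phase,
                 aberrant_days = as_tibble(aberrant_days),
                 noise_sd = noise_sd),
            class = "technical_artifacts")
}

#' Covariate effect specification
#'
#' Adjustment-scale effects of sex/menopause, age, body size, smoking and
#' alcohol on each index. Effects are additive on the adjustment scale; any
#' index absent from a component is unaffected by it. The defaults plant the
#' dominant known covariate signals (e.g. lower HGB/RBC in premenopausal
#' women, higher platelet counts in women, age trends, smoking effects on
#' white-cell counts).
#'
#' @param sexmeno_offsets tibble `index`, `level`, `offset` with levels among
#'   `male`, `female-pre`, `female-post`, `female-hyst`, `no-answer`.
#' @param age_slope,age_quad named per-index coefficients of `(age - 55)/10`
#'   and its square.
#' @param bmi_slope named per-index coefficient of centred log-BMI.
#' @param packyears_slope named per-index coefficient of `pack_years / 20`.
#' @param alcohol_slope named per-index coefficient of `alcohol_quantity / 4`.
#' @param period_amplitude named per-index amplitude of a sinusoid in
#'   days-since-last-period (premenopausal women only).
#' @return a `covariate_effects` object.
#' @export
covariate_effects <- function(
    sexmeno_offsets = tribble(
      ~index, ~level, ~offset,
      "HGB", "male", 0.085, "HGB", "female-pre", -0.035,
      "RBC", "male", 0.055, "RBC", "female-pre", -0.02,
      "PLT", "male", -0.06,
      "MPV", "male", -0.01,
      "RET_PCT", "female-pre", 0.10,
      "NEUT", "female-pre", 0.06,
      "LYMPH", "male", -0.02
    ),
    age_slope = c(RBC = -0.01, HGB = -0.008, MCV = 0.008, RDW = 0.012,
                  PLT = -0.02, NEUT = 0.015, LYMPH = -0.03, MONO = 0.02,
                  EO = 0.02, BASO = 0.01, MPV = 0.004, PDW = 0.004,
                  RET_PCT = 0.02),
    age_quad = c(PLT = -0.006, LYMPH = -0.008),
    bmi_slope = c(WBC = 0.2, NEUT = 0.25, LYMPH = 0.18, MONO = 0.12,
                  PLT = 0.10, HGB = 0.05, RBC = 0.05, RET_PCT = 0.2,
                  EO = 0.15, BASO = 0.08, MCV = -0.01, RDW = 0.03,
                  MPV = 0.01, PDW = 0.01),
    packyears_slope = c(NEUT = 0.08, MONO = 0.05, BASO = 0.04, EO = 0.03,
                        LYMPH = 0.05, RBC = 0.01, MCV = 0.012, HGB = 0.012,
                        RDW = 0.02, PLT = 0.015, RET_PCT = 0.03,
                        MPV = 0.005, PDW = 0.005),
    alcohol_slope = c(MCV = 0.006, HGB = 0.005, PLT = -0.01, NEUT = -0.01,
                      RDW = 0.004, RET_PCT = 0.01),
    period_amplitude = c(HGB = 0.01, PLT = 0.015, NEUT = 0.02)) {
  structure(list(sexmeno_offsets = as_tibble(sexmeno_offsets),
                 age_slope = age_slope, age_quad = age_quad,
                 bmi_slope = bmi_slope, packyears_slope = packyears_slope,
                 alcohol_slope = alcohol_slope,
                 period_amplitude = period_amplitude),
            class = "covariate_effects")
}

.cov_component <- function(coefs, index, x) {
  k <- coefs[index]
  if (is.na(k)) 0 else k * x
}

# total covariate contribution for one index, on the adjustment scale
.covariate_contribution <- function(index, cov, spec) {
  out <- numeric(nrow(cov))
  so <- spec$sexmeno_offsets
  so <- so[so$index == index, ]
  if (nrow(so)) {
    m <- setNames(so$offset, so$level)
    add <- m[as.character(cov$sexmeno)]
    add[is.na(add)] <- 0
    out <- out + add
  }
  az <- (cov$age - 55) / 10
  out <- out + .cov_component(spec$age_slope, index, az) +
    .cov_component(spec$age_quad, index, az^2)
  lbmi <- log(cov$weight) - 2 * log(cov$height / 100)
  out <- out + .cov_component(spec$bmi_slope, index, lbmi - median(lbmi))
  py <- ifelse(is.na(cov$pack_years), 0, cov$pack_years)
  out <- out + .cov_component(spec$packyears_slope, index, py / 20)
  alc <- ifelse(is.na(cov$alcohol_quantity), 0, cov$alcohol_quantity)
  out <- out + .cov_component(spec$alcohol_slope, index, alc / 4)
  pa <- spec$period_amplitude[index]
  if (!is.na(pa)) {
    dsp <- cov$days_since_period
    contrib <- ifelse(is.na(dsp), 0, pa * sin(2 * pi * dsp / 28))
    out <- out + contrib
  }
  unname(out)
}

# technical artifact contribution shared across indices, adjustment scale
.technical_contribution <- function(meta, art, window_days) {
  out <- numeric(nrow(meta))
  slopes <- art$drift_slope
  instr <- as.character(meta$instrument)
  if (is.null(names(slopes))) {
    slopes <- setNames(rep_len(slopes, length(unique(instr))), unique(instr))
  }
  s <- slopes[instr]
  s[is.na(s)] <- 0
  out <- out + s * (meta$day / window_days)
  if (nrow(art$calibration_jumps)) {
    for (j in seq_len(nrow(art$calibration_jumps))) {
      cj <- art$calibration_jumps[j, ]
      hit <- instr == cj$instrument & meta$day >= cj$day
      out[hit] <- out[hit] + cj$size
    }
  }
  out <- out + art$tod_amplitude * sin(2 * pi * (meta$t_day - 8) / 24)
  out <- out + art$delay_slope * (meta$delay_h - mean(meta$delay_h))
  out <- out + art$weekday_effects[meta$weekday_num]
  out <- out + art$seasonal_amplitude *
    cos(2 * pi * (meta$t_year - art$seasonal_phase) / 365.25)
  if (nrow(art$aberrant_days)) {
    key <- paste(meta$day, instr)
    ab <- art$aberrant_days
    abkey <- paste(ab$day, ab$instrument)
    idx <- match(key, abkey)
    out <- out + ifelse(is.na(idx), 0, ab$shift[idx])
  }
  out
}

#' Simulate a full-blood-count cohort
#'
#' Builds a per-sample table of raw measured blood indices with instrument
#' ids, acquisition and venipuncture timestamps, recruitment centre and
#' biological covariates. On each index's adjustment scale the simulated
#' value is baseline + sd_a x (genetic + polygenic + residual biology) +
#' covariate effects + technical artifacts + technical noise; the measured
#' value is the inverse transform, and derived indices are computed from the
#' measured ones. All planted components are retained in `$truth` for
#' recovery testing.
#'
#' Samples are recruited over a `window_days` window in day batches so every
#' active (day, instrument) cell holds enough measurements for aberrant-day
#' statistics.
#'
#' @param genotypes a `genotype_matrix` covering the cohort samples.
#' @param architecture an [architecture_spec()] (or `NULL` for no genetics).
#' @param artifacts a [technical_artifacts()] specification.
#' @param covariates a [covariate_effects()] specification.
#' @param study_id study label ("A", "B" or "C").
#' @param analyzer analyzer family, `"coulter"` or `"sysmex"` (drives the
#'   platelet exclusion rule in [sample_filters()]).
#' @param indices measured indices to simulate (default: full measured set).
#' @param n_instruments number of analyzers in the study.
#' @param n_centers recruitment centres.
#' @param window_days recruitment window length (default two years).
#' @param batch_per_day average samples measured per active day.
#' @param start_date first study day (a Monday by default).
#' @param seed integer seed; bit-identical output for identical seeds.
#' @return a `cohort_dataset`: list with `study_id`, `analyzer`, `samples`
#'   (tibble), `truth` (long tibble of planted components per index, on the
#'   adjustment scale), `registry`.
#' @examples
#' g <- simulate_genotypes(200, 10, seed = 1)
#' ch <- simulate_cohort(g, seed = 1)
#' dplyr::glimpse(ch$samples[1:8])
#' @export
simulate_cohort <- function(genotypes,
                            architecture = architecture_spec(),
                            artifacts = technical_artifacts(),
                            covariates = covariate_effects(),
                            study_id = "A",
                            analyzer = c("coulter", "sysmex"),
                            indices = NULL,
                            n_instruments = 3, n_centers = 4,
                            window_days = 730, batch_per_day = 60,
                            start_date = as.Date("2020-01-06"),
                            seed = 1L) {
  analyzer <- match.arg(analyzer)
  reg <- blood_index_registry()
  measured <- reg$index[reg$role == "measured"]
  if (!is.null(indices)) measured <- intersect(measured, indices)
  n <- length(genotypes$sample_ids)
  eff <- architecture$effects
  missing_v <- setdiff(eff$variant_id, genotypes$variants$variant_id)
  if (length(missing_v)) {
    abort(paste0("Causal variants absent from genotypes: ",
                 paste(missing_v, collapse = ", ")))
  }

  withr::with_seed(seed, {
    # --- recruitment times, instruments, centres -------------------------
    n_days <- max(2L, ceiling(n / batch_per_day))
    active_days <- unique(round(seq(0, window_days - 1, length.out = n_days)))
    day <- sort(rep_len(active_days, n))
    instrument <- paste0("M", sample.int(n_instruments, n, replace = TRUE))
    center <- paste0("C", sample.int(n_centers, n, replace = TRUE))
    t_day <- runif(n, 8, 20)                     # hours since midnight
    # overnight transport: ~2/3 measured within 24 h, ~2-3% beyond 36 h
    delay_h <- pmin(rgamma(n, shape = 9, scale = 7 / 3), 70)
    date <- start_date + day
    acq_time <- as.POSIXct(date, tz = "UTC") + t_day * 3600
    ven_time <- acq_time - delay_h * 3600
    weekday_num <- as.integer(format(date, "%u"))
    t_year <- as.numeric(format(date, "%j")) - 1 + t_day / 24

    # --- biological covariates -------------------------------------------
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- runif(n, 40, 70)
    sexmeno <- ifelse(sex == "M", "male",
                      ifelse(age + rnorm(n, 0, 2) < 50.5,
                             "female-pre", "female-post"))
    hyst <- sex == "F" & runif(n) < 0.05
    sexmeno[hyst] <- "female-hyst"
    sexmeno[runif(n) < 0.01] <- "no-answer"
    height <- rnorm(n, ifelse(sex == "M", 176, 163), 6.5)
    weight <- exp(rnorm(n, log(26), 0.14)) * (height / 100)^2
    smoking_habit <- sample(
      c("never", "special-occasions", "rarely", "occasional", "most-days",
        "every-day"), n, replace = TRUE,
      prob = c(0.52, 0.08, 0.08, 0.08, 0.09, 0.15))
    pack_years <- ifelse(smoking_habit == "never", 0,
                         rgamma(n, shape = 1.5, scale = 10))
    pack_years[runif(n) < 0.02] <- NA            # missing covariate data
    drinking_status <- sample(c("never", "previous", "current"), n,
                              replace = TRUE, prob = c(0.10, 0.05, 0.85))
    drinking_habit <- sample(
      c("never", "special-occasions", "1-3-times-monthly", "1-2-times-weekly",
        "3-5-times-weekly", "most-days"), n, replace = TRUE,
      prob = c(0.1, 0.12, 0.12, 0.26, 0.2, 0.2))
    alcohol_quantity <- ifelse(drinking_status == "current",
                               rgamma(n, shape = 1.2, scale = 2.5), 0)
    alcohol_quantity[runif(n) < 0.02] <- NA
    days_since_period <- ifelse(sexmeno == "female-pre",
                                runif(n, 0, 35), NA_real_)

    cov_tbl <- tibble(sexmeno = sexmeno, age = age, height = height,
                      weight = weight, smoking_habit = smoking_habit,
                      pack_years = pack_years,
                      drinking_status = drinking_status,
                      drinking_habit = drinking_habit,
                      alcohol_quantity = alcohol_quantity,
                      days_since_period = days_since_period)
    meta <- tibble(day = day, instrument = instrument, t_day = t_day,
                   delay_h = delay_h, weekday_num = weekday_num,
                   t_year = t_year)
    technical <- .technical_contribution(meta, artifacts, window_days)

    # --- per-index assembly on the adjustment scale ----------------------
    values <- list()
    truth <- list()
    for (idx in measured) {
      row <- reg[reg$index == idx, ]
      base_a <- to_adjustment_scale(row$baseline, row$adjustment_scale)
      sd_a <- row$sd_a
      e <- eff[eff$index == idx, ]
      genetic <- numeric(n)
      var_gen <- 0
      if (nrow(e)) {
        for (j in seq_len(nrow(e))) {
          g <- genotypes$dosage[, e$variant_id[j]]
          p <- mean(g) / 2
          genetic <- genetic + e$beta[j] * (g - 2 * p)
          var_gen <- var_gen + 2 * p * (1 - p) * e$beta[j]^2
        }
      }
      h2p <- unname(architecture$h2_poly[idx])
      if (is.null(h2p) || length(h2p) != 1 || is.na(h2p)) h2p <- 0
      if (var_gen + h2p >= 1) {
        abort(sprintf(
          "Planted variance fractions for %s sum to %.3f >= 1.", idx,
          var_gen + h2p))
      }
      polygenic <- rnorm(n, 0, sqrt(h2p))
      resid <- rnorm(n, 0, sqrt(1 - var_gen - h2p))
      cov_contrib <- .covariate_contribution(idx, cov_tbl, covariates)
      nsd <- artifacts$noise_sd
      if (!is.null(names(nsd))) {
        nsd <- unname(nsd[idx])
        if (is.na(nsd)) nsd <- 0.02
      }
      noise <- rnorm(n, 0, nsd)
      a_val <- base_a + sd_a * (genetic + polygenic + resid) +
        cov_contrib + technical + noise
      values[[idx]] <- from_adjustment_scale(a_val, row$adjustment_scale)
      truth[[idx]] <- tibble(
        sample_id = genotypes$sample_ids, index = idx,
        genetic = sd_a * genetic, polygenic = sd_a * polygenic,
        biological_resid = sd_a * resid, covariate = cov_contrib,
        technical = technical, noise = noise, a_value = a_val)
    }
  })

  samples <- bind_cols(
    tibble(sample_id = genotypes$sample_ids, study = study_id,
           instrument = instrument, center = center,
           acq_time = acq_time, ven_time = ven_time, day = day,
           sex = sex),
    cov_tbl,
    as_tibble(values))
  samples <- derive_indices(samples)
  structure(list(study_id = study_id, analyzer = analyzer,
                 samples = samples, truth = bind_rows(truth),
                 registry = reg, artifacts = artifacts,
                 architecture = architecture),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> study %s (%s analyzer): %d samples, %d indices\n",
              x$study_id, x$analyzer, nrow(x$samples),
              sum(x$registry$index %in% names(x$samples))))
  invisible(x)
}

#' Write cohort sample tables as TSV
#'
#' Timestamps are serialized as ISO-8601 UTC strings.
#'
#' @param cohort a `cohort_dataset`; `path` output file.
#' @export
write_cohort_tsv <- function(cohort, path) {
  tab <- cohort$samples |>
    mutate(acq_time = format(.data$acq_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           ven_time = format(.data$ven_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_tsv(tab, path)
  invisible(path)
}
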