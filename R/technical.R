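# Stage-1 technical/seasonal adjustment: penalized-spline additive model of
# instrument drift (with calibration discontinuities), within-day time and
# venipuncture-delay effects, weekday and instrument offsets and a cyclic
# seasonal term, fitted on the central part of the data, with an
# aberrant-day exclusion pass and a refit.

#' Aberrant day-instrument scores
#'
#' For each (day, instrument) cell of drift-adjusted values on the adjustment
#' scale, computes the standardized deviation of the cell mean from the
#' global median,
#' `z = sqrt(n_cell) * |mean(cell) - median(all)| / MAD(all)`,
#' with the raw (unscaled) median absolute deviation in the denominator.
#' Cells with fewer than `min_n` points or `z > z_max` are flagged for
#' exclusion. The leading factor is `sqrt(n)` by default; set
#' `scale = "n"` for the literal cardinality.
#'
#' @param values drift-adjusted values on the adjustment scale.
#' @param day,instrument cell keys, same length as `values`.
#' @param min_n minimum measurements per cell (default 10).
#' @param z_max exclusion threshold (default 8).
#' @param scale `"sqrt_n"` (default) or `"n"` leading factor.
#' @return tibble with `day`, `instrument`, `n`, `z`, `excluded`, `reason`.
#' @export
aberrant_day_scores <- function(values, day, instrument,
                                min_n = 10, z_max = 8,
                                scale = c("sqrt_n", "n")) {
  scale <- match.arg(scale)
  ok <- !is.na(values)
  gmed <- median(values[ok])
  gmad <- median(abs(values[ok] - gmed))
  cells <- tibble(day = day[ok], instrument = instrument[ok],
                  value = values[ok]) |>
    group_by(.data$day, .data$instrument) |>
    summarise(n = dplyr::n(), cell_mean = mean(.data$value), .groups = "drop")
  if (!is.finite(gmad) || gmad == 0) {
    warn("Global MAD is zero: aberrant-day scores undefined; cells flagged for manual review.")
    return(cells |>
             mutate(z = NA_real_, excluded = .data$n < min_n,
                    reason = ifelse(.data$excluded, "cell_too_small",
                                    "mad_zero")))
  }
  fac <- if (scale == "sqrt_n") sqrt(cells$n) else cells$n
  cells |>
    mutate(z = fac * abs(.data$cell_mean - gmed) / gmad,
           excluded = .data$n < min_n | .data$z > z_max,
           reason = dplyr::case_when(
             .data$n < min_n ~ "cell_too_small",
             .data$z > z_max ~ "aberrant_day",
             TRUE ~ NA_character_))
}

# model frame of time covariates for the technical GAM
.technical_frame <- function(samples, index, reg) {
  scale <- reg$adjustment_scale[reg$index == index]
  day0 <- min(as.Date(samples$acq_time))
  acq <- samples$acq_time
  tibble(
    a = to_adjustment_scale(samples[[index]], scale),
    t = as.numeric(difftime(acq, as.POSIXct(day0, tz = "UTC"),
                            units = "days")),
    day = as.integer(as.Date(acq) - day0),
    t_day = as.numeric(acq - as.POSIXct(as.Date(acq), tz = "UTC")) / 3600,
    t_ven = as.numeric(difftime(acq, samples$ven_time, units = "hours")),
    t_year = as.numeric(format(acq, "%j")) - 1,
    wd = factor(format(acq, "%u"), levels = as.character(1:7)),
    m = factor(samples$instrument)
  )
}

# assemble and fit the stage-1 GAM on the rows in `mask`
.fit_technical_gam <- function(df, mask, knots) {
  fit_df <- df[mask, , drop = FALSE]
  fit_df$wd <- droplevels(fit_df$wd)
  # instruments need >= 3 distinct days of data to support a drift smooth;
  # others have the term dropped (drift evaluated at a constant, absorbed by
  # the instrument offset)
  days_per_m <- tapply(fit_df$day, fit_df$m, function(d) length(unique(d)))
  days_per_m[is.na(days_per_m)] <- 0
  good <- names(days_per_m)[days_per_m >= 3]
  if (!length(good)) abort("No instrument has enough distinct days to fit drift.")
  if (length(good) < nlevels(fit_df$m)) {
    bad <- setdiff(levels(fit_df$m), good)
    warn(paste0("Drift term dropped for instrument(s) with < 3 distinct days: ",
                paste(bad, collapse = ", ")))
  }
  ref <- good[1]
  prep <- function(d) {
    bad_row <- !(as.character(d$m) %in% good)
    d$m_drift <- factor(ifelse(bad_row, ref, as.character(d$m)),
                        levels = good)
    d$t_drift <- ifelse(bad_row, median(d$t[as.character(d$m) == ref]), d$t)
    d
  }
  fit_df <- prep(fit_df)
  kd <- max(4, min(knots$drift,
                   min(days_per_m[good]) - 1))
  n_per_m <- table(fit_df$m)
  kb <- max(4, min(knots$bivariate, min(n_per_m[n_per_m > 0]) - 1))
  ks <- max(4, min(knots$seasonal, length(unique(round(fit_df$t_year))) - 2))
  # each instrument gets its own smoothing parameter: calibration jumps on
  # one machine must not be smoothed away by another machine's gentle drift
  terms <- c("m", "wd",
             sprintf("s(t_drift, by = m_drift, bs = 'ps', k = %d)", kd),
             sprintf("s(t_day, t_ven, by = m, bs = 'tp', k = %d)", kb),
             sprintf("s(t_year, bs = 'cc', k = %d)", ks))
  form <- as.formula(paste("a ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = fit_df, method = "REML",
                   knots = list(t_year = c(0, 365.25)))
  list(fit = fit, prep = prep)
}

.predict_technical <- function(fitobj, df) {
  as.numeric(predict(fitobj$fit, newdata = fitobj$prep(df)))
}

#' Stage-1 technical and seasonal adjustment of a measured index
#'
#' Two-pass procedure on the adjustment scale: (1) fit the technical GAM
#' (per-instrument drift P-splines, per-instrument bivariate
#' time-of-day x venipuncture-delay thin-plate smooth, cyclic seasonal
#' spline, weekday and instrument offsets) on the central data (within
#' `central_k` scaled MADs of the median); (2) compute drift-adjusted values
#' for all data, score (day, instrument) cells with [aberrant_day_scores()]
#' and flag aberrant cells; (3) refit excluding aberrant cells and recompute
#' adjusted values. Adjusted values keep the original location (grand mean of
#' the fitted surface added back) so they remain valid on the index's natural
#' scale, and measurements from excluded cells are set missing.
#'
#' @param cohort a `cohort_dataset`.
#' @param index a measured index name present in the cohort.
#' @param knots basis dimensions, `list(drift =, bivariate =, seasonal =)`
#'   (defaults 50/30/30; capped by the available support).
#' @param central_k central-data threshold in scaled MADs (default 3.5).
#' @param mad_constant MAD scaling for the central mask (1.4826).
#' @param min_cell_n,z_max aberrant-day rule parameters (10 and 8).
#' @return a `technical_fit`: list with `index`, `adjusted` (tibble:
#'   `sample_id`, `raw`, `a_raw`, `a_adjusted`, `adjusted`, `excluded`,
#'   `reason`), `aberrant` (cell table), `fit` (the final mgcv fit),
#'   `scale`.
#' @export
technical_adjust <- function(cohort, index,
                             knots = list(drift = 50, bivariate = 30,
                                          seasonal = 30),
                             central_k = 3.5, mad_constant = 1.4826,
                             min_cell_n = 10, z_max = 8) {
  reg <- cohort$registry
  if (!index %in% reg$index[reg$role == "measured"]) {
    abort(sprintf("'%s' is not a measured index.", index))
  }
  samples <- cohort$samples
  df <- .technical_frame(samples, index, reg)
  scale <- reg$adjustment_scale[reg$index == index]

  central <- central_mask(df$a, central_k, mad_constant)
  pass1 <- .fit_technical_gam(df, central, knots)
  pred1 <- .predict_technical(pass1, df)
  drift_adj <- df$a - pred1 + mean(pred1, na.rm = TRUE)

  cells <- aberrant_day_scores(drift_adj, df$day, as.character(df$m),
                               min_n = min_cell_n, z_max = z_max)
  bad_cells <- cells[cells$excluded, c("day", "instrument")]
  in_bad <- paste(df$day, as.character(df$m)) %in%
    paste(bad_cells$day, bad_cells$instrument)

  pass2 <- .fit_technical_gam(df, central & !in_bad, knots)
  pred2 <- .predict_technical(pass2, df)
  a_adj <- df$a - pred2 + mean(pred2, na.rm = TRUE)
  a_adj[in_bad] <- NA_real_

  adjusted <- tibble(
    sample_id = samples$sample_id,
    raw = samples[[index]],
    a_raw = df$a,
    a_adjusted = a_adj,
    adjusted = from_adjustment_scale(a_adj, scale),
    excluded = in_bad | is.na(df$a),
    reason = dplyr::case_when(
      in_bad ~ "aberrant_cell",
      is.na(df$a) ~ "out_of_domain",
      TRUE ~ NA_character_))
  structure(list(index = index, scale = scale, adjusted = adjusted,
                 aberrant = cells, fit = pass2$fit),
            class = "technical_fit")
}

#' @export
print.technical_fit <- function(x, ...) {
  cat(sprintf("<technical_fit> %s (%s scale): %d values, %d excluded, %d aberrant cell(s)\n",
              x$index, x$scale, nrow(x$adjusted), sum(x$adjusted$excluded),
              sum(x$aberrant$excluded)))
  invisible(x)
}

#' Apply stage-1 adjustment to every measured index of a cohort
#'
#' Runs [technical_adjust()] per measured index, replaces the measured
#' columns by their adjusted values and recomputes the derived indices from
#' them (the stage ordering of the two-stage adjustment contract).
#'
#' @inheritParams technical_adjust
#' @param indices measured indices to adjust (default: all present).
#' @return list with `cohort` (samples updated, derived recomputed),
#'   `fits` (named list of `technical_fit`), `exclusions` (long tibble).
#' @export
technical_adjust_cohort <- function(cohort, indices = NULL, ...) {
  reg <- cohort$registry
  measured <- intersect(reg$index[reg$role == "measured"],
                        names(cohort$samples))
  if (!is.null(indices)) measured <- intersect(measured, indices)
  fits <- list()
  out <- cohort
  for (idx in measured) {
    tf <- technical_adjust(cohort, idx, ...)
    fits[[idx]] <- tf
    out$samples[[idx]] <- tf$adjusted$adjusted
  }
  out$samples <- derive_indices(out$samples)
  exclusions <- purrr::map_dfr(fits, function(tf) {
    tf$adjusted |>
      filter(.data$excluded) |>
      transmute(sample_id = .data$sample_id, index = tf$index,
                stage = "technical", reason = .data$reason)
  })
  list(cohort = out, fits = fits, exclusions = exclusions)
}
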