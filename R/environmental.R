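# Stage-2 adjustment: environmental and sex effects (age-by-menopause,
# body size, smoking, alcohol, days-since-last-period) removed by a
# penalized-spline additive model fitted on the central data.

#' Study-specific environmental term specification
#'
#' Studies with richer questionnaires ("B"-style) add a days-since-last-period
#' smooth (premenopausal women only) and a previous-day alcohol-quantity
#' smooth to the shared terms (age-by-menopause smooth, bivariate
#' log-height x log-weight smooth by menopause category, pack-years smooth,
#' categorical smoking and drinking variables).
#'
#' @param study study id; "B" enables the extra terms.
#' @param knots named list of basis dimensions.
#' @return a list term specification for [environmental_adjust()].
#' @export
environmental_terms <- function(study = c("A", "C", "B"),
                                knots = list(age = 30, body = 30,
                                             packyears = 10, alcohol = 30,
                                             period = 30)) {
  study <- match.arg(study)
  list(study = study,
       days_since_period = study == "B",
       alcohol_quantity = study == "B",
       knots = knots)
}

# mean-impute numeric covariates and add missingness dummies
.impute_covariates <- function(df, vars) {
  for (v in vars) {
    miss <- is.na(df[[v]])
    if (any(miss) && !all(miss)) {
      df[[paste0(v, "_missing")]] <- factor(ifelse(miss, "yes", "no"))
      df[[v]][miss] <- mean(df[[v]], na.rm = TRUE)
    } else if (all(miss)) {
      df[[v]] <- 0                         # term collapses to the intercept
    }
  }
  df
}

#' Stage-2 environmental and sex adjustment of an index
#'
#' Fits a penalized-spline model of the stage-1-adjusted index value (on the
#' adjustment scale) on age (smooth, by menopause category), log-height x
#' log-weight (bivariate smooth, by menopause category), pack-years of
#' smoking (smooth), categorical smoking and drinking variables, and -- for
#' study-B-style term specs -- days since last period (within premenopausal
#' women) and alcohol quantity. The fit uses the central data (within
#' `central_k` scaled MADs); residuals are computed for all data and
#' re-located to the original mean. Covariates with missing values are
#' mean-imputed with a missingness dummy. Applies to measured and derived
#' indices alike.
#'
#' @param cohort a `cohort_dataset` whose samples carry stage-1-adjusted
#'   index values.
#' @param index index name.
#' @param terms a specification from [environmental_terms()]; defaults to the
#'   cohort's study.
#' @param central_k,mad_constant central-data mask parameters.
#' @return an `environmental_fit`: list with `index`, `adjusted` (tibble:
#'   `sample_id`, `a_input`, `a_adjusted`, `adjusted`), `fit`, `scale`.
#' @export
environmental_adjust <- function(cohort, index, terms = NULL,
                                 central_k = 3.5, mad_constant = 1.4826) {
  terms <- terms %||%
    environmental_terms(if (cohort$study_id %in% c("A", "B", "C"))
      cohort$study_id else "A")
  reg <- cohort$registry
  if (!index %in% reg$index) abort(sprintf("Unknown index '%s'.", index))
  scale <- reg$adjustment_scale[reg$index == index]
  s <- cohort$samples
  kn <- terms$knots

  canonical <- c("male", "female-pre", "female-post", "female-hyst",
                 "no-answer", "unsure")
  df <- tibble(
    a = to_adjustment_scale(s[[index]], scale),
    age = s$age,
    sexmeno = factor(s$sexmeno, levels = canonical),
    lheight = log(s$height), lweight = log(s$weight),
    pack_years = s$pack_years,
    smoking_habit = factor(ifelse(is.na(s$smoking_habit), "no-answer",
                                  s$smoking_habit)),
    drinking_status = factor(ifelse(is.na(s$drinking_status), "no-answer",
                                    s$drinking_status)),
    drinking_habit = factor(ifelse(is.na(s$drinking_habit), "no-answer",
                                   s$drinking_habit))
  )
  absent <- setdiff(canonical, unique(as.character(df$sexmeno)))
  if (length(absent)) {
    warn(paste0("Menopause level(s) absent from data, dropped: ",
                paste(absent, collapse = ", ")))
  }
  df$sexmeno <- droplevels(df$sexmeno)
  num_vars <- c("pack_years")
  if (terms$alcohol_quantity) {
    df$alcohol_quantity <- s$alcohol_quantity
    num_vars <- c(num_vars, "alcohol_quantity")
  }
  if (terms$days_since_period) {
    df$dsp <- ifelse(s$sexmeno == "female-pre" & !is.na(s$days_since_period),
                     s$days_since_period, NA_real_)
    df$is_pre <- as.numeric(s$sexmeno == "female-pre")
    # impute within the smooth's own support; the by-indicator zeroes the
    # term for everyone else (male samples are untouched by it)
    df$dsp[is.na(df$dsp)] <- mean(df$dsp, na.rm = TRUE)
  }
  df <- .impute_covariates(df, num_vars)

  # cap factor-by basis dimensions by the thinnest level's support
  lvl_n <- table(df$sexmeno)
  ka <- max(4, min(kn$age, min(lvl_n) - 1, 30))
  kb <- max(4, min(kn$body, min(lvl_n) - 1, 30))
  smooth_ok <- function(v) length(unique(df[[v]])) > 8
  tt <- c(sprintf("s(age, by = sexmeno, bs = 'ps', k = %d, id = 1)", ka),
          sprintf("s(lheight, lweight, by = sexmeno, bs = 'tp', k = %d, id = 2)", kb),
          if (smooth_ok("pack_years"))
            sprintf("s(pack_years, bs = 'ps', k = %d)",
                    max(4, min(kn$packyears, 10))),
          "smoking_habit", "drinking_status", "drinking_habit")
  if (terms$alcohol_quantity && smooth_ok("alcohol_quantity")) {
    tt <- c(tt, sprintf("s(alcohol_quantity, bs = 'ps', k = %d)",
                        max(4, min(kn$alcohol, 10))))
  }
  if (terms$days_since_period && sum(df$is_pre) > 30) {
    tt <- c(tt, sprintf("s(dsp, by = is_pre, bs = 'ps', k = %d)",
                        max(4, min(kn$period, 10))))
  }
  tt <- c(tt, grep("_missing$", names(df), value = TRUE))
  form <- as.formula(paste("a ~", paste(tt, collapse = " + ")))

  central <- central_mask(df$a, central_k, mad_constant)
  fit <- mgcv::gam(form, data = df[central, , drop = FALSE],
                   method = "REML")
  pred <- as.numeric(predict(fit, newdata = df))
  a_adj <- df$a - pred + mean(pred, na.rm = TRUE)
  a_adj[is.na(df$a)] <- NA_real_
  structure(list(index = index, scale = scale,
                 adjusted = tibble(sample_id = s$sample_id,
                                   a_input = df$a, a_adjusted = a_adj,
                                   adjusted = from_adjustment_scale(a_adj,
                                                                    scale)),
                 fit = fit),
            class = "environmental_fit")
}

#' @export
print.environmental_fit <- function(x, ...) {
  cat(sprintf("<environmental_fit> %s (%s scale), %d values\n",
              x$index, x$scale, nrow(x$adjusted)))
  invisible(x)
}
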