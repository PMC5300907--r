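# broom-style tidiers and ggplot2 autoplot methods for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an MR result
#'
#' @param x an `mr_result`.
#' @param ... unused.
#' @return tibble with one row per index (`theta`, `se`, `p`, odds ratio and
#'   CI); the Egger intercept, when present, appears as an extra row with
#'   `index = "(intercept)"`.
#' @export
tidy.mr_result <- function(x, ...) {
  out <- as_tibble(x)
  int <- attr(x, "intercept")
  if (!is.null(int)) {
    out <- bind_rows(out, tibble(index = "(intercept)",
                                 theta = int$estimate, se = int$se,
                                 p = int$p))
  }
  out
}

#' @rdname tidy.mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = attr(x, "method"),
         n_instruments = attr(x, "n_instruments"),
         n_indices = sum(as_tibble(x)$index != "(intercept)"),
         sigma2 = attr(x, "sigma2"))
}

#' Tidy a conditional model
#'
#' @param x a `conditional_model` from [stepwise_select()].
#' @param ... unused.
#' @export
tidy.conditional_model <- function(x, ...) as_tibble(x)

#' @rdname tidy.conditional_model
#' @export
glance.conditional_model <- function(x, ...) {
  tibble(n_selected = nrow(x), r_squared = attr(x, "r_squared"),
         alpha = attr(x, "alpha"), n = attr(x, "n"),
         n_skipped_collinear = length(attr(x, "skipped")))
}

#' Forest plot of MR causal estimates
#'
#' Odds ratio of disease per SD of each index with 95% intervals.
#'
#' @param object an `mr_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$index)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_lo,
                                         xmax = .data$or_hi), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per SD of index", y = NULL,
                  title = attr(object, "method"))
}

#' Manhattan-style plot of meta-analysis results
#'
#' @param object a `meta_sumstats` tibble.
#' @param alpha significance line (default 8.31e-9).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.meta_sumstats <- function(object, alpha = 8.31e-9, ...) {
  d <- as_tibble(object) |> filter(.data$included, !is.na(.data$p))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6,
                                  y = -log10(pmax(.data$p, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "orange") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::guides(colour = "none")
}

#' Day-averaged raw vs technically adjusted index series
#'
#' Shows per-instrument day means before and after stage-1 adjustment; drift,
#' calibration jumps and seasonal oscillation visible in the raw panel should
#' be flat after adjustment.
#'
#' @param object a `technical_fit`.
#' @param cohort the `cohort_dataset` the fit came from.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.technical_fit <- function(object, cohort, ...) {
  s <- cohort$samples
  d <- tibble(day = as.integer(as.Date(s$acq_time) - min(as.Date(s$acq_time))),
              instrument = s$instrument,
              raw = object$adjusted$a_raw,
              adjusted = object$adjusted$a_adjusted) |>
    tidyr::pivot_longer(c("raw", "adjusted"), names_to = "stage") |>
    group_by(.data$day, .data$instrument, .data$stage) |>
    summarise(day_mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$day_mean,
                                  colour = .data$instrument)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~stage, ncol = 1) +
    ggplot2::labs(x = "study day", y = sprintf("%s (adjustment scale)",
                                               object$index))
}
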