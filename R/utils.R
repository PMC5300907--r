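# shared small helpers

#' Scaled median absolute deviation
#'
#' MAD with the 1.4826 normal-consistency factor by default, so thresholds
#' expressed in "median absolute deviations/SD" are comparable to ordinary
#' standard deviations for Gaussian data. Set `constant = 1` for the raw MAD.
#'
#' @param x numeric vector (NAs dropped).
#' @param constant consistency factor; 1.4826 (default) or 1 for the raw MAD.
#' @return scalar MAD.
#' @export
scaled_mad <- function(x, constant = 1.4826) {
  stats::mad(x, constant = constant, na.rm = TRUE)
}

# mask of points within `k` scaled MADs of the median; NAs are FALSE
central_mask <- function(x, k = 3.5, constant = 1.4826) {
  m <- median(x, na.rm = TRUE)
  s <- scaled_mad(x, constant)
  if (!is.finite(s) || s == 0) {
    return(!is.na(x))
  }
  !is.na(x) & abs(x - m) < k * s
}

# derive a child RNG seed from a base seed and a stage offset, kept < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483629)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
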