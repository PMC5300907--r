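# Adjustment scales: positive-support indices are modelled on the log scale,
# proportion-support indices (stored in percent units) on the logit scale.

#' Transform index values to their adjustment scale
#'
#' Positive-support indices map through `log`; proportion-support indices
#' (percent units, 0-100) map through `logit(value/100)`. Values outside the
#' domain (non-positive counts, percentages at or beyond the 0/100 boundary)
#' are flagged missing rather than mapped to infinities.
#'
#' @param value numeric vector on the natural (reported) scale.
#' @param scale `"log"` or `"logit"`, or a single row of
#'   [blood_index_registry()].
#' @return numeric vector on the adjustment scale, `NA` where undefined.
#' @seealso [from_adjustment_scale()]
#' @examples
#' to_adjustment_scale(1, "log")     # 0
#' to_adjustment_scale(50, "logit")  # 0
#' to_adjustment_scale(75, "logit")  # log(3)
#' @export
to_adjustment_scale <- function(value, scale) {
  scale <- .resolve_scale(scale)
  if (scale == "log") {
    out <- ifelse(!is.na(value) & value > 0, log(value), NA_real_)
  } else {
    p <- value / 100
    ok <- !is.na(p) & p > 0 & p < 1
    out <- ifelse(ok, log(p / (1 - p)), NA_real_)
  }
  out
}

#' Back-transform from the adjustment scale
#'
#' Inverse of [to_adjustment_scale()]; restores the input to machine
#' precision on the valid domain.
#'
#' @inheritParams to_adjustment_scale
#' @param value numeric vector on the adjustment scale.
#' @export
from_adjustment_scale <- function(value, scale) {
  scale <- .resolve_scale(scale)
  if (scale == "log") exp(value) else 100 * stats::plogis(value)
}

.resolve_scale <- function(scale) {
  if (is.data.frame(scale)) scale <- scale$adjustment_scale
  scale <- match.arg(scale, c("log", "logit"))
  scale
}
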