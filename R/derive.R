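#' Recompute derived blood indices from measured ones
#'
#' Applies the registry derivation formulas (e.g. HCT = RBC# x MCV / 10,
#' MCH = 10 x HGB / RBC#, PCT = PLT# x MPV / 10^4, percentages =
#' 100 x count / parent count) to a table of measured index values, in
#' dependency order. Zero denominators yield `NA` (flagged missing), never
#' infinities. Re-deriving a table that already carries consistent derived
#' columns is the identity.
#'
#' @param measured data frame with one column per measured index (natural
#'   units); extra columns are passed through untouched.
#' @param indices which derived indices to compute; default all whose
#'   measured parents are present.
#' @return tibble: the input plus (re)computed derived index columns.
#' @examples
#' derive_indices(tibble::tibble(RBC = 5, MCV = 90, HGB = 15))
#' @export
derive_indices <- function(measured, indices = NULL) {
  out <- as_tibble(measured)
  reg <- blood_index_registry()
  derived <- reg$index[reg$role == "derived"]
  todo <- if (is.null(indices)) derived else intersect(derived, indices)
  # .derivations is ordered so parents (WBC) precede children (percentages)
  for (idx in intersect(names(.derivations), todo)) {
    parents <- .derivation_parents[[idx]]
    if (!all(parents %in% names(out))) next
    val <- .derivations[[idx]](out)
    val[!is.finite(val)] <- NA_real_
    out[[idx]] <- val
  }
  out
}
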