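#' Gate a specimen observation by its postmortem interval
#'
#' Applies the framework's postmortem stability windows. A measurement is
#' `optimal` when the specimen was collected strictly before the best-within
#' target, `acceptable_flagged` when collected between the best-within target
#' (inclusive) and the maximum sampling PMI (inclusive), and `NS` (not
#' scorable) beyond the maximum or when the specimen was never collected.
#' `NS` always carries a reason; downstream domains inherit it.
#'
#' @param pmi_h Postmortem interval at collection, in hours (`NA` when the
#'   specimen was not collected).
#' @param window One validity-window row, from [validity_window()].
#' @param collected Whether the specimen was collected at all.
#' @return A list of class `mvi_validity` with `state` (one of `"optimal"`,
#'   `"acceptable_flagged"`, `"NS"`) and `reason` (non-empty for `NS`).
#' @examples
#' ref <- load_reference_set()
#' gate_specimen(12, validity_window(ref, "liver", "cyp"))
#' gate_specimen(60, validity_window(ref, "vitreous", "vitreous_chemistry"))
#' @export
gate_specimen <- function(pmi_h, window, collected = !is.na(pmi_h)) {
  status <- function(state, reason = "") {
    structure(list(state = state, reason = reason), class = "mvi_validity")
  }
  if (!isTRUE(collected)) {
    return(status("NS", "specimen not collected"))
  }
  if (!is.numeric(pmi_h) || length(pmi_h) != 1L || is.na(pmi_h)) {
    stop("input error: collected specimen requires a numeric PMI", call. = FALSE)
  }
  if (pmi_h < 0) {
    stop("input error: PMI must be non-negative", call. = FALSE)
  }
  if (pmi_h < window$best_within_h) {
    status("optimal")
  } else if (pmi_h <= window$max_pmi_h) {
    status("acceptable_flagged")
  } else {
    status("NS", sprintf("PMI exceeds maximum (%.1f h > %g h)",
                         pmi_h, window$max_pmi_h))
  }
}

is_ns <- function(status) identical(status$state, "NS")

#' @export
print.mvi_validity <- function(x, ...) {
  cat(x$state, if (nzchar(x$reason)) paste0(" (", x$reason, ")"), "\n",
      sep = "")
  invisible(x)
}
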