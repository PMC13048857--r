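# CMSP Core and the vitreous glucose/BHB contextual pattern.
#
# Both are interpretive reporting artifacts computed downstream of the
# domain scores; neither ever feeds back into MVI scoring or archetype
# assignment.

#' Compute the CMSP Core summary from the three anchor ordinals
#'
#' The Cytokine-Metabolic Suppression Profile Core aggregates the IL-6, CRP
#' and F2-isoprostane ordinals as an unweighted sum (0--9) with a fixed
#' four-level label: minimal (0--1), mild (2--4), moderate (5--7), severe
#' (8--9). Any NS anchor renders the core NS.
#'
#' @param il6_bin,crp_bin,redox_bin Ordinals 0--3, or `NA` for NS.
#' @return A list of class `mvi_cmsp` with the three bins, `core_sum`
#'   (`NA` when NS), `core_label`, and `ns_reason`.
#' @examples
#' cmsp_core(2, 1, 2)  # core 5, moderate
#' @export
cmsp_core <- function(il6_bin, crp_bin, redox_bin) {
  bins <- c(il6 = il6_bin, crp = crp_bin, redox = redox_bin)
  if (any(!is.na(bins) & !(bins %in% 0:3))) {
    stop("input error: CMSP anchor bins must be 0-3 or NS", call. = FALSE)
  }
  if (anyNA(bins)) {
    ns_from <- paste(names(bins)[is.na(bins)], collapse = ", ")
    return(structure(
      list(il6_bin = il6_bin, crp_bin = crp_bin, redox_bin = redox_bin,
           core_sum = NA_integer_, core_label = NA_character_,
           ns_reason = paste("anchor not scorable:", ns_from)),
      class = "mvi_cmsp"
    ))
  }
  s <- as.integer(sum(bins))
  label <- c("minimal", "minimal", "mild", "mild", "mild",
             "moderate", "moderate", "moderate", "severe", "severe")[s + 1L]
  structure(
    list(il6_bin = as.integer(il6_bin), crp_bin = as.integer(crp_bin),
         redox_bin = as.integer(redox_bin), core_sum = s,
         core_label = label, ns_reason = ""),
    class = "mvi_cmsp"
  )
}

#' Classify the vitreous glucose/BHB contextual pattern
#'
#' Descriptive pattern over the two vitreous ordinals: both 0--1 is minimal
#' deviation; glucose 2--3 with BHB 0--1 is the stress-hyperglycemia
#' pattern; BHB 2--3 with glucose 0--1 is the ketosis pattern; both 2--3 is
#' mixed dysregulation. Any NS input yields indeterminate (the printed NS
#' row keys on BHB; NS handling is applied symmetrically rather than
#' interpreting a half-scorable pair). The pattern is contextual only and
#' never modifies CMSP Core, MVI scoring or archetype assignment.
#'
#' @param glucose_bin,bhb_bin Vitreous ordinals 0--3, or `NA` for NS.
#' @return A list of class `mvi_vitreous` with the bins and `label` (one of
#'   `"minimal_deviation"`, `"stress_hyperglycemia"`, `"ketosis"`,
#'   `"mixed_dysregulation"`, `"indeterminate_NS"`).
#' @export
vitreous_pattern <- function(glucose_bin, bhb_bin) {
  for (b in c(glucose_bin, bhb_bin)) {
    if (!is.na(b) && !(b %in% 0:3)) {
      stop("input error: vitreous bins must be 0-3 or NS", call. = FALSE)
    }
  }
  label <- if (is.na(glucose_bin) || is.na(bhb_bin)) {
    "indeterminate_NS"
  } else if (glucose_bin >= 2 && bhb_bin >= 2) {
    "mixed_dysregulation"
  } else if (glucose_bin >= 2) {
    "stress_hyperglycemia"
  } else if (bhb_bin >= 2) {
    "ketosis"
  } else {
    "minimal_deviation"
  }
  structure(
    list(glucose_bin = glucose_bin, bhb_bin = bhb_bin, label = label),
    class = "mvi_vitreous"
  )
}

#' @export
print.mvi_cmsp <- function(x, ...) {
  if (is.na(x$core_sum)) {
    cat("CMSP Core: NS —", x$ns_reason, "\n")
  } else {
    cat(sprintf("CMSP Core: %d/9 (%s) [IL-6 %d, CRP %d, redox %d]\n",
                x$core_sum, x$core_label, x$il6_bin, x$crp_bin, x$redox_bin))
  }
  invisible(x)
}

#' @export
print.mvi_vitreous <- function(x, ...) {
  cat(sprintf("Vitreous context: %s (glucose %s, BHB %s)\n", x$label,
              ifelse(is.na(x$glucose_bin), "NS", x$glucose_bin),
              ifelse(is.na(x$bhb_bin), "NS", x$bhb_bin)))
  invisible(x)
}
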