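# Domains 2-5: cytokine and redox anchors, adjudicated modifier domains.

#' Construct a per-domain ordinal score
#'
#' Domains 1--3 are core domains; 4 and 5 are modifier domains. A score of
#' `NA` denotes NS (not scorable) and must carry a reason.
#'
#' @param domain Domain number 1--5.
#' @param score Integer 0--3, or `NA` for NS.
#' @param ns_reason Reason string, required when `score` is `NA`.
#' @param basis Free-text description of the scored anchor.
#' @param flags Character vector of advisory flags.
#' @return A list of class `mvi_domain_score` with fields `domain`, `name`,
#'   `role` (`"core"` for 1--3, `"modifier"` for 4--5), `score`, `ns`,
#'   `ns_reason`, `basis`, `flags`.
#' @export
domain_score <- function(domain, score, ns_reason = "", basis = "",
                         flags = character()) {
  domain <- as.integer(domain)
  stopifnot(domain %in% 1:5)
  ns <- is.na(score)
  if (!ns && !(score %in% 0:3)) {
    stop("input error: domain score must be 0-3 or NS", call. = FALSE)
  }
  if (ns && !nzchar(ns_reason)) {
    stop("input error: NS domain score requires a reason", call. = FALSE)
  }
  structure(
    list(domain = domain, name = MVI_DOMAIN_NAMES[domain],
         role = if (domain <= 3L) "core" else "modifier",
         score = as.integer(score), ns = ns,
         ns_reason = if (ns) ns_reason else "",
         basis = basis, flags = flags),
    class = "mvi_domain_score"
  )
}

#' @export
print.mvi_domain_score <- function(x, ...) {
  cat(sprintf("Domain %d (%s, %s): %s\n", x$domain, x$name, x$role,
              if (x$ns) paste0("NS — ", x$ns_reason) else x$score))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Bin an analyte value into its ordinal severity tier
#'
#' Bin edges are lower-inclusive on the normal side: `value <= e0` scores 0,
#' `(e0, e1]` scores 1, `(e1, e2]` scores 2, `> e2` scores 3. A value
#' exactly on a printed shared edge therefore falls in the lower bin.
#'
#' @param value Non-negative measurement (vectorized).
#' @param spec One row of `load_reference_set()$bin_specs`, or an analyte
#'   name plus `ref`.
#' @param ref Reference set, used when `spec` is an analyte name.
#' @return Integer vector of ordinal scores 0--3.
#' @examples
#' ref <- load_reference_set()
#' bin_analyte(c(30, 350), "IL6", ref)  # 0, 3
#' @export
bin_analyte <- function(value, spec, ref = NULL) {
  if (is.character(spec)) {
    stopifnot(!is.null(ref))
    spec <- ref$bin_specs[ref$bin_specs$analyte == spec, , drop = FALSE]
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop("input error: analyte values must be non-negative", call. = FALSE)
  }
  as.integer((value > spec$e0) + (value > spec$e1) + (value > spec$e2))
}

#' Score Domain 2 (cytokine load)
#'
#' IL-6 and CRP (femoral serum/plasma) are binned independently and the
#' domain ordinal is the maximum over the available markers — either marker
#' alone is sufficient evidence of severity. NS when femoral blood fails
#' PMI validity or neither marker is available.
#'
#' @param il6_pg_ml,crp_mg_l Marker values (`NA` when unavailable).
#' @param blood_validity `mvi_validity` for femoral blood.
#' @param ref Reference set.
#' @return An `mvi_domain_score` for domain 2, with `il6_bin`/`crp_bin`
#'   fields (NA when the marker is absent or blood is NS).
#' @export
score_domain2 <- function(il6_pg_ml, crp_mg_l, blood_validity, ref) {
  if (is_ns(blood_validity)) {
    sc <- domain_score(2L, NA_integer_, ns_reason = blood_validity$reason,
                       basis = "femoral IL-6/CRP")
    sc$il6_bin <- NA_integer_
    sc$crp_bin <- NA_integer_
    return(sc)
  }
  flags <- if (blood_validity$state == "acceptable_flagged") {
    "femoral blood PMI in acceptable-but-flagged window"
  } else character()
  il6_bin <- if (is.na(il6_pg_ml)) NA_integer_ else
    bin_analyte(il6_pg_ml, "IL6", ref)
  crp_bin <- if (is.na(crp_mg_l)) NA_integer_ else
    bin_analyte(crp_mg_l, "CRP", ref)
  bins <- c(il6_bin, crp_bin)
  if (all(is.na(bins))) {
    sc <- domain_score(2L, NA_integer_, ns_reason = "no cytokine markers",
                       basis = "femoral IL-6/CRP", flags = flags)
  } else {
    used <- c("IL-6", "CRP")[!is.na(bins)]
    sc <- domain_score(2L, max(bins, na.rm = TRUE),
                       basis = paste0("max over ", paste(used, collapse = ", ")),
                       flags = flags)
  }
  sc$il6_bin <- il6_bin
  sc$crp_bin <- crp_bin
  sc
}

#' Score Domain 3 (redox balance)
#'
#' Tissue F2-isoprostanes (8-iso-PGF2alpha) expressed as fold over the
#' laboratory reference. Liver is the default tissue; a kidney-cortex value
#' is scored when no liver value exists but is flagged as corroborative
#' tissue only. NS when the scoring tissue fails PMI validity or no value
#' is available.
#'
#' @param redox_fold Fold-over-reference value (`NA` when unavailable).
#' @param tissue `"liver"` or `"kidney"`.
#' @param tissue_validity `mvi_validity` for the tissue the value came from.
#' @param ref Reference set.
#' @return An `mvi_domain_score` for domain 3 with a `redox_bin` field.
#' @export
score_domain3 <- function(redox_fold, tissue, tissue_validity, ref) {
  if (is_ns(tissue_validity)) {
    sc <- domain_score(3L, NA_integer_, ns_reason = tissue_validity$reason,
                       basis = "tissue F2-isoprostanes")
    sc$redox_bin <- NA_integer_
    return(sc)
  }
  flags <- if (tissue_validity$state == "acceptable_flagged") {
    sprintf("%s PMI in acceptable-but-flagged window", tissue)
  } else character()
  if (is.na(redox_fold)) {
    sc <- domain_score(3L, NA_integer_, ns_reason = "no redox measurement",
                       basis = "tissue F2-isoprostanes", flags = flags)
    sc$redox_bin <- NA_integer_
    return(sc)
  }
  if (identical(tissue, "kidney")) {
    flags <- c(flags, "corroborative tissue only (kidney cortex, no liver value)")
  }
  bin <- bin_analyte(redox_fold, "F2_ISOPROSTANE_FOLD", ref)
  sc <- domain_score(3L, bin,
                     basis = sprintf("F2-isoprostane fold (%s)", tissue),
                     flags = flags)
  sc$redox_bin <- bin
  sc
}

#' Score a modifier domain from an adjudicated ordinal
#'
#' Domains 4 (neurochemical integrity) and 5 (xenobiotic/metal burden) have
#' no printed bin tables; their ordinals are adjudicated from the anchor
#' workups (brainstem neuropathology with serotonergic IHC; comprehensive
#' toxicology with ICP-MS metals) and validated here as a pass-through.
#'
#' @param domain `"neurochemical"` (domain 4) or `"xenobiotic_metal"`
#'   (domain 5).
#' @param score Adjudicated ordinal 0--3, or `NA` for NS.
#' @param basis Non-empty description of the adjudication basis (required
#'   when scored).
#' @param ns_reason Reason, required when `score` is `NA`.
#' @return An `mvi_domain_score` for domain 4 or 5.
#' @export
score_modifier <- function(domain, score, basis = "",
                           ns_reason = "adjudication not available") {
  d <- switch(domain, neurochemical = 4L, xenobiotic_metal = 5L,
              stop("input error: unknown modifier domain '", domain, "'",
                   call. = FALSE))
  if (!is.na(score) && !(score %in% 0:3)) {
    stop("input error: adjudicated ordinal must be 0-3 or NS", call. = FALSE)
  }
  if (!is.na(score) && !nzchar(basis)) {
    stop("input error: scored adjudicated ordinal requires a basis",
         call. = FALSE)
  }
  domain_score(d, score, ns_reason = ns_reason, basis = basis)
}
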