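# Domain 1: hepatic CYP capacity.
#
# Two-step normalization keeps physiologic immaturity from being read as
# suppression: a measured value is first expressed as %Adult against the
# adult reference scalar, then compared with the age-matched developmental
# expectation for its isoform and measure.  Protein abundance is the primary
# (postmortem-stable) anchor; QC-qualified probe activity substitutes only
# when no protein value exists for an isoform.

#' Normalize a measured CYP value to percent of the adult reference
#'
#' Protein abundance is normalized against the published adult mean;
#' probe activity against the midpoint of the published adult range (no
#' adult activity mean is printed). A plausibility flag is raised when the
#' result exceeds 150 %Adult or the raw value exceeds the printed adult
#' maximum; the flag never alters scoring.
#'
#' @param value Measured value (pmol/mg for protein; pmol/min/mg for
#'   activity), non-negative.
#' @param isoform One of `"CYP3A4"`, `"CYP2D6"`, `"CYP2C19"`, `"CYP3A5"`.
#' @param measure `"protein_abundance"` or `"probe_activity"`.
#' @param ref An `mvi_reference_set`.
#' @return A list with `pct_adult` and `plausibility_flag`.
#' @examples
#' ref <- load_reference_set()
#' normalize_to_adult(42.9, "CYP3A4", "protein_abundance", ref)$pct_adult # 50
#' @export
normalize_to_adult <- function(value, isoform, measure, ref) {
  stopifnot(isoform %in% MVI_ISOFORMS, measure %in% MVI_MEASURES)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      !is.finite(value) || value < 0) {
    stop("input error: measured value must be a finite non-negative number",
         call. = FALSE)
  }
  if (measure == "protein_abundance") {
    row <- ref$adult_protein[ref$adult_protein$isoform == isoform, ]
    scalar <- row$mean
  } else {
    row <- ref$adult_activity[ref$adult_activity$isoform == isoform, ]
    scalar <- (row$range_low + row$range_high) / 2
  }
  if (!is.finite(scalar) || scalar <= 0) {
    stop("configuration error: adult reference scalar for ", isoform, " (",
         measure, ") must be strictly positive", call. = FALSE)
  }
  pct <- 100 * value / scalar
  list(
    pct_adult = pct,
    plausibility_flag = pct > 150 || value > row$range_high
  )
}

#' Grade a normalized CYP value against age-matched expectations
#'
#' The %Adult value is compared with the developmental tier table for the
#' isoform and measure at the decedent's age bin. Tiers are half-open
#' intervals keyed by the printed lower edges: normal `[normal_min, Inf)`
#' scores 0, mild `[mild_low, normal_min)` scores 1, moderate
#' `[moderate_low, mild_low)` scores 2, severe `[0, moderate_low)` scores 3.
#' A value exactly at the printed age-bin minimum therefore grades normal.
#'
#' Special cases: at ages where the isoform's capacity is physiologically
#' near zero the row carries no tiers and the grade is `not_gradable`;
#' CYP3A5 non-expressors are never graded for suppression and receive
#' `genotype_zeroed` (physiologic score 0) regardless of the measured value.
#' Unknown or indeterminate CYP3A5 genotype is graded as an expressor.
#'
#' @param pct_adult Percent of adult reference (non-negative scalar).
#' @param isoform,measure Isoform and measure identifying the tier table.
#' @param age_days Age at death in days.
#' @param genotype CYP3A5 genotype class (`"expressor"`, `"non_expressor"`,
#'   `"unknown"`); ignored for other isoforms.
#' @param ref An `mvi_reference_set`.
#' @return A list of class `mvi_isoform_grade` with `isoform`, `measure`,
#'   `pct_adult`, `tier` (`"normal"`, `"mild"`, `"moderate"`, `"severe"`,
#'   `"not_gradable"` or `"genotype_zeroed"`), `score` (0--3, `NA` when
#'   not gradable) and `age_bin`.
#' @export
grade_isoform <- function(pct_adult, isoform, measure, age_days,
                          genotype = "unknown", ref) {
  stopifnot(isoform %in% MVI_ISOFORMS, measure %in% MVI_MEASURES,
            genotype %in% MVI_GENOTYPES)
  if (pct_adult < 0) stop("input error: pct_adult must be non-negative",
                          call. = FALSE)
  table <- ref$tier_tables[[paste(isoform, measure, sep = ".")]]
  bin <- resolve_age_bin(table, age_days)
  out <- function(tier, score) {
    structure(list(isoform = isoform, measure = measure,
                   pct_adult = pct_adult, tier = tier, score = score,
                   age_bin = bin$label),
              class = "mvi_isoform_grade")
  }
  if (isoform == "CYP3A5" && genotype == "non_expressor") {
    return(out("genotype_zeroed", 0L))
  }
  if (!bin$gradable) {
    return(out("not_gradable", NA_integer_))
  }
  if (pct_adult >= bin$normal_min) {
    out("normal", 0L)
  } else if (pct_adult >= bin$mild_low) {
    out("mild", 1L)
  } else if (pct_adult >= bin$moderate_low) {
    out("moderate", 2L)
  } else {
    out("severe", 3L)
  }
}

# Select the scoring measurement per isoform: protein primary, QC-qualified
# activity only where no protein value exists; a co-existing activity value
# is carried as corroboration only.
.select_cyp_measurements <- function(measurements) {
  scored <- list()
  corroborative <- character()
  dropped <- character()
  for (iso in unique(measurements$isoform)) {
    m <- measurements[measurements$isoform == iso, , drop = FALSE]
    prot <- m[m$measure == "protein_abundance", , drop = FALSE]
    act <- m[m$measure == "probe_activity", , drop = FALSE]
    if (nrow(prot)) {
      scored[[iso]] <- prot[1, ]
      if (nrow(act)) {
        corroborative <- c(corroborative,
          sprintf("%s activity reported as corroboration only", iso))
      }
    } else if (nrow(act) && isTRUE(act$qc_qualified[1])) {
      scored[[iso]] <- act[1, ]
    } else if (nrow(act)) {
      dropped <- c(dropped,
        sprintf("%s activity not QC-qualified; excluded", iso))
    }
  }
  list(scored = scored, notes = c(corroborative, dropped))
}

#' Score Domain 1 (hepatic CYP capacity)
#'
#' Normalizes and grades every usable isoform measurement and aggregates to
#' the domain ordinal as the maximum (worst) tier over gradable isoforms.
#' Isoforms that are not gradable at the decedent's age, or genotype-zeroed
#' CYP3A5, are excluded from the maximum (a genotype-zeroed isoform still
#' anchors a score of 0 when it is the only one). The domain is `NS` when
#' the liver specimen fails PMI validity, when no measurements exist, or
#' when no isoform is gradable at the age.
#'
#' @param measurements Data frame with columns `isoform`, `measure`,
#'   `value`, `qc_qualified` (logical, activity only).
#' @param genotype CYP3A5 genotype class.
#' @param age_days Age at death in days.
#' @param liver_validity An `mvi_validity` for the liver CYP specimen.
#' @param ref An `mvi_reference_set`.
#' @return A `mvi_domain_score` (see [domain_score()]) for domain 1, with
#'   per-isoform grades attached as the `grades` attribute-like field.
#' @export
score_domain1 <- function(measurements, genotype, age_days, liver_validity,
                          ref) {
  if (is_ns(liver_validity)) {
    return(domain_score(1L, NA_integer_, ns_reason = liver_validity$reason,
                        basis = "hepatic CYP panel"))
  }
  flags <- if (liver_validity$state == "acceptable_flagged") {
    "liver PMI in acceptable-but-flagged window"
  } else character()
  if (is.null(measurements) || nrow(measurements) == 0L) {
    return(domain_score(1L, NA_integer_, ns_reason = "no CYP measurements",
                        basis = "hepatic CYP panel", flags = flags))
  }
  sel <- .select_cyp_measurements(measurements)
  flags <- c(flags, sel$notes)
  grades <- list()
  for (iso in names(sel$scored)) {
    m <- sel$scored[[iso]]
    norm <- normalize_to_adult(m$value, iso, m$measure, ref)
    g <- grade_isoform(norm$pct_adult, iso, m$measure, age_days, genotype,
                       ref)
    g$plausibility_flag <- norm$plausibility_flag
    if (norm$plausibility_flag) {
      flags <- c(flags, sprintf(
        "%s %s %.1f %%Adult exceeds plausibility bounds", iso, m$measure,
        norm$pct_adult))
    }
    grades[[iso]] <- g
  }
  scores <- vapply(grades, function(g) g$score, integer(1))
  tiers <- vapply(grades, function(g) g$tier, character(1))
  gradable <- tiers %in% c("normal", "mild", "moderate", "severe")
  zeroed <- tiers == "genotype_zeroed"
  if (!any(gradable)) {
    if (any(zeroed)) {
      # genotype-zeroed CYP3A5 as sole isoform anchors a physiologic 0
      sc <- domain_score(1L, 0L, basis = "CYP3A5 genotype-zeroed only",
                         flags = flags)
    } else {
      sc <- domain_score(1L, NA_integer_,
                         ns_reason = "no gradable isoform at this age",
                         basis = "hepatic CYP panel", flags = flags)
    }
  } else {
    sc <- domain_score(1L, max(scores[gradable]),
                       basis = paste0("max tier over gradable isoforms (",
                                      paste(names(grades)[gradable],
                                            collapse = ", "), ")"),
                       flags = flags)
  }
  sc$grades <- grades
  sc
}
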