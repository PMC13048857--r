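# Final report assembly: specimen gating -> domain scoring -> CMSP and
# vitreous context -> archetype -> totals.  Deterministic: identical inputs
# give byte-identical serialized reports.

.gate_for <- function(case, specimen, analyte_group, ref) {
  hit <- case$specimens[case$specimens$specimen == specimen, , drop = FALSE]
  if (nrow(hit) == 0L || !isTRUE(hit$collected[1])) {
    return(gate_specimen(NA_real_, validity_window(ref, specimen,
                                                   analyte_group),
                         collected = FALSE))
  }
  gate_specimen(hit$pmi_h[1], validity_window(ref, specimen, analyte_group))
}

#' Compute the full MVI report for one case
#'
#' Runs the pipeline in order: specimen PMI gating, Domain 1 CYP capacity
#' (two-step normalization), Domains 2--3 biomarker binning, Domains 4--5
#' adjudicated pass-through, CMSP Core and the vitreous contextual pattern,
#' archetype assignment, and totals. The MVI total is the sum of scorable
#' domain ordinals and is reported against a scorable maximum of 3 times
#' the number of scorable domains (NS domains shrink the denominator
#' instead of being imputed as 0). Vitreous markers and the CMSP summary
#' are computed downstream of the domain scores and never feed back into
#' them.
#'
#' @param case An `mvi_case` (see [case_record()]).
#' @param ref An `mvi_reference_set` from [load_reference_set()].
#' @return An object of class `mvi_report`: `case_id`, `domain_scores`
#'   (list of five `mvi_domain_score`), `mvi_total`, `scorable_max`,
#'   `archetype`, `cmsp`, `vitreous`, `flags`, `reference_set_version`.
#' @examples
#' ref <- load_reference_set()
#' case <- generate_case(targets = c(3, 2, 2, 1, 2), age_days = 200,
#'                       seed = 1, ref = ref)
#' compute_mvi(case, ref)
#' @export
compute_mvi <- function(case, ref = load_reference_set()) {
  problems <- validate_case_record(case)
  if (length(problems)) {
    stop("input error in case record '", case$case_id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  liver_cyp <- .gate_for(case, "liver", "cyp", ref)
  blood <- .gate_for(case, "femoral_blood", "cytokines", ref)
  vitreous_gate <- .gate_for(case, "vitreous", "vitreous_chemistry", ref)

  d1 <- score_domain1(case$cyp_measurements, case$cyp3a5_genotype,
                      case$age_days, liver_cyp, ref)

  d2 <- score_domain2(case$biomarkers$il6_pg_ml, case$biomarkers$crp_mg_l,
                      blood, ref)

  redox_tissue <- case$biomarkers$redox_tissue
  redox_gate <- .gate_for(case, redox_tissue, "redox", ref)
  redox_fold <- case$biomarkers$redox_fold
  if (is.na(redox_fold) && !is.na(case$biomarkers$redox_ng_g)) {
    if (is.na(ref$redox_reference)) {
      redox_fold <- NA_real_
    } else {
      redox_fold <- case$biomarkers$redox_ng_g / ref$redox_reference
    }
  }
  d3 <- score_domain3(redox_fold, redox_tissue, redox_gate, ref)
  if (d3$ns && is.na(redox_fold) && !is.na(case$biomarkers$redox_ng_g) &&
      is.na(ref$redox_reference)) {
    d3$ns_reason <- "raw redox value supplied but no laboratory redox reference configured"
  }

  adj_score <- function(domain) {
    hit <- case$adjudicated[case$adjudicated$domain == domain, ,
                            drop = FALSE]
    if (nrow(hit) == 0L) {
      return(score_modifier(domain, NA_integer_,
                            ns_reason = "adjudication not available"))
    }
    score_modifier(domain, hit$score[1], basis = hit$basis[1],
                   ns_reason = if (nzchar(hit$ns_reason[1]))
                     hit$ns_reason[1] else "adjudicated NS")
  }
  d4 <- adj_score("neurochemical")
  d5 <- adj_score("xenobiotic_metal")

  domains <- list(d1, d2, d3, d4, d5)
  scores <- vapply(domains, function(d)
    if (d$ns) NA_integer_ else d$score, integer(1))

  archetype <- assign_archetype(scores)
  cmsp <- cmsp_core(d2$il6_bin, d2$crp_bin, d3$redox_bin)

  vit_bin <- function(value, analyte) {
    if (is_ns(vitreous_gate) || is.na(value)) NA_integer_
    else bin_analyte(value, analyte, ref)
  }
  vitreous <- vitreous_pattern(
    vit_bin(case$biomarkers$vitreous_glucose_mmol_l, "VITREOUS_GLUCOSE"),
    vit_bin(case$biomarkers$vitreous_bhb_mmol_l, "VITREOUS_BHB"))

  scorable <- !is.na(scores)
  flags <- unlist(lapply(domains, function(d)
    if (length(d$flags)) sprintf("D%d: %s", d$domain, d$flags) else NULL))
  flags <- c(flags, archetype$flags,
             unlist(lapply(domains, function(d)
               if (d$ns) sprintf("D%d NS: %s", d$domain, d$ns_reason)
               else NULL)))

  structure(
    list(case_id = case$case_id,
         domain_scores = domains,
         mvi_total = as.integer(sum(scores[scorable])),
         scorable_max = as.integer(3L * sum(scorable)),
         archetype = archetype,
         cmsp = cmsp,
         vitreous = vitreous,
         flags = if (is.null(flags)) character() else unname(flags),
         reference_set_version = ref$version),
    class = "mvi_report"
  )
}

#' Score a batch of cases
#'
#' @param cases List of `mvi_case` records.
#' @param ref Reference set.
#' @return A list of `mvi_report` objects, one per case, in input order.
#' @export
compute_mvi_batch <- function(cases, ref = load_reference_set()) {
  lapply(cases, compute_mvi, ref = ref)
}

#' Serialize an MVI report to JSON
#'
#' Stable field ordering and full numeric precision: identical inputs
#' always produce byte-identical JSON.
#'
#' @param report An `mvi_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  x <- list(
    case_id = report$case_id,
    reference_set_version = report$reference_set_version,
    mvi_total = report$mvi_total,
    scorable_max = report$scorable_max,
    domain_scores = lapply(report$domain_scores, function(d)
      list(domain = d$domain, name = d$name, role = d$role,
           score = if (d$ns) "NS" else d$score,
           ns_reason = d$ns_reason, basis = d$basis, flags = d$flags)),
    archetype = list(
      ref_no = report$archetype$ref_no,
      mechanistic_class = report$archetype$mechanistic_class,
      core_domains = report$archetype$core_domains,
      modifier_domains = report$archetype$modifier_domains,
      referral_trail = report$archetype$referral_trail,
      dominance_note = report$archetype$dominance_note),
    cmsp = unclass(report$cmsp),
    vitreous = unclass(report$vitreous),
    flags = report$flags
  )
  json <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.mvi_report <- function(x, ...) {
  cat("=== MVI report: case '", x$case_id, "' ===\n", sep = "")
  for (d in x$domain_scores) print(d)
  cat(sprintf("MVI total: %d / %d scorable\n", x$mvi_total, x$scorable_max))
  print(x$archetype)
  print(x$cmsp)
  print(x$vitreous)
  if (length(x$flags)) {
    cat("Flags:\n")
    for (f in x$flags) cat("  -", f, "\n")
  }
  cat("Reference set:", x$reference_set_version, "\n")
  invisible(x)
}

#' Render an MVI report as a plain-text/markdown summary
#'
#' @param report An `mvi_report`.
#' @return Character vector of markdown lines.
#' @export
report_to_markdown <- function(report) {
  sc <- vapply(report$domain_scores, function(d)
    if (d$ns) "NS" else as.character(d$score), character(1))
  lines <- c(
    sprintf("## MVI report: %s", report$case_id),
    "",
    "| Domain | Role | Score |",
    "|---|---|---|",
    vapply(seq_along(report$domain_scores), function(i) {
      d <- report$domain_scores[[i]]
      sprintf("| %d %s | %s | %s |", d$domain, d$name, d$role, sc[i])
    }, character(1)),
    "",
    sprintf("**MVI total:** %d / %d scorable", report$mvi_total,
            report$scorable_max),
    sprintf("**Archetype:** %s",
            if (is.na(report$archetype$ref_no))
              report$archetype$mechanistic_class
            else sprintf("#%d %s", report$archetype$ref_no,
                         report$archetype$mechanistic_class)),
    sprintf("**CMSP Core:** %s",
            if (is.na(report$cmsp$core_sum))
              paste("NS -", report$cmsp$ns_reason)
            else sprintf("%d/9 (%s)", report$cmsp$core_sum,
                         report$cmsp$core_label)),
    sprintf("**Vitreous context:** %s", report$vitreous$label)
  )
  if (length(report$flags)) {
    lines <- c(lines, "", "Flags:", paste0("- ", report$flags))
  }
  lines
}
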