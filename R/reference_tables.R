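#' Load the MVI reference set
#'
#' Assembles the complete set of lookup tables the scoring engine runs on:
#' adult hepatic CYP references (protein means and plausibility ranges;
#' probe-activity ranges), age-matched developmental tier tables for the four
#' isoforms in both measures, ordinal bin edges for the cytokine, redox and
#' vitreous analytes, and per-specimen postmortem-interval validity windows.
#'
#' Built-in values are framework constants. A laboratory may override only
#' the adult references and the redox laboratory reference, via a YAML/JSON
#' file or an equivalent list; developmental tier fractions, ordinal bin
#' edges and validity windows are fixed by design and cannot be overridden.
#'
#' @param config Optional laboratory override: a path to a YAML or JSON file,
#'   or a list, of the form
#'   `list(adult_protein = list(CYP3A4 = list(mean =, range_low =, range_high =)),
#'         adult_activity = list(CYP2D6 = list(range_low =, range_high =)),
#'         redox_reference = <ng/g>)`.
#'   Unspecified fields keep their built-in values.
#' @return An object of class `mvi_reference_set`: a list with elements
#'   `version` (string identifying the table build and any override),
#'   `adult_protein`, `adult_activity`, `tier_tables`, `bin_specs`,
#'   `validity_windows`, and `redox_reference` (ng/g, `NA` unless configured).
#' @examples
#' ref <- load_reference_set()
#' ref$adult_protein
#' resolve_age_bin(ref$tier_tables$CYP3A4.protein_abundance, 200)
#' @export
load_reference_set <- function(config = NULL) {
  ref <- structure(
    list(
      version = "builtin-1.0",
      adult_protein = .adult_protein_refs(),
      adult_activity = .adult_activity_refs(),
      tier_tables = .tier_tables(),
      bin_specs = .bin_specs(),
      validity_windows = .validity_windows(),
      redox_reference = NA_real_
    ),
    class = "mvi_reference_set"
  )
  if (!is.null(config)) {
    ref <- .apply_reference_overrides(ref, .read_config(config))
    ref$version <- paste0("builtin-1.0+lab-", .stable_hash(ref))
  }
  validate_reference_set(ref)
  ref
}

.read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || length(config) != 1L || !file.exists(config)) {
    stop("configuration error: config must be a list or an existing file path",
         call. = FALSE)
  }
  if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

.apply_reference_overrides <- function(ref, cfg) {
  allowed <- c("adult_protein", "adult_activity", "redox_reference")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("configuration error: non-overridable section(s): ",
         paste(bad, collapse = ", "),
         " (tier fractions, bin edges and validity windows are framework constants)",
         call. = FALSE)
  }
  for (table in c("adult_protein", "adult_activity")) {
    for (iso in names(cfg[[table]])) {
      if (!iso %in% MVI_ISOFORMS) {
        stop("configuration error: table '", table, "': unknown isoform '",
             iso, "'", call. = FALSE)
      }
      row <- which(ref[[table]]$isoform == iso)
      entry <- cfg[[table]][[iso]]
      fields <- intersect(names(entry),
                          c("mean", "sd", "range_low", "range_high"))
      for (f in fields) ref[[table]][row, f] <- as.numeric(entry[[f]])
    }
  }
  if (!is.null(cfg$redox_reference)) {
    ref$redox_reference <- as.numeric(cfg$redox_reference)
  }
  ref
}

#' Validate a reference set against the framework's structural invariants
#'
#' Checks every table: ranges ordered, protein means strictly positive, tier
#' edges strictly ordered within gradable rows, normal minima non-decreasing
#' across gradable age bins, age bins partitioning `[0, Inf)`, ordinal bin
#' edges ascending, and validity windows with best-within at most max PMI.
#'
#' @param ref An `mvi_reference_set`.
#' @return `ref`, invisibly; a configuration error is signalled naming the
#'   offending table and row otherwise.
#' @export
validate_reference_set <- function(ref) {
  fail <- function(tab, row, msg) {
    stop("configuration error in ", tab, " (", row, "): ", msg, call. = FALSE)
  }
  ap <- ref$adult_protein
  for (i in seq_len(nrow(ap))) {
    if (!is.finite(ap$mean[i]) || ap$mean[i] <= 0) {
      fail("adult_protein", ap$isoform[i], "mean must be strictly positive")
    }
    if (ap$range_low[i] > ap$range_high[i]) {
      fail("adult_protein", ap$isoform[i], "range_low exceeds range_high")
    }
  }
  aa <- ref$adult_activity
  for (i in seq_len(nrow(aa))) {
    if (aa$range_low[i] > aa$range_high[i]) {
      fail("adult_activity", aa$isoform[i], "range_low exceeds range_high")
    }
    if (aa$range_low[i] <= 0) {
      fail("adult_activity", aa$isoform[i],
           "activity range must be strictly positive")
    }
  }
  if (!aa$genotype_stratified[aa$isoform == "CYP3A5"]) {
    fail("adult_activity", "CYP3A5", "must be flagged genotype-stratified")
  }
  for (nm in names(ref$tier_tables)) {
    tt <- ref$tier_tables[[nm]]
    if (tt$low_days[1] != 0) fail(nm, tt$label[1], "bins must start at day 0")
    if (!is.infinite(tt$high_days[nrow(tt)])) {
      fail(nm, tt$label[nrow(tt)], "last bin must be open-ended")
    }
    if (nrow(tt) > 1 && any(tt$low_days[-1] != tt$high_days[-nrow(tt)])) {
      fail(nm, "age bins", "bins must partition [0, Inf) without gaps")
    }
    g <- tt[tt$gradable, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      if (!(g$moderate_low[i] < g$mild_low[i] &&
            g$mild_low[i] < g$normal_min[i])) {
        fail(nm, g$label[i], "tier edges must satisfy moderate < mild < normal")
      }
    }
    if (is.unsorted(g$normal_min)) {
      fail(nm, "normal_min", "normal minima must be non-decreasing with age")
    }
    ng <- tt[!tt$gradable, , drop = FALSE]
    if (nrow(ng) && any(!is.na(ng$normal_min))) {
      fail(nm, "non-gradable rows", "must carry no tier edges")
    }
  }
  bs <- ref$bin_specs
  for (i in seq_len(nrow(bs))) {
    if (!(bs$e0[i] < bs$e1[i] && bs$e1[i] < bs$e2[i])) {
      fail("bin_specs", bs$analyte[i], "edges must be strictly ascending")
    }
  }
  vw <- ref$validity_windows
  for (i in seq_len(nrow(vw))) {
    if (vw$best_within_h[i] > vw$max_pmi_h[i]) {
      fail("validity_windows", vw$specimen[i], "best_within_h exceeds max_pmi_h")
    }
  }
  invisible(ref)
}

#' Resolve the developmental age bin containing an age
#'
#' Age bins are half-open day intervals `[low_days, high_days)` that
#' partition `[0, Inf)`, so every non-negative age lies in exactly one bin.
#'
#' @param table One developmental tier table from
#'   `load_reference_set()$tier_tables`.
#' @param age_days Age at death in whole days (non-negative).
#' @return The matching row of `table` (one-row data frame).
#' @export
resolve_age_bin <- function(table, age_days) {
  if (!is.numeric(age_days) || length(age_days) != 1L || is.na(age_days) ||
      age_days < 0) {
    stop("input error: age_days must be a single non-negative number",
         call. = FALSE)
  }
  hit <- which(table$low_days <= age_days & age_days < table$high_days)
  table[hit, , drop = FALSE]
}

#' Look up the validity window for a specimen/analyte-group pair
#'
#' @param ref An `mvi_reference_set`.
#' @param specimen One of `"liver"`, `"femoral_blood"`, `"vitreous"`,
#'   `"kidney"`.
#' @param analyte_group One of `"cyp"`, `"cytokines"`, `"redox"`,
#'   `"vitreous_chemistry"`.
#' @return A one-row data frame with `best_within_h` and `max_pmi_h`.
#' @export
validity_window <- function(ref, specimen, analyte_group) {
  vw <- ref$validity_windows
  hit <- vw[vw$specimen == specimen & vw$analyte_group == analyte_group, ,
            drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("configuration error: no validity window for ", specimen, "/",
         analyte_group, call. = FALSE)
  }
  hit
}

#' Serialize a reference set to JSON
#'
#' The serialization is canonical (stable field order, full numeric
#' precision) so that writing and reloading reproduces identical tables.
#'
#' @param ref An `mvi_reference_set`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @seealso [reference_set_from_json()]
#' @export
reference_set_to_json <- function(ref, path = NULL) {
  json <- jsonlite::toJSON(unclass(ref), dataframe = "columns", digits = NA,
                           na = "null", auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Reload a reference set from its JSON serialization
#'
#' @param json A JSON string or file path produced by
#'   [reference_set_to_json()].
#' @return An `mvi_reference_set`, validated.
#' @export
reference_set_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  # JSON has no integer/double distinction: restore doubles throughout
  renumber <- function(df, cols) {
    df <- as.data.frame(df)
    for (col in intersect(cols, names(df))) df[[col]] <- as.numeric(df[[col]])
    df
  }
  x$adult_protein <- renumber(x$adult_protein,
                              c("mean", "sd", "range_low", "range_high"))
  x$adult_activity <- renumber(x$adult_activity,
                               c("range_low", "range_high"))
  x$tier_tables <- lapply(x$tier_tables, function(tt) {
    tt <- renumber(tt, c("low_days", "high_days", "normal_min", "mild_low",
                         "moderate_low"))
    tt$high_days[is.na(tt$high_days)] <- Inf
    tt
  })
  x$bin_specs <- renumber(x$bin_specs, c("e0", "e1", "e2"))
  x$validity_windows <- renumber(x$validity_windows,
                                 c("best_within_h", "max_pmi_h"))
  x$redox_reference <- if (is.null(x$redox_reference)) NA_real_
                       else as.numeric(x$redox_reference)
  ref <- structure(x, class = "mvi_reference_set")
  validate_reference_set(ref)
  ref
}

#' @export
print.mvi_reference_set <- function(x, ...) {
  cat("MVI reference set [", x$version, "]\n", sep = "")
  cat("  adult protein references: ", nrow(x$adult_protein), " isoforms\n",
      sep = "")
  cat("  adult activity references:", nrow(x$adult_activity), "isoforms\n")
  cat("  developmental tier tables:", length(x$tier_tables), "\n")
  cat("  ordinal bin specs:        ", nrow(x$bin_specs), "analytes\n")
  cat("  validity windows:         ", nrow(x$validity_windows), "rows\n")
  cat("  redox laboratory reference:",
      if (is.na(x$redox_reference)) "not set (fold input expected)"
      else paste(x$redox_reference, "ng/g"), "\n")
  invisible(x)
}

# Polynomial rolling hash (mod 2^31-1) over the canonical JSON; used only to
# tag overridden reference sets.  Exact in double arithmetic.
.stable_hash <- function(ref) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(
    unclass(ref)[setdiff(names(ref), "version")],
    dataframe = "columns", digits = NA, na = "null", auto_unbox = TRUE
  )))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
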