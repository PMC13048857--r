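# Independent oracles, transcribed directly from the printed reference
# tables as text.  These deliberately re-derive expectations from the
# printed cells (lower bounds parsed out of strings like "48-59%") through
# an explicit if-chain, independent of the package's stored edge tables.

REF <- load_reference_set()

# printed developmental tier cells: normal / mild / moderate columns.
# NA row = suppression cannot be graded at this age.
printed_tier_cells <- list(
  CYP3A4.protein_abundance = list(
    list("0-7 days", NA, NA, NA),
    list("1-4 weeks", "5%", "4%", "3%"),
    list("1-2 months", "15%", "12-14%", "11%"),
    list("2-3 months", "35%", "28-34%", "25-27%"),
    list("3-6 months", "35%", "28-34%", "25-27%"),
    list("6-12 months", "60%", "48-59%", "42-47%"),
    list(">12 months", "85%", "68-84%", "60-67%")
  ),
  CYP2D6.protein_abundance = list(
    list("0-7 days", NA, NA, NA),
    list("1-4 weeks", "5%", "4%", "3%"),
    list("1-2 months", "10%", "8-9%", "7%"),
    list("2-3 months", "25%", "20-24%", "18-19%"),
    list("3-6 months", "25%", "20-24%", "18-19%"),
    list("6-12 months", "60%", "48-59%", "42-47%"),
    list(">12 months", "85%", "68-84%", "60-67%")
  ),
  CYP2C19.protein_abundance = list(
    list("0-4 weeks", NA, NA, NA),
    list("1-2 months", "5%", "4%", "3%"),
    list("2-3 months", "20%", "16-19%", "14-15%"),
    list("3-6 months", "20%", "16-19%", "14-15%"),
    list("6-12 months", "60%", "48-59%", "42-47%"),
    list(">12 months", "85%", "68-84%", "60-67%")
  ),
  CYP3A5.protein_abundance = list(
    list("0-12 months", "70%", "56-69%", "49-55%"),
    list(">12 months", NA, NA, NA)
  ),
  CYP3A4.probe_activity = list(
    list("0-7 days", NA, NA, NA),
    list("1-4 weeks", "5%", "4-4.9%", "3.5-3.9%"),
    list("1-2 months", "20%", "16-19%", "14-15%"),
    list("2-3 months", "30%", "24-29%", "21-23%"),
    list("3-6 months", "40%", "32-39%", "28-31%"),
    list("6-12 months", "50%", "40-49%", "35-39%"),
    list(">12 months", "80%", "64-79%", "56-63%")
  ),
  CYP2D6.probe_activity = list(
    list("0-7 days", NA, NA, NA),
    list("1-4 weeks", "5%", "4-4.9%", "3.5-3.9%"),
    list("1-2 months", "15%", "12-14%", "10-11%"),
    list("2-3 months", "25%", "20-24%", "17-19%"),
    list("3-6 months", "40%", "32-39%", "28-31%"),
    list("6-12 months", "60%", "48-59%", "42-47%"),
    list(">12 months", "90%", "72-89%", "63-71%")
  ),
  CYP2C19.probe_activity = list(
    list("0-7 days", NA, NA, NA),
    list("1-4 weeks", "10%", "8-9%", "7%"),
    list("1-2 months", "25%", "20-24%", "18-19%"),
    list("2-3 months", "35%", "28-34%", "25-27%"),
    list("3-6 months", "50%", "40-49%", "35-39%"),
    list("6-12 months", "70%", "56-69%", "49-55%"),
    list(">12 months", "90%", "72-89%", "63-71%")
  ),
  CYP3A5.probe_activity = list(
    list("0-7 days", "10%", "8-9%", "7%"),
    list("1-4 weeks", "20%", "16-19%", "14-15%"),
    list("1-2 months", "30%", "24-29%", "21-23%"),
    list("2-3 months", "40%", "32-39%", "28-31%"),
    list("3-6 months", "50%", "40-49%", "35-39%"),
    list("6-12 months", "70%", "56-69%", "49-55%"),
    list(">12 months", "90%", "72-89%", "63-71%")
  )
)

# lower bound of a printed percent cell ("48-59%" -> 48, "5%" -> 5)
cell_lower <- function(cell) {
  as.numeric(sub("^\\s*([0-9.]+).*$", "\\1", cell))
}

# independent tier oracle: explicit if-chain over printed lower bounds
oracle_tier <- function(pct, row) {
  if (is.na(row[[2]])) return(NA_integer_)
  normal <- cell_lower(row[[2]])
  mild <- cell_lower(row[[3]])
  moderate <- cell_lower(row[[4]])
  if (pct >= normal) 0L
  else if (pct >= mild) 1L
  else if (pct >= moderate) 2L
  else 3L
}

# a representative age (days) strictly inside each printed age-bin label
age_inside <- c(
  "0-7 days" = 3, "1-4 weeks" = 15, "0-4 weeks" = 15, "1-2 months" = 45,
  "2-3 months" = 75, "3-6 months" = 120, "6-12 months" = 250,
  ">12 months" = 400, "0-12 months" = 100
)

# independent ordinal-bin oracle from the printed severity table:
# explicit branches per analyte, printed edges hardcoded
oracle_bin <- function(analyte, value) {
  edges <- switch(analyte,
    IL6 = c(30, 80, 300), CRP = c(10, 40, 150),
    F2_ISOPROSTANE_FOLD = c(1, 2, 4),
    VITREOUS_BHB = c(2.5, 5, 10), VITREOUS_GLUCOSE = c(10, 15, 25))
  if (value <= edges[1]) 0L
  else if (value <= edges[2]) 1L
  else if (value <= edges[3]) 2L
  else 3L
}

# exhaustive truth table for the vitreous contextual pattern, transcribed
# row by row from the printed pattern guide (NS handled symmetrically)
oracle_vitreous <- function(glucose, bhb) {
  if (is.na(glucose) || is.na(bhb)) return("indeterminate_NS")
  low_g <- glucose %in% 0:1
  low_b <- bhb %in% 0:1
  if (low_g && low_b) "minimal_deviation"
  else if (!low_g && low_b) "stress_hyperglycemia"
  else if (low_g && !low_b) "ketosis"
  else "mixed_dysregulation"
}

# convenience: numeric score vector (NA = NS) out of a report
report_scores <- function(report) {
  vapply(report$domain_scores, function(d)
    if (d$ns) NA_integer_ else d$score, integer(1))
}
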