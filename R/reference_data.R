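# Built-in reference constants of the MVI framework.
#
# Everything here is a framework constant: adult hepatic CYP references,
# age-matched developmental tier tables (protein and probe activity),
# ordinal severity bin edges for the cytokine/redox/vitreous analytes, and
# postmortem-interval validity windows per specimen.  Laboratory overrides
# may replace adult means/ranges and the redox laboratory reference only;
# tier fractions, bin edges and validity windows are never overridable.

MVI_ISOFORMS <- c("CYP3A4", "CYP2D6", "CYP2C19", "CYP3A5")
MVI_MEASURES <- c("protein_abundance", "probe_activity")
MVI_ANALYTES <- c("IL6", "CRP", "F2_ISOPROSTANE_FOLD",
                  "VITREOUS_BHB", "VITREOUS_GLUCOSE")
MVI_SPECIMENS <- c("liver", "femoral_blood", "vitreous", "kidney")
MVI_GENOTYPES <- c("expressor", "non_expressor", "unknown")
MVI_DOMAIN_NAMES <- c("CYP450 capacity", "Cytokine load", "Redox balance",
                      "Neurochemical integrity", "Xenobiotic/metal burden")

# Adult human liver microsomal protein abundance (pmol/mg).  Means drive the
# %Adult normalization; ranges are plausibility bounds only.
.adult_protein_refs <- function() {
  data.frame(
    isoform    = MVI_ISOFORMS,
    mean       = c(85.8, 7.90, 5.02, 4.00),
    sd         = c(74.6, 6.24, 6.68, 7.66),
    range_low  = c(6.96, 0.00, 0.02, 0.31),
    range_high = c(246.2, 25.1, 25.0, 34.2),
    genotype_stratified = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Expected adult probe-substrate activity ranges (pmol/min/mg).  Activity is
# normalized against the range midpoint because no adult mean is published.
.adult_activity_refs <- function() {
  data.frame(
    isoform = MVI_ISOFORMS,
    probe_reaction = c(
      "midazolam 1'-hydroxylation",
      "dextromethorphan O-demethylation",
      "S-mephenytoin 4'-hydroxylation",
      "midazolam 1'-hydroxylation"
    ),
    range_low  = c(350, 120, 60, 100),
    range_high = c(450, 160, 90, 250),
    genotype_stratified = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Age-bin day boundaries (half-open [low, high) in days since birth).
# Calendar labels overlap at their printed edges; these boundaries partition
# [0, Inf) deterministically: month m starts at day 30.5*m rounded.
.AGE_DAYS <- c(
  "0-7 days"    = 0, "1-4 weeks" = 8, "0-4 weeks" = 0,
  "1-2 months"  = 31, "2-3 months" = 61, "3-6 months" = 91,
  "6-12 months" = 183, ">12 months" = 366, "0-12 months" = 0
)

.tier_rows <- function(labels, normal, mild, moderate) {
  # A row with NA edges is non-gradable (capacity physiologically near zero,
  # or no printed tiers).  Tier intervals are keyed by lower edges:
  # normal [normal, Inf), mild [mild, normal), moderate [moderate, mild),
  # severe [0, moderate).
  low  <- unname(.AGE_DAYS[labels])
  high <- c(low[-1], Inf)
  data.frame(
    label = labels, low_days = low, high_days = high,
    gradable = !is.na(normal),
    normal_min = normal, mild_low = mild, moderate_low = moderate,
    stringsAsFactors = FALSE
  )
}

# Developmental tier tables: %Adult lower edges per age bin.
# Protein abundance tables.
.tier_tables <- function() {
  list(
    CYP3A4.protein_abundance = .tier_rows(
      c("0-7 days", "1-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(NA,  5, 15, 35, 35, 60, 85),
      mild     = c(NA,  4, 12, 28, 28, 48, 68),
      moderate = c(NA,  3, 11, 25, 25, 42, 60)
    ),
    CYP2D6.protein_abundance = .tier_rows(
      c("0-7 days", "1-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(NA,  5, 10, 25, 25, 60, 85),
      mild     = c(NA,  4,  8, 20, 20, 48, 68),
      moderate = c(NA,  3,  7, 18, 18, 42, 60)
    ),
    CYP2C19.protein_abundance = .tier_rows(
      c("0-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(NA,  5, 20, 20, 60, 85),
      mild     = c(NA,  4, 16, 16, 48, 68),
      moderate = c(NA,  3, 14, 14, 42, 60)
    ),
    # CYP3A5 protein: a single printed infancy row; the adult row carries no
    # printed tiers and is therefore non-gradable.
    CYP3A5.protein_abundance = .tier_rows(
      c("0-12 months", ">12 months"),
      normal   = c(70, NA),
      mild     = c(56, NA),
      moderate = c(49, NA)
    ),
    CYP3A4.probe_activity = .tier_rows(
      c("0-7 days", "1-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(NA,   5, 20, 30, 40, 50, 80),
      mild     = c(NA,   4, 16, 24, 32, 40, 64),
      moderate = c(NA, 3.5, 14, 21, 28, 35, 56)
    ),
    CYP2D6.probe_activity = .tier_rows(
      c("0-7 days", "1-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(NA,   5, 15, 25, 40, 60, 90),
      mild     = c(NA,   4, 12, 20, 32, 48, 72),
      moderate = c(NA, 3.5, 10, 17, 28, 42, 63)
    ),
    CYP2C19.probe_activity = .tier_rows(
      c("0-7 days", "1-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(NA, 10, 25, 35, 50, 70, 90),
      mild     = c(NA,  8, 20, 28, 40, 56, 72),
      moderate = c(NA,  7, 18, 25, 35, 49, 63)
    ),
    # CYP3A5 activity is gradable from birth (expressors only).
    CYP3A5.probe_activity = .tier_rows(
      c("0-7 days", "1-4 weeks", "1-2 months", "2-3 months", "3-6 months",
        "6-12 months", ">12 months"),
      normal   = c(10, 20, 30, 40, 50, 70, 90),
      mild     = c( 8, 16, 24, 32, 40, 56, 72),
      moderate = c( 7, 14, 21, 28, 35, 49, 63)
    )
  )
}

# Ordinal severity bins for CMSP anchors and vitreous context markers.
# bin(value): value <= e0 -> 0; <= e1 -> 1; <= e2 -> 2; > e2 -> 3.
.bin_specs <- function() {
  data.frame(
    analyte = MVI_ANALYTES,
    units = c("pg/mL", "mg/L", "fold over laboratory reference",
              "mmol/L", "mmol/L"),
    e0 = c(30, 10, 1, 2.5, 10),
    e1 = c(80, 40, 2, 5, 15),
    e2 = c(300, 150, 4, 10, 25),
    role = c("cytokine_anchor", "cytokine_anchor", "redox_anchor",
             "contextual", "contextual"),
    stringsAsFactors = FALSE
  )
}

# Postmortem stability windows (hours): best-within is exclusive, max is
# inclusive.
.validity_windows <- function() {
  data.frame(
    specimen = c("liver", "femoral_blood", "liver", "kidney", "vitreous"),
    analyte_group = c("cyp", "cytokines", "redox", "redox",
                      "vitreous_chemistry"),
    best_within_h = c(24, 24, 24, 24, 24),
    max_pmi_h = c(48, 48, 48, 48, 72),
    stringsAsFactors = FALSE
  )
}
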