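ref <- load_reference_set()

ok_liver <- gate_specimen(12, validity_window(ref, "liver", "cyp"))
ns_liver <- gate_specimen(50, validity_window(ref, "liver", "cyp"))

meas <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(isoform = r[[1]], measure = r[[2]],
               value = as.numeric(r[[3]]),
               qc_qualified = if (length(r) > 3) r[[4]] else NA,
               stringsAsFactors = FALSE)))
}

test_that("normalization uses the adult mean (protein) and range midpoint (activity)", {
  expect_equal(
    normalize_to_adult(85.8, "CYP3A4", "protein_abundance", ref)$pct_adult,
    100)
  expect_equal(
    normalize_to_adult(42.9, "CYP3A4", "protein_abundance", ref)$pct_adult,
    50)
  expect_equal(
    normalize_to_adult(0, "CYP2D6", "protein_abundance", ref)$pct_adult, 0)
  # activity midpoints: 400, 140, 75, 175
  expect_equal(
    normalize_to_adult(400, "CYP3A4", "probe_activity", ref)$pct_adult, 100)
  expect_equal(
    normalize_to_adult(70, "CYP2D6", "probe_activity", ref)$pct_adult, 50)
  expect_equal(
    normalize_to_adult(75, "CYP2C19", "probe_activity", ref)$pct_adult, 100)
  expect_equal(
    normalize_to_adult(175, "CYP3A5", "probe_activity", ref)$pct_adult, 100)
})

test_that("plausibility flag marks implausible values without altering them", {
  n <- normalize_to_adult(85.8 * 1.6, "CYP3A4", "protein_abundance", ref)
  expect_true(n$plausibility_flag)
  expect_equal(n$pct_adult, 160)
  # above printed adult max but below 150 %Adult: still flagged
  n2 <- normalize_to_adult(250, "CYP3A4", "protein_abundance", ref)
  expect_true(n2$plausibility_flag)
  expect_false(
    normalize_to_adult(85.8, "CYP3A4", "protein_abundance", ref)$plausibility_flag)
  expect_error(normalize_to_adult(-1, "CYP3A4", "protein_abundance", ref),
               "input error")
})

test_that("grading reproduces the printed examples", {
  g <- grade_isoform(50, "CYP3A4", "protein_abundance", 200, "unknown", ref)
  expect_equal(g$tier, "mild")
  expect_equal(g$score, 1L)
  g <- grade_isoform(41.9, "CYP3A4", "protein_abundance", 200, "unknown", ref)
  expect_equal(g$tier, "severe")
  expect_equal(g$score, 3L)
  g <- grade_isoform(80, "CYP3A4", "protein_abundance", 5, "unknown", ref)
  expect_equal(g$tier, "not_gradable")
  expect_true(is.na(g$score))
  g <- grade_isoform(30, "CYP3A5", "protein_abundance", 90, "non_expressor",
                     ref)
  expect_equal(g$tier, "genotype_zeroed")
  expect_equal(g$score, 0L)
})

test_that("a value exactly at every printed minimum grades normal", {
  for (nm in names(printed_tier_cells)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    for (row in printed_tier_cells[[nm]]) {
      if (is.na(row[[2]])) next
      g <- grade_isoform(cell_lower(row[[2]]), parts[1], parts[2],
                         age_inside[[row[[1]]]], "expressor", ref)
      expect_equal(g$score, 0L, label = paste(nm, row[[1]], "minimum"))
    }
  }
})

test_that("grading agrees with the printed-cell oracle on a pct sweep", {
  pcts <- seq(0, 120, by = 0.5)
  for (nm in names(printed_tier_cells)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    for (row in printed_tier_cells[[nm]]) {
      if (is.na(row[[2]])) next
      age <- age_inside[[row[[1]]]]
      got <- vapply(pcts, function(p)
        grade_isoform(p, parts[1], parts[2], age, "expressor", ref)$score,
        integer(1))
      want <- vapply(pcts, oracle_tier, integer(1), row = row)
      expect_identical(got, want, label = paste(nm, row[[1]]))
      # monotone severity: tier never drops as pct falls
      expect_false(is.unsorted(rev(got)), label = paste(nm, row[[1]],
                                                        "monotone"))
    }
  }
})

test_that("CYP3A5 non-expressor grade ignores the measured value", {
  for (v in c(0, 0.5, 4, 40, 400, 1000)) {
    pct <- normalize_to_adult(v, "CYP3A5", "protein_abundance", ref)$pct_adult
    g <- grade_isoform(pct, "CYP3A5", "protein_abundance", 90,
                       "non_expressor", ref)
    expect_equal(g$tier, "genotype_zeroed")
    expect_equal(g$score, 0L)
  }
  # unknown genotype is graded as expressor
  g <- grade_isoform(30, "CYP3A5", "protein_abundance", 90, "unknown", ref)
  expect_equal(g$tier, "severe")
})

test_that("Domain 1 aggregates as the worst gradable isoform", {
  m <- meas(list("CYP3A4", "protein_abundance", 85.8 * 0.30),  # severe @200d
            list("CYP2D6", "protein_abundance", 7.90 * 0.70))  # normal
  d <- score_domain1(m, "unknown", 200, ok_liver, ref)
  expect_equal(d$score, 3L)
  m <- meas(list("CYP3A4", "protein_abundance", 85.8 * 0.70),
            list("CYP2D6", "protein_abundance", 7.90 * 0.70),
            list("CYP2C19", "protein_abundance", 5.02 * 0.70),
            list("CYP3A5", "protein_abundance", 4.00 * 0.90))
  d <- score_domain1(m, "expressor", 200, ok_liver, ref)
  expect_equal(d$score, 0L)
})

test_that("Domain 1 NS paths carry reasons", {
  m <- meas(list("CYP3A4", "protein_abundance", 40))
  d <- score_domain1(m, "unknown", 200, ns_liver, ref)
  expect_true(d$ns)
  expect_match(d$ns_reason, "PMI exceeds maximum")
  d <- score_domain1(empty_cyp_measurements(), "unknown", 200, ok_liver, ref)
  expect_true(d$ns)
  expect_equal(d$ns_reason, "no CYP measurements")
  # all isoforms non-gradable at 3 days
  m <- meas(list("CYP3A4", "protein_abundance", 1),
            list("CYP2D6", "protein_abundance", 1),
            list("CYP2C19", "protein_abundance", 1))
  d <- score_domain1(m, "unknown", 3, ok_liver, ref)
  expect_true(d$ns)
  expect_equal(d$ns_reason, "no gradable isoform at this age")
})

test_that("protein is primary; activity only substitutes when QC-qualified", {
  # protein severe + co-existing activity normal: activity is corroboration
  m <- meas(list("CYP3A4", "protein_abundance", 85.8 * 0.30),
            list("CYP3A4", "probe_activity", 400, TRUE))
  d <- score_domain1(m, "unknown", 200, ok_liver, ref)
  expect_equal(d$score, 3L)
  expect_true(any(grepl("corroboration only", d$flags)))
  # activity alone, QC-qualified: scored (170/400 = 42.5 %Adult; mild at
  # 200 d where the activity normal minimum is 50%)
  m <- meas(list("CYP3A4", "probe_activity", 170, TRUE))
  d <- score_domain1(m, "unknown", 200, ok_liver, ref)
  expect_equal(d$score, 1L)
  # activity alone, not QC-qualified: excluded -> NS
  m <- meas(list("CYP3A4", "probe_activity", 200, FALSE))
  d <- score_domain1(m, "unknown", 200, ok_liver, ref)
  expect_true(d$ns)
  expect_true(any(grepl("not QC-qualified", d$flags)))
})

test_that("genotype-zeroed CYP3A5 as the only isoform anchors score 0", {
  m <- meas(list("CYP3A5", "protein_abundance", 0.1))
  d <- score_domain1(m, "non_expressor", 90, ok_liver, ref)
  expect_equal(d$score, 0L)
  expect_false(d$ns)
  # but genotype-zeroed never overrides a gradable isoform's worse tier
  m <- rbind(m, meas(list("CYP3A4", "protein_abundance", 85.8 * 0.30)))
  d <- score_domain1(m, "non_expressor", 200, ok_liver, ref)
  expect_equal(d$score, 3L)
})
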