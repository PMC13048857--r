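test_that("built-in reference set carries the printed constants", {
  ref <- load_reference_set()
  ap <- ref$adult_protein
  expect_equal(ap$mean[ap$isoform == "CYP3A4"], 85.8)
  expect_equal(ap$mean[ap$isoform == "CYP2D6"], 7.90)
  expect_equal(ap$mean[ap$isoform == "CYP2C19"], 5.02)
  expect_equal(ap$mean[ap$isoform == "CYP3A5"], 4.00)
  expect_equal(ap$range_low[ap$isoform == "CYP2D6"], 0)
  aa <- ref$adult_activity
  expect_equal(aa$range_low[aa$isoform == "CYP3A4"], 350)
  expect_equal(aa$range_high[aa$isoform == "CYP3A4"], 450)
  expect_true(aa$genotype_stratified[aa$isoform == "CYP3A5"])
  vw <- ref$validity_windows
  expect_equal(vw$max_pmi_h[vw$specimen == "vitreous"], 72)
  expect_equal(vw$max_pmi_h[vw$specimen == "liver" & vw$analyte_group == "cyp"],
               48)
  expect_equal(unique(vw$best_within_h), 24)
})

test_that("age bins partition [0, Inf): exactly one bin per age in 0..800", {
  ref <- load_reference_set()
  for (nm in names(ref$tier_tables)) {
    tt <- ref$tier_tables[[nm]]
    hits <- vapply(0:800, function(a)
      sum(tt$low_days <= a & a < tt$high_days), integer(1))
    expect_true(all(hits == 1L), label = paste(nm, "partition"))
  }
})

test_that("normal minima are non-decreasing over gradable age bins", {
  ref <- load_reference_set()
  for (nm in names(ref$tier_tables)) {
    g <- ref$tier_tables[[nm]]
    g <- g[g$gradable, ]
    expect_false(is.unsorted(g$normal_min), label = nm)
  }
})

test_that("resolve_age_bin honours the half-open day boundaries", {
  ref <- load_reference_set()
  t3a4 <- ref$tier_tables$CYP3A4.protein_abundance
  expect_equal(resolve_age_bin(t3a4, 0)$label, "0-7 days")
  expect_equal(resolve_age_bin(t3a4, 7)$label, "0-7 days")
  expect_equal(resolve_age_bin(t3a4, 8)$label, "1-4 weeks")
  expect_equal(resolve_age_bin(t3a4, 200)$label, "6-12 months")
  expect_equal(resolve_age_bin(t3a4, 366)$label, ">12 months")
  t2c19 <- ref$tier_tables$CYP2C19.protein_abundance
  bin20 <- resolve_age_bin(t2c19, 20)
  expect_equal(bin20$label, "0-4 weeks")
  expect_false(bin20$gradable)
  expect_error(resolve_age_bin(t3a4, -1), "input error")
})

test_that("tier tables match the printed cells exactly", {
  ref <- load_reference_set()
  for (nm in names(printed_tier_cells)) {
    tt <- ref$tier_tables[[nm]]
    printed <- printed_tier_cells[[nm]]
    expect_equal(nrow(tt), length(printed), label = nm)
    for (i in seq_along(printed)) {
      row <- printed[[i]]
      expect_equal(tt$label[i], row[[1]], label = paste(nm, "label", i))
      if (is.na(row[[2]])) {
        expect_false(tt$gradable[i], label = paste(nm, row[[1]]))
      } else {
        expect_equal(tt$normal_min[i], cell_lower(row[[2]]),
                     label = paste(nm, row[[1]], "normal"))
        expect_equal(tt$mild_low[i], cell_lower(row[[3]]),
                     label = paste(nm, row[[1]], "mild"))
        expect_equal(tt$moderate_low[i], cell_lower(row[[4]]),
                     label = paste(nm, row[[1]], "moderate"))
      }
    }
  }
})

test_that("laboratory overrides are restricted and validated", {
  ref <- load_reference_set(config = list(
    adult_protein = list(CYP3A4 = list(mean = 90)),
    redox_reference = 120))
  expect_equal(ref$adult_protein$mean[ref$adult_protein$isoform == "CYP3A4"],
               90)
  expect_equal(ref$redox_reference, 120)
  expect_match(ref$version, "^builtin-1\\.0\\+lab-")
  # invariant violation named in the error
  expect_error(
    load_reference_set(config = list(
      adult_protein = list(CYP3A4 = list(range_low = 300, range_high = 200)))),
    "configuration error.*adult_protein.*CYP3A4")
  # tier fractions and bin edges are framework constants
  expect_error(
    load_reference_set(config = list(tier_tables = list())),
    "non-overridable")
  expect_error(
    load_reference_set(config = list(
      adult_protein = list(NOTANISOFORM = list(mean = 5)))),
    "unknown isoform")
  expect_error(
    load_reference_set(config = list(
      adult_protein = list(CYP2D6 = list(mean = -1)))),
    "strictly positive")
})

test_that("overrides can come from YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("adult_protein:", "  CYP2D6:", "    mean: 8.5",
               "redox_reference: 95"), yml)
  ref <- load_reference_set(config = yml)
  expect_equal(ref$adult_protein$mean[ref$adult_protein$isoform == "CYP2D6"],
               8.5)
  expect_equal(ref$redox_reference, 95)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"adult_activity": {"CYP3A4": {"range_low": 340}}}', js)
  ref2 <- load_reference_set(config = js)
  expect_equal(
    ref2$adult_activity$range_low[ref2$adult_activity$isoform == "CYP3A4"],
    340)
})

test_that("reference set serializes and reloads identically", {
  for (cfg in list(NULL, list(redox_reference = 101))) {
    ref <- load_reference_set(config = cfg)
    back <- reference_set_from_json(reference_set_to_json(ref))
    expect_identical(back$adult_protein, ref$adult_protein)
    expect_identical(back$adult_activity, ref$adult_activity)
    expect_identical(back$bin_specs, ref$bin_specs)
    expect_identical(back$validity_windows, ref$validity_windows)
    expect_identical(back$tier_tables, ref$tier_tables)
    expect_identical(back$redox_reference, ref$redox_reference)
    expect_identical(back$version, ref$version)
    # canonical serialization: byte-identical on a second pass
    expect_identical(reference_set_to_json(back), reference_set_to_json(ref))
  }
})
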