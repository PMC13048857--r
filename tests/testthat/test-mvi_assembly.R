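ref <- load_reference_set()

# hand-built case engineered to score (3,2,2,1,2) at age 200 days
worked_case <- function(vitreous_glucose = 20, vitreous_bhb = 1,
                        vitreous_pmi = 10, il6 = 100, case_id = "WE-1") {
  case_record(
    case_id = case_id, age_days = 200,
    specimens = data.frame(
      specimen = c("liver", "femoral_blood", "vitreous"),
      pmi_h = c(10, 10, vitreous_pmi), collected = TRUE,
      stringsAsFactors = FALSE),
    cyp_measurements = data.frame(
      isoform = "CYP3A4", measure = "protein_abundance",
      value = 85.8 * 0.30, qc_qualified = NA, stringsAsFactors = FALSE),
    cyp3a5_genotype = "unknown",
    biomarkers = list(il6_pg_ml = il6, crp_mg_l = 20, redox_fold = 3,
                      redox_tissue = "liver",
                      vitreous_glucose_mmol_l = vitreous_glucose,
                      vitreous_bhb_mmol_l = vitreous_bhb),
    adjudicated = data.frame(
      domain = c("neurochemical", "xenobiotic_metal"),
      score = c(1L, 2L),
      basis = c("brainstem neuropathology + SERT/TPH2 IHC",
                "comprehensive toxicology + ICP-MS metals"),
      ns_reason = "", stringsAsFactors = FALSE)
  )
}

test_that("the five-domain worked example assembles to 10/15 and archetype 11", {
  rep <- compute_mvi(worked_case(), ref)
  expect_equal(report_scores(rep), c(3L, 2L, 2L, 1L, 2L))
  expect_equal(rep$mvi_total, 10L)
  expect_equal(rep$scorable_max, 15L)
  expect_equal(rep$archetype$ref_no, 11L)
  expect_setequal(rep$archetype$modifier_domains$domain, c(4L, 5L))
  expect_equal(rep$cmsp$core_sum, 5L)
  expect_equal(rep$cmsp$core_label, "moderate")
  expect_equal(rep$vitreous$label, "stress_hyperglycemia")
})

test_that("an all-normal case scores 0 with no archetype", {
  case <- generate_case(c(0, 0, 0, 0, 0), age_days = 200, seed = 3,
                        ref = ref)
  rep <- compute_mvi(case, ref)
  expect_equal(rep$mvi_total, 0L)
  expect_equal(rep$scorable_max, 15L)
  expect_true(is.na(rep$archetype$ref_no))
})

test_that("NS domains shrink the scorable denominator instead of imputing 0", {
  case <- generate_case(c(3, NA, 2, 1, 2), age_days = 200, seed = 4,
                        ref = ref)
  rep <- compute_mvi(case, ref)
  expect_true(rep$domain_scores[[2]]$ns)
  expect_equal(rep$mvi_total, 8L)
  expect_equal(rep$scorable_max, 12L)
  expect_true(any(grepl("D2 NS", rep$flags)))
  expect_true(any(grepl("core domain 2 not scorable", rep$flags)))
})

test_that("vitreous inputs never touch domain scores, total, or archetype", {
  base <- compute_mvi(worked_case(), ref)
  variants <- list(
    worked_case(vitreous_glucose = 30, vitreous_bhb = 11),
    worked_case(vitreous_glucose = 0.5, vitreous_bhb = 0.1),
    worked_case(vitreous_pmi = 80)  # vitreous NS
  )
  for (v in variants) {
    rep <- compute_mvi(v, ref)
    expect_equal(report_scores(rep), report_scores(base))
    expect_equal(rep$mvi_total, base$mvi_total)
    expect_equal(rep$scorable_max, base$scorable_max)
    expect_equal(rep$archetype$ref_no, base$archetype$ref_no)
    expect_equal(rep$cmsp$core_sum, base$cmsp$core_sum)
  }
  expect_equal(compute_mvi(worked_case(vitreous_pmi = 80), ref)$vitreous$label,
               "indeterminate_NS")
})

test_that("reports are byte-identical for identical inputs", {
  r1 <- report_to_json(compute_mvi(worked_case(), ref))
  r2 <- report_to_json(compute_mvi(worked_case(), ref))
  expect_identical(as.character(r1), as.character(r2))
})

test_that("raising a severity input never lowers the MVI total", {
  totals <- vapply(c(10, 50, 100, 200, 400, 600), function(il6)
    compute_mvi(worked_case(il6 = il6), ref)$mvi_total, integer(1))
  expect_false(is.unsorted(totals))
})

test_that("schema violations surface as input errors", {
  bad <- worked_case()
  bad$age_days <- -5L
  expect_error(compute_mvi(bad, ref), "age_days")
  bad2 <- worked_case()
  bad2$cyp3a5_genotype <- "heterozygote"
  expect_error(compute_mvi(bad2, ref), "cyp3a5_genotype")
})

test_that("raw redox values convert only with a configured lab reference", {
  with_raw <- function(r) {
    case <- worked_case()
    case$biomarkers$redox_fold <- NA_real_
    case$biomarkers$redox_ng_g <- 300
    compute_mvi(case, r)
  }
  no_ref <- with_raw(ref)
  expect_true(no_ref$domain_scores[[3]]$ns)
  expect_match(no_ref$domain_scores[[3]]$ns_reason, "redox reference")
  lab <- load_reference_set(config = list(redox_reference = 100))
  converted <- with_raw(lab)                     # fold 3 -> bin 2
  expect_equal(converted$domain_scores[[3]]$score, 2L)
})

test_that("markdown rendering reflects the computed report", {
  md <- report_to_markdown(compute_mvi(worked_case(), ref))
  expect_true(any(grepl("\\*\\*MVI total:\\*\\* 10 / 15", md)))
  expect_true(any(grepl("#11", md)))
})
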