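cc18 <- cascadeConfig(2018)

test_that("cohort inclusion follows the medication / pre-diabetes-pass rule", {
  pats <- rbind(
    fx_patient("10000000001", birth_year = 1962),  # 55, metformin in x-1
    fx_patient("10000000002", birth_year = 1950),  # pass in x-1
    fx_patient("10000000003", birth_year = 1950),  # nothing
    fx_patient("10000000004", birth_year = 1950),  # metformin in x-2 only
    fx_patient("10000000005", birth_year = 1950))  # other drug in x-1
  ph <- rbind(fx_pharma("10000000001", "A10BA02", "2017-03-01"),
              fx_pharma("10000000004", "A10BA02", "2016-03-01"),
              fx_pharma("10000000005", "C10AA05", "2017-03-01"))
  cl <- fx_claim("10000000002", "prediabetes_pass", "2017-06-15",
                 prescriber = "other")
  b <- fx_bundle(pats, claims = cl, pharma = ph)
  sel <- selectCohort(b, cc18)
  expect_setequal(sel$cohort, c("10000000001", "10000000002"))
  expect_equal(unname(sel$exclusion_log["n_cohort"]), 2L)
})

test_that("type-1 registrations in x-1 or x-2 exclude, earlier ones do not", {
  pats <- rbind(fx_patient("20000000001", birth_year = 1950),
                fx_patient("20000000002", birth_year = 1950),
                fx_patient("20000000003", birth_year = 1950))
  ph <- rbind(fx_pharma("20000000001", "A10AB01", "2017-02-01"),
              fx_pharma("20000000002", "A10AB01", "2017-02-01"),
              fx_pharma("20000000003", "A10AB01", "2017-02-01"))
  cl <- rbind(
    fx_claim("20000000001", "insulin_pump", "2016-09-01"),    # x-2: excluded
    fx_claim("20000000002", "t1d_convention", "2017-01-10"),  # x-1: excluded
    fx_claim("20000000003", "t1d_convention", "2015-05-01"))  # x-3: kept
  b <- fx_bundle(pats, claims = cl, pharma = ph)
  sel <- selectCohort(b, cc18)
  expect_equal(sel$cohort, "20000000003")
  expect_equal(unname(sel$exclusion_log["n_removed_t1d"]), 2L)
})

test_that("'above 40' is strict by default and configurable", {
  pats <- rbind(fx_patient("30000000001", birth_year = 1977),  # exactly 40
                fx_patient("30000000002", birth_year = 1976))  # 41
  ph <- rbind(fx_pharma("30000000001", "A10BA02", "2017-03-01"),
              fx_pharma("30000000002", "A10BA02", "2017-03-01"))
  b <- fx_bundle(pats, pharma = ph)
  expect_equal(selectCohort(b, cc18)$cohort, "30000000002")
  inc <- cascadeConfig(2018, age_inclusive = TRUE)
  expect_setequal(selectCohort(b, inc)$cohort,
                  c("30000000001", "30000000002"))
})

test_that("stage 1 needs a glucose/HbA1c test inside the 3-year window", {
  pats <- rbind(fx_patient("40000000001"), fx_patient("40000000002"),
                fx_patient("40000000003"), fx_patient("40000000004"))
  cl <- rbind(
    fx_claim("40000000001", "lab_test_billed", "2016-04-01",
             analyte = "glucose"),           # x-2: tested
    fx_claim("40000000002", "lab_test_billed", "2016-04-01",
             analyte = "ldl_c"),             # wrong analyte
    fx_claim("40000000003", "lab_test_billed", "2014-12-31",
             analyte = "hba1c"),             # x-4: outside window
    fx_claim("40000000004", "lab_test_billed", "2015-01-01",
             analyte = "hba1c"))             # first day of window
  b <- fx_bundle(pats, claims = cl)
  got <- stageTested(b, pats$ssn, cc18)
  expect_equal(unname(got), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("in-care uses GP visits for FFS, GP prescriptions for capitation", {
  pats <- rbind(
    fx_patient("50000000001"),                                  # FFS + visit
    fx_patient("50000000002", scheme = "capitation",
               practice_id = "PRC"),                            # cap + GP rx
    fx_patient("50000000003"),                                  # FFS, no visit
    fx_patient("50000000004", scheme = "capitation",
               practice_id = "PRC"))                            # cap, spec rx
  cl <- fx_claim("50000000001", "gp_visit", "2017-05-01")
  ph <- rbind(fx_pharma("50000000002", "A10BA02", "2017-05-01",
                        prescriber = "gp"),
              fx_pharma("50000000003", "A10BA02", "2017-05-01",
                        prescriber = "specialist"),
              fx_pharma("50000000004", "A10BA02", "2017-05-01",
                        prescriber = "specialist"))
  b <- fx_bundle(pats, claims = cl, pharma = ph)
  got <- stageInCare(b, pats$ssn, cc18)
  expect_equal(unname(got), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("sensitivity mode flips only FFS patients and reports both
          indicators", {
  pats <- rbind(
    fx_patient("51000000001"),                       # FFS: visit, no GP rx
    fx_patient("51000000002", scheme = "capitation", practice_id = "PRC"))
  cl <- fx_claim("51000000001", "gp_visit", "2017-05-01")
  ph <- fx_pharma("51000000002", "A10BA02", "2017-05-01", prescriber = "gp")
  b <- fx_bundle(pats, claims = cl, pharma = ph)
  main <- stageInCare(b, pats$ssn, cc18, both = TRUE)
  sens <- stageInCare(b, pats$ssn,
                      cascadeConfig(2018, in_care_sensitivity = TRUE),
                      both = TRUE)
  # capitation patient unchanged, FFS patient flips to FALSE
  expect_equal(main$in_care, c(TRUE, TRUE))
  expect_equal(sens$in_care, c(FALSE, TRUE))
  expect_equal(sens$visit_indicator, c(TRUE, FALSE))
  expect_equal(sens$rx_indicator, c(FALSE, TRUE))
})

test_that("in-treatment needs year-x medication, or education for the
          pre-diabetes trajectory", {
  pats <- rbind(fx_patient("60000000001"), fx_patient("60000000002"),
                fx_patient("60000000003"), fx_patient("60000000004"))
  ph <- fx_pharma("60000000001", "A10BB01", "2018-06-01")   # sulfonylurea x
  cl <- rbind(
    fx_claim("60000000002", "prediabetes_pass", "2017-03-01"),
    fx_claim("60000000002", "dietician_consult", "2018-02-01"),  # in x: true
    fx_claim("60000000003", "prediabetes_pass", "2017-03-01"),
    fx_claim("60000000003", "dietician_consult", "2017-11-01"),  # x-1: false
    fx_claim("60000000004", "dietician_consult", "2018-02-01"))  # no pass
  b <- fx_bundle(pats, claims = cl, pharma = ph)
  got <- stageInTreatment(b, pats$ssn, cc18)
  expect_equal(unname(got), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("HbA1c follow-up spacing: one measurement in each half-year", {
  pats <- rbind(fx_patient("70000000001"), fx_patient("70000000002"),
                fx_patient("70000000003"))
  cl <- rbind(
    fx_claim("70000000001", "lab_test_billed", "2018-02-10",
             analyte = "hba1c"),
    fx_claim("70000000001", "lab_test_billed", "2018-09-20",
             analyte = "hba1c"),            # months 2 and 9: true
    fx_claim("70000000002", "lab_test_billed", "2018-01-15",
             analyte = "hba1c"),
    fx_claim("70000000002", "lab_test_billed", "2018-03-15",
             analyte = "hba1c"),            # both in first quarter
    fx_claim("70000000003", "lab_test_billed", "2018-05-01",
             analyte = "hba1c"))            # single measurement
  b <- fx_bundle(pats, claims = cl)
  fu <- stageFollowUp(b, pats$ssn, cc18)
  expect_equal(fu$hba1c_2x, c(TRUE, FALSE, FALSE))
  # the alternate reading only requires two measurements in the window
  fu_any <- stageFollowUp(b, pats$ssn,
                          cascadeConfig(2018, hba1c_spacing = "any"))
  expect_equal(fu_any$hba1c_2x, c(TRUE, TRUE, FALSE))
})

test_that("stage-5 indicators and their conjunction", {
  full <- rbind(
    fx_claim("80000000001", "lab_test_billed", "2018-02-10",
             analyte = "hba1c"),
    fx_claim("80000000001", "lab_test_billed", "2018-09-20",
             analyte = "hba1c"),
    fx_claim("80000000001", "lab_test_billed", "2018-04-01",
             analyte = "ldl_c"),
    fx_claim("80000000001", "lab_test_billed", "2018-04-01",
             analyte = "albuminuria"),
    fx_claim("80000000001", "lab_test_billed", "2018-04-01",
             analyte = "creatinine"),
    fx_claim("80000000001", "foot_exam", "2018-05-05"),
    fx_claim("80000000001", "ophthalmologist_visit", "2018-06-06",
             prescriber = "specialist"))
  # patient 2: same but no ophthalmologist; full lipid panel instead of LDL
  p2 <- full[1:5, ]
  p2$patient_fk <- "80000000002"
  p2$analyte[3] <- "total_chol"
  p2 <- rbind(p2,
              fx_claim("80000000002", "lab_test_billed", "2018-04-02",
                       analyte = "hdl_c"),
              fx_claim("80000000002", "lab_test_billed", "2018-04-02",
                       analyte = "triglycerides"),
              fx_claim("80000000002", "foot_exam", "2018-05-05"))
  pats <- rbind(fx_patient("80000000001"), fx_patient("80000000002"))
  b <- fx_bundle(pats, claims = rbind(full, p2))
  fu <- stageFollowUp(b, pats$ssn, cc18)
  expect_equal(fu$stage5_all, c(TRUE, FALSE))
  expect_true(fu$lipid[2])        # panel counts as lipid profile
  expect_false(fu$ophthalmologist[2])
  expect_true(all(fu[1, c("hba1c_2x", "lipid", "microalbuminuria",
                          "creatinine_egfr", "foot_exam",
                          "ophthalmologist")] == TRUE))
})

test_that("glycaemic control: strict threshold, most recent wins, unknown
          excluded", {
  pats <- rbind(fx_patient("90000000001"), fx_patient("90000000002"),
                fx_patient("90000000003"), fx_patient("90000000004"))
  labs <- rbind(
    fx_lab("90000000001", "hba1c", 52, "2019-08-01"),   # controlled
    fx_lab("90000000002", "hba1c", 53, "2019-08-01"),   # strict <: not
    fx_lab("90000000003", "hba1c", 60, "2019-03-01"),
    fx_lab("90000000003", "hba1c", 50, "2019-10-01"))   # recency: controlled
  b <- fx_bundle(pats, labs = labs)
  linked <- fx_linked(b)
  m <- match(sort(linked$patients$patient_id), linked$patients$patient_id)
  ct <- stageControlled(linked, linked$patients$patient_id[m], cc18)
  # patient ids sort in ssn order here by construction of the fixture
  by_birth <- ct[order(ct$pid), ]
  expect_equal(sum(ct$controlled %in% TRUE), 2L)
  expect_equal(sum(ct$controlled %in% FALSE), 1L)
  expect_equal(sum(is.na(ct$controlled)), 1L)           # no HbA1c in x+1
  # band assignment around the default cut points 48/53/64
  labs2 <- rbind(fx_lab("90000000001", "hba1c", 45, "2019-08-01"),
                 fx_lab("90000000002", "hba1c", 50, "2019-08-01"),
                 fx_lab("90000000003", "hba1c", 60, "2019-08-01"),
                 fx_lab("90000000004", "hba1c", 70, "2019-08-01"))
  b2 <- fx_bundle(pats, labs = labs2)
  ct2 <- stageControlled(fx_linked(b2), fx_linked(b2)$patients$patient_id,
                         cc18)
  expect_setequal(ct2$control_band,
                  c("well_under_control", "just_under_control",
                    "just_not_under_control", "totally_not_under_control"))
})

test_that("CKD-EPI 2009 eGFR matches hand-computed values", {
  # female, 60y, Scr 0.8 mg/dL and male, 50y, Scr 1.2 mg/dL
  expect_equal(egfrCkdEpi(0.8, 60, "F"),
               141 * (0.8 / 0.7)^(-1.209) * 0.993^60 * 1.018,
               tolerance = 1e-12)
  expect_equal(round(egfrCkdEpi(0.8, 60, "F"), 1), 80.1)
  expect_equal(round(egfrCkdEpi(1.2, 50, "M"), 1), 70.1)
  # low creatinine engages the min() branch
  expect_equal(egfrCkdEpi(0.5, 40, "F"),
               141 * (0.5 / 0.7)^(-0.329) * 0.993^40 * 1.018,
               tolerance = 1e-12)
  expect_true(is.na(egfrCkdEpi(1.0, 50, "X")))
})

test_that("cohort selection equals the brute-force rule oracle", {
  for (seed in c(101, 102)) {
    cfg <- simConfig(seed = seed,
                     n_practices_per_type = c(mono_ffs = 2L, multi_ffs = 1L,
                                              multi_capitation = 1L),
                     patients_per_practice = list(mean = 40, dispersion = 8),
                     prevalence_t2d = 0.25, t1d_decoy_frac = 0.3)
    sim <- simulateClaims(cfg)
    expect_lte(nrow(sim$bundle$patients), 250)
    expect_identical(selectCohort(sim$bundle, cc18)$cohort,
                     oracle_cohort(sim$bundle, 2018))
  }
})

test_that("cascade bars: conjunction bound, order- and label-invariance", {
  cfg <- simConfig(seed = 110,
                   n_practices_per_type = c(mono_ffs = 4L, multi_ffs = 2L,
                                            multi_capitation = 2L),
                   patients_per_practice = list(mean = 120, dispersion = 8),
                   prevalence_t2d = 0.3)
  sim <- simulateClaims(cfg)
  cohort <- selectCohort(sim$bundle, cc18)$cohort
  linked <- linkClaims(sim$bundle, cohort, seed = 5)
  casc <- buildCascade(linked, cc18)
  # stage5_all never exceeds any single indicator rate, in any stratum
  for (lv in unique(casc$bars$stratum)) {
    sub <- casc$bars[casc$bars$stratum == lv, ]
    all5 <- sub$pct[sub$stage == "followed_up"]
    inds <- sub$pct[startsWith(sub$stage, "fu_")]
    expect_true(all(all5 <= inds + 1e-9), label = lv)
  }
  # row-order invariance of the claims side
  sh <- linked
  set.seed(1)
  sh$claims <- sh$claims[sample(nrow(sh$claims)), ]
  sh$pharma <- sh$pharma[sample(nrow(sh$pharma)), ]
  sh$labs <- sh$labs[sample(nrow(sh$labs)), ]
  casc2 <- buildCascade(sh, cc18)
  expect_equal(casc2$bars, casc$bars)
  # patient-id relabelling (a different linkage seed) leaves bars unchanged
  linked3 <- linkClaims(sim$bundle, cohort, seed = 99)
  # a different transport-number draw permutes the pseudonym assignment
  expect_false(identical(linked3$patients$birth_year,
                         linked$patients$birth_year))
  casc3 <- buildCascade(linked3, cc18)
  expect_equal(casc3$bars, casc$bars)
})

test_that("a single-patient cohort yields unit bars", {
  pats <- fx_patient("95000000001")
  ph <- fx_pharma("95000000001", "A10BA02", "2017-03-01")  # cohort, no more
  cl <- fx_claim("95000000001", "gp_visit", "2017-04-01")
  b <- fx_bundle(pats, claims = cl, pharma = ph)
  casc <- buildCascade(b, cc18)
  ov <- casc$bars[casc$bars$stratum == "overall", ]
  expect_equal(ov$pct[ov$stage == "in_care"], 100)
  expect_equal(ov$pct[ov$stage == "in_treatment"], 0)
  expect_equal(ov$denominator[ov$stage == "in_care"], 1L)
})
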