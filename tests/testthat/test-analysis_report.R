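# shared medium fixture: one simulated run through cohort + linkage + cascade
.analysis_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simConfig(seed = 61,
                     n_practices_per_type = c(mono_ffs = 6L, multi_ffs = 3L,
                                              multi_capitation = 3L),
                     patients_per_practice = list(mean = 150, dispersion = 8),
                     prevalence_t2d = 0.35)
    sim <- simulateClaims(cfg)
    cc <- cascadeConfig(2018)
    cohort <- selectCohort(sim$bundle, cc)$cohort
    linked <- linkClaims(sim$bundle, cohort, seed = 3)
    cascade <- buildCascade(linked, cc)
    acic <- acicScoreTable(generateAcicSurveys(cfg, sim$bundle$practices))
    cache <<- list(sim = sim, cascade = cascade, acic = acic, cc = cc,
                   linked = linked)
    cache
  }
})

test_that("the analysis frame has one row per cohort patient with practice
          scores attached", {
  fx <- .analysis_fixture()
  fr <- buildFrame(fx$cascade, fx$acic)
  expect_equal(nrow(fr), nrow(fx$cascade$patient))
  expect_false(any(fr$acic_missing))
  expect_true(all(c("acic_overall", "organization", "vulnerable", "ptype",
                    "drop_in_treatment") %in% names(fr)))
  # drop_k defined only for patients reaching stage k-1
  expect_true(all(is.na(fr$drop_in_treatment[!fr$stage3_in_care])))
  expect_true(all(!is.na(fr$drop_in_treatment[fr$stage3_in_care])))
  # shuffled inputs produce the identical frame after canonical sort
  sh <- fx$cascade
  set.seed(2)
  sh$patient <- sh$patient[sample(nrow(sh$patient)), ]
  fr2 <- buildFrame(sh, fx$acic[sample(nrow(fx$acic)), ])
  expect_equal(fr2, fr)
})

test_that("a 1-practice, 1-patient frame attaches that practice's scores", {
  pats <- fx_patient("96000000001")
  ph <- fx_pharma("96000000001", "A10BA02", "2017-03-01")
  b <- fx_bundle(pats, pharma = ph)
  casc <- buildCascade(b, cascadeConfig(2018))
  acic <- data.frame(practice_id = "PRF", rater_id = "consensus",
                     organization = 5, community_linkages = 6,
                     self_management_support = 4, decision_support = 5,
                     delivery_system_design = 7,
                     clinical_information_systems = 3, acic_overall = 5)
  fr <- buildFrame(casc, acic)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$acic_overall, 5)
})

test_that("logistic coefficients agree with an independent IRLS solver", {
  fx <- .analysis_fixture()
  fr <- buildFrame(fx$cascade, fx$acic)
  res <- dropRegressions(fr, "drop_in_treatment",
                         covariates = c("vulnerable", "age"))
  multi <- res$coefficients[res$coefficients$model_id == "multivariable", ]
  dat <- fr[!is.na(fr$drop_in_treatment), ]
  X <- cbind(1, as.numeric(dat$vulnerable), dat$age)
  orc <- oracle_logistic(X, as.numeric(dat$drop_in_treatment))
  expect_equal(unname(multi$estimate), orc$coef, tolerance = 1e-6)
  expect_equal(unname(multi$std_error), orc$se, tolerance = 1e-4)
  expect_equal(multi$odds_ratio, exp(multi$estimate))
})

test_that("a covariate unrelated to the drop has OR near 1; an injected
          vulnerability log-OR is recovered", {
  # generator with vulnerability-specific stage-4 retention: log-OR 0.7 on
  # the drop scale (retention 0.8 vs plogis(qlogis(0.8) - 0.7))
  cfg <- simConfig(seed = 62,
                   n_practices_per_type = c(mono_ffs = 6L, multi_ffs = 3L,
                                            multi_capitation = 3L),
                   patients_per_practice = list(mean = 420, dispersion = 8),
                   prevalence_t2d = 0.5, p_vulnerable = 0.4,
                   retention_by_vulnerable =
                     c(stage4 = plogis(qlogis(0.8) - 0.7)))
  sim <- simulateClaims(cfg)
  cc <- cascadeConfig(2018)
  cohort <- selectCohort(sim$bundle, cc)$cohort
  casc <- buildCascade(linkClaims(sim$bundle, cohort, seed = 4), cc)
  acic <- acicScoreTable(generateAcicSurveys(cfg, sim$bundle$practices))
  fr <- buildFrame(casc, acic)
  res <- dropRegressions(fr, "drop_in_treatment",
                         covariates = c("vulnerable", "sex"))
  co <- res$coefficients
  vul <- co[co$model_id == "bivariate_vulnerable" &
              co$term == "vulnerableTRUE", ]
  expect_lt(abs(vul$estimate - 0.7), 2 * vul$std_error)
  # sex was not used by the generator: OR compatible with 1
  sx <- co[co$model_id == "bivariate_sex" & co$term == "sexM", ]
  expect_lt(abs(sx$estimate), 3 * sx$std_error)
})

test_that("degenerate outcomes are flagged, not estimated", {
  fx <- .analysis_fixture()
  fr <- buildFrame(fx$cascade, fx$acic)
  fr$all_true <- TRUE
  res <- dropRegressions(fr, "all_true")
  expect_true(res$degenerate_outcome)
  expect_false(res$converged)
  expect_null(res$coefficients)
})


test_that("multilevel model recovers a practice-level ACIC effect", {
  fr <- .simulate_frame(50, 100, beta_acic = 0.25, sd_intercept = 0.3,
                        seed = 63)
  fit <- multilevelFit(fr, "stage4_in_treatment",
                       patient_covariates = character(0),
                       practice_covariates = "acic_overall")
  co <- fit$coefficients[fit$coefficients$term == "acic_overall", ]
  expect_gt(co$estimate, 0)                      # sign recovered
  expect_lt(abs(co$estimate - 0.25), 2 * co$std_error)
  expect_equal(fit$n_practices, 50L)
  expect_gte(fit$ranef_variance, 0)
})

test_that("zero practice heterogeneity yields near-zero intercept variance", {
  fr <- .simulate_frame(40, 120, beta_acic = 0, sd_intercept = 0, seed = 64)
  fit <- multilevelFit(fr, "stage4_in_treatment",
                       patient_covariates = character(0),
                       practice_covariates = "acic_overall")
  expect_lt(fit$ranef_variance, 0.02)
})

test_that("multilevel fit is invariant to practice relabelling and refuses a
          single practice", {
  fr <- .simulate_frame(20, 80, beta_acic = 0.3, sd_intercept = 0.4,
                        seed = 65)
  fit1 <- multilevelFit(fr, "stage4_in_treatment",
                        patient_covariates = character(0))
  fr2 <- fr
  relab <- setNames(sprintf("ZZ%03d", rev(seq_len(20))),
                    sprintf("PR%03d", seq_len(20)))
  fr2$practice_id <- unname(relab[fr2$practice_id])
  fit2 <- multilevelFit(fr2, "stage4_in_treatment",
                        patient_covariates = character(0))
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit2$ranef_variance, fit1$ranef_variance, tolerance = 1e-6)
  fr1p <- fr[fr$practice_id == "PR001", ]
  expect_error(multilevelFit(fr1p, "stage4_in_treatment",
                             patient_covariates = character(0)),
               "dropRegressions")
})

test_that("report twins equal the cascade percentages and an all-11 ACIC
          sits on the outer ring", {
  fx <- .analysis_fixture()
  rep1 <- renderReport(fx$cascade, fx$acic, fx$sim$bundle$practices)
  expect_identical(rep1$data$bars, fx$cascade$bars)
  expect_s3_class(rep1$figures$spiderweb, "ggplot")
  expect_s3_class(rep1$figures$cascade_bars, "ggplot")
  # determinism: same inputs, identical data twins
  rep2 <- renderReport(fx$cascade, fx$acic, fx$sim$bundle$practices)
  expect_identical(rep2$data, rep1$data)
  # all items 11 -> every spider axis at 11
  acic11 <- fx$acic
  for (cl in setdiff(names(acic11), c("practice_id", "rater_id")))
    acic11[[cl]] <- 11
  rep3 <- renderReport(fx$cascade, acic11, fx$sim$bundle$practices)
  expect_true(all(rep3$data$spider$score == 11))
  # written twins match the in-memory data
  d <- withr::local_tempdir()
  renderReport(fx$cascade, fx$acic, fx$sim$bundle$practices, out_dir = d)
  bars_disk <- read.csv(file.path(d, "cascade_bars.csv"))
  expect_equal(bars_disk$pct, fx$cascade$bars$pct)
  expect_true(file.exists(file.path(d, "acic_spiderweb.png")))
})
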