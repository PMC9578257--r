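.yr <- function(d) as.POSIXlt(d)$year + 1900L

#' Cascade configuration
#'
#' Windows, thresholds and reading flags of the six-stage cascade of care.
#' The treatment year is `year_x`; the selection year (cohort definition) is
#' x-1, the control year x+1, and the retrospective testing window x-3..x-1.
#'
#' @param year_x integer treatment year.
#' @param age_min minimum age in the selection year; with
#'   `age_inclusive = FALSE` (default) "above `age_min`" is read strictly
#'   (age >= `age_min` + 1). Age is computed as (x-1) - birth year.
#' @param age_inclusive include patients aged exactly `age_min`.
#' @param hba1c_control_threshold glycaemic-control threshold in mmol/mol;
#'   control means last HbA1c of year x+1 strictly below it.
#' @param control_bands ordered thresholds for the exploratory four-level
#'   control stratification (must be strictly increasing and contain the
#'   control threshold); bands are labelled `well_under_control`,
#'   `just_under_control`, `just_not_under_control`,
#'   `totally_not_under_control`.
#' @param in_care_sensitivity apply the capitation-style in-care indicator
#'   (GP-prescribed medication or lab test) to all patients, not only to
#'   capitation patients.
#' @param hba1c_spacing reading of ">= 2 HbA1c measurements (at least one in
#'   6 months)": `"half_each"` (default) requires at least one measurement in
#'   each half of the follow-up window; `"any"` requires only two
#'   measurements in the window.
#' @param followup_window `"12m"` (calendar year x, default) or `"24m"`
#'   (years x..x+1) for the follow-up indicators.
#' @return a `cascade_config` object.
#' @export
cascadeConfig <- function(year_x, age_min = 40L, age_inclusive = FALSE,
                          hba1c_control_threshold = 53,
                          control_bands = c(48, 53, 64),
                          in_care_sensitivity = FALSE,
                          hba1c_spacing = c("half_each", "any"),
                          followup_window = c("12m", "24m")) {
  hba1c_spacing <- match.arg(hba1c_spacing)
  followup_window <- match.arg(followup_window)
  if (!is.null(control_bands)) {
    if (any(diff(control_bands) <= 0))
      stop("control_bands must be strictly increasing", call. = FALSE)
    if (!hba1c_control_threshold %in% control_bands)
      stop("control_bands must contain the control threshold", call. = FALSE)
  }
  structure(list(year_x = as.integer(year_x), age_min = as.integer(age_min),
                 age_inclusive = age_inclusive,
                 hba1c_control_threshold = hba1c_control_threshold,
                 control_bands = control_bands,
                 in_care_sensitivity = in_care_sensitivity,
                 hba1c_spacing = hba1c_spacing,
                 followup_window = followup_window),
            class = "cascade_config")
}

# uniform access to claims-side tables of either a pre-linkage bundle (keyed
# by ssn) or a linked dataset (keyed by patient_id); lab result values are
# available only post-linkage
.ds_tables <- function(x) {
  if (inherits(x, "claims_bundle")) {
    pat <- x$patients
    pat$pid <- pat$ssn
    cl <- x$claims; cl$pid <- cl$patient_fk
    ph <- x$pharma; ph$pid <- ph$patient_fk
    labs <- data.frame(pid = character(0), analyte = character(0),
                       value = numeric(0), date = as.Date(character(0)))
    list(patients = pat, practices = x$practices, claims = cl, pharma = ph,
         labs = labs)
  } else if (inherits(x, "linked_dataset")) {
    pat <- x$patients; pat$pid <- pat$patient_id
    cl <- x$claims; cl$pid <- cl$patient_fk
    ph <- x$pharma; ph$pid <- ph$patient_fk
    lb <- x$labs
    labs <- data.frame(pid = lb$patient_id, analyte = lb$analyte,
                       value = lb$value, date = lb$date,
                       stringsAsFactors = FALSE)
    list(patients = pat, practices = x$practices, claims = cl, pharma = ph,
         labs = labs)
  } else stop("expected a claims_bundle or linked_dataset")
}

#' Algorithmic selection of the type-2-diabetes cohort
#'
#' Applies the claims-based identification algorithm: include patients above
#' the age threshold in the selection year x-1 with at least one antidiabetic
#' dispense (metformin, sulfonylurea or insulin) or a pre-diabetes-pass
#' registration in x-1; exclude patients with a type-1-diabetes convention or
#' insulin-pump registration in x-1 or x-2 (these reimbursements are specific
#' to type 1 diabetes).
#'
#' @param x a `claims_bundle` (pre-linkage, ssn keys) or `linked_dataset`.
#' @param config a `cascade_config`.
#' @return list with `cohort` (sorted patient keys), `exclusion_log` (counts
#'   removed by each rule) and `flags` (per-patient rule evaluation).
#' @export
selectCohort <- function(x, config) {
  stopifnot(inherits(config, "cascade_config"))
  ds <- .ds_tables(x)
  sel <- config$year_x - 1L
  min_age <- config$age_min + if (config$age_inclusive) 0L else 1L
  if (nrow(ds$pharma)) {
    yr_ph <- .yr(ds$pharma$date)
    med_sel <- unique(ds$pharma$pid[yr_ph == sel &
                                    ds$pharma$drug_class %in%
                                      .t2d_drug_classes])
  } else med_sel <- character(0)
  yr_cl <- if (nrow(ds$claims)) .yr(ds$claims$date) else integer(0)
  pass_sel <- unique(ds$claims$pid[ds$claims$category == "prediabetes_pass" &
                                   yr_cl == sel])
  t1d_ids <- unique(ds$claims$pid[ds$claims$category %in%
                                    c("t1d_convention", "insulin_pump") &
                                  yr_cl %in% c(sel, sel - 1L)])
  pat <- ds$patients
  age <- sel - pat$birth_year
  age_ok <- age >= min_age
  incl <- pat$pid %in% med_sel | pat$pid %in% pass_sel
  excl <- pat$pid %in% t1d_ids
  in_cohort <- age_ok & incl & !excl
  flags <- data.frame(pid = pat$pid, age = age, age_ok = age_ok,
                      t2d_medication = pat$pid %in% med_sel,
                      prediabetes_pass = pat$pid %in% pass_sel,
                      t1d_exclusion = excl, in_cohort = in_cohort,
                      stringsAsFactors = FALSE)
  list(cohort = sort(pat$pid[in_cohort]),
       exclusion_log = c(n_patients = nrow(pat),
                         n_meeting_inclusion = sum(incl),
                         n_removed_age = sum(incl & !age_ok),
                         n_removed_t1d = sum(incl & age_ok & excl),
                         n_cohort = sum(in_cohort)),
       flags = flags)
}

.followup_bounds <- function(config) {
  x <- config$year_x
  if (config$followup_window == "12m") {
    list(start = as.Date(sprintf("%d-01-01", x)),
         mid = as.Date(sprintf("%d-07-01", x)),
         end = as.Date(sprintf("%d-12-31", x)))
  } else {
    list(start = as.Date(sprintf("%d-01-01", x)),
         mid = as.Date(sprintf("%d-01-01", x + 1L)),
         end = as.Date(sprintf("%d-12-31", x + 1L)))
  }
}

# analyte observations (billed claims plus linked lab results) per patient
.analyte_obs <- function(ds, analytes, from, to) {
  cl <- ds$claims
  keep <- cl$category == "lab_test_billed" & cl$analyte %in% analytes &
    cl$date >= from & cl$date <= to
  obs <- data.frame(pid = cl$pid[keep], analyte = cl$analyte[keep],
                    date = cl$date[keep], stringsAsFactors = FALSE)
  lb <- ds$labs
  keep <- lb$analyte %in% analytes & lb$date >= from & lb$date <= to
  rbind(obs, data.frame(pid = lb$pid[keep], analyte = lb$analyte[keep],
                        date = lb$date[keep], stringsAsFactors = FALSE))
}

#' Stage 1 - tested
#'
#' At least one blood glucose or HbA1c test (billed lab-test claim of those
#' analytes, or linked lab result) in the three-year testing window x-3..x-1.
#'
#' @param x a `claims_bundle` or `linked_dataset`.
#' @param cohort patient keys of the diagnosed cohort.
#' @param config a `cascade_config`.
#' @return named logical vector over `cohort`.
#' @export
stageTested <- function(x, cohort, config) {
  ds <- .ds_tables(x)
  from <- as.Date(sprintf("%d-01-01", config$year_x - 3L))
  to <- as.Date(sprintf("%d-12-31", config$year_x - 1L))
  obs <- .analyte_obs(ds, c("glucose", "hba1c"), from, to)
  stats::setNames(cohort %in% obs$pid, cohort)
}

#' Stage 3 - in care
#'
#' Fee-for-service patients: at least one GP-visit claim in the selection
#' year. Capitation patients (whose GP visits are not registered): at least
#' one medication or lab-test event prescribed by a GP in the selection year.
#' With `in_care_sensitivity` the prescription indicator is applied to all
#' patients.
#'
#' @inheritParams stageTested
#' @param both also return the two component indicators.
#' @return named logical vector over `cohort`, or (with `both = TRUE`) a data
#'   frame with columns `in_care`, `visit_indicator`, `rx_indicator`.
#' @export
stageInCare <- function(x, cohort, config, both = FALSE) {
  ds <- .ds_tables(x)
  sel <- config$year_x - 1L
  cl <- ds$claims; ph <- ds$pharma
  yr_cl <- if (nrow(cl)) .yr(cl$date) else integer(0)
  visit_ids <- unique(cl$pid[cl$category == "gp_visit" & yr_cl == sel])
  rx_ids <- unique(c(
    if (nrow(ph)) ph$pid[.yr(ph$date) == sel & ph$prescriber_cat == "gp"],
    cl$pid[cl$category == "lab_test_billed" & yr_cl == sel &
           cl$prescriber_cat == "gp"]))
  scheme <- ds$patients$scheme[match(cohort, ds$patients$pid)]
  visit_ind <- cohort %in% visit_ids
  rx_ind <- cohort %in% rx_ids
  in_care <- if (config$in_care_sensitivity) rx_ind else
    ifelse(scheme == "capitation", rx_ind, visit_ind)
  if (both)
    data.frame(pid = cohort, in_care = in_care, visit_indicator = visit_ind,
               rx_indicator = rx_ind, stringsAsFactors = FALSE)
  else stats::setNames(in_care, cohort)
}

#' Stage 4 - in treatment
#'
#' At least one antidiabetic dispense in treatment year x, or — for patients
#' who entered the cohort via the pre-diabetes trajectory — at least one
#' diabetes-education or dietician consult in year x.
#'
#' @inheritParams stageTested
#' @return named logical vector over `cohort`.
#' @export
stageInTreatment <- function(x, cohort, config) {
  ds <- .ds_tables(x)
  yx <- config$year_x; sel <- yx - 1L
  ph <- ds$pharma; cl <- ds$claims
  med_x <- if (nrow(ph))
    unique(ph$pid[.yr(ph$date) == yx & ph$drug_class %in% .t2d_drug_classes])
  else character(0)
  yr_cl <- if (nrow(cl)) .yr(cl$date) else integer(0)
  pass_ids <- unique(cl$pid[cl$category == "prediabetes_pass" & yr_cl == sel])
  educ_x <- unique(cl$pid[cl$category %in%
                            c("diabetes_education", "dietician_consult") &
                          yr_cl == yx])
  stats::setNames(cohort %in% med_x |
                    (cohort %in% pass_ids & cohort %in% educ_x), cohort)
}

#' Stage 5 - followed up (six indicator booleans plus their conjunction)
#'
#' Within the follow-up window (calendar year x by default): at least two
#' HbA1c measurements with at least one in each half of the window (or simply
#' two, under the `"any"` reading); an annual lipid profile (LDL-c, or the
#' full total/HDL/triglycerides panel); an annual microalbuminuria measure;
#' an annual creatinine measurement (with eGFR computed by the CKD-EPI 2009
#' equation when the result value is linked); an annual foot examination; and
#' an annual ophthalmologist consultation. Test indicators are evaluated from
#' billed claims as well as linked lab results, so they remain computable for
#' patients whose laboratory did not participate.
#'
#' @inheritParams stageTested
#' @return data frame over `cohort`: the six indicator columns, `stage5_all`
#'   (their conjunction) and `egfr` (mL/min/1.73m2; `NA` when no linked
#'   creatinine value or missing sex/age).
#' @export
stageFollowUp <- function(x, cohort, config) {
  ds <- .ds_tables(x)
  b <- .followup_bounds(config)
  hb <- .analyte_obs(ds, "hba1c", b$start, b$end)
  hb <- unique(hb[hb$pid %in% cohort, c("pid", "date")])
  n_tot <- table(factor(hb$pid, levels = cohort))
  n_h1 <- table(factor(hb$pid[hb$date < b$mid], levels = cohort))
  n_h2 <- table(factor(hb$pid[hb$date >= b$mid], levels = cohort))
  hba1c_2x <- if (config$hba1c_spacing == "half_each")
    as.vector(n_tot) >= 2L & as.vector(n_h1) >= 1L & as.vector(n_h2) >= 1L
  else as.vector(n_tot) >= 2L

  lip <- .analyte_obs(ds, c("ldl_c", "total_chol", "hdl_c", "triglycerides"),
                      b$start, b$end)
  lipid <- cohort %in% lip$pid[lip$analyte == "ldl_c"] |
    (cohort %in% lip$pid[lip$analyte == "total_chol"] &
     cohort %in% lip$pid[lip$analyte == "hdl_c"] &
     cohort %in% lip$pid[lip$analyte == "triglycerides"])
  micro <- cohort %in% .analyte_obs(ds, "albuminuria", b$start, b$end)$pid
  creat_obs <- .analyte_obs(ds, "creatinine", b$start, b$end)
  creat <- cohort %in% creat_obs$pid

  cl <- ds$claims
  in_w <- cl$date >= b$start & cl$date <= b$end
  foot <- cohort %in% cl$pid[cl$category == "foot_exam" & in_w]
  opht <- cohort %in% cl$pid[cl$category == "ophthalmologist_visit" & in_w]

  # eGFR from the most recent linked creatinine value in the window
  lb <- ds$labs
  keep <- lb$analyte == "creatinine" & lb$date >= b$start & lb$date <= b$end &
    lb$pid %in% cohort
  egfr <- rep(NA_real_, length(cohort))
  if (any(keep)) {
    sub <- lb[keep, , drop = FALSE]
    sub <- sub[order(sub$pid, sub$date), , drop = FALSE]
    last <- sub[!duplicated(sub$pid, fromLast = TRUE), , drop = FALSE]
    m <- match(last$pid, cohort)
    pat <- ds$patients
    pm <- match(last$pid, pat$pid)
    age_x <- config$year_x - pat$birth_year[pm]
    egfr[m] <- egfrCkdEpi(last$value, age_x, pat$sex[pm])
  }
  data.frame(pid = cohort, hba1c_2x = hba1c_2x, lipid = lipid,
             microalbuminuria = micro, creatinine_egfr = creat,
             foot_exam = foot, ophthalmologist = opht,
             stage5_all = hba1c_2x & lipid & micro & creat & foot & opht,
             egfr = egfr, stringsAsFactors = FALSE)
}

#' Stage 6 - under glycaemic control
#'
#' Controlled iff the most recent linked HbA1c result of control year x+1 is
#' strictly below the threshold (53 mmol/mol). Same-day duplicates are
#' averaged. Patients without a linked HbA1c in x+1 get `NA` (unknown) and
#' are excluded from the stage-6 bar denominator, with the excluded count
#' reported alongside.
#'
#' @inheritParams stageTested
#' @return data frame over `cohort`: `controlled` (logical, `NA` unknown),
#'   `last_hba1c` (mmol/mol) and `control_band` (four-level factor per
#'   `config$control_bands`, `NA` when unknown).
#' @export
stageControlled <- function(x, cohort, config) {
  ds <- .ds_tables(x)
  yc <- config$year_x + 1L
  lb <- ds$labs
  keep <- lb$analyte == "hba1c" & .yr(lb$date) == yc & lb$pid %in% cohort
  last_v <- rep(NA_real_, length(cohort))
  if (any(keep)) {
    sub <- lb[keep, , drop = FALSE]
    sub <- sub[order(sub$pid, sub$date), , drop = FALSE]
    last_date <- tapply(as.integer(sub$date), sub$pid, max)
    is_last <- as.integer(sub$date) ==
      last_date[match(sub$pid, names(last_date))]
    v <- tapply(sub$value[is_last], sub$pid[is_last], mean)
    last_v[match(names(v), cohort)] <- as.vector(v)
  }
  controlled <- last_v < config$hba1c_control_threshold
  band <- rep(NA_character_, length(cohort))
  if (!is.null(config$control_bands)) {
    labels <- c("well_under_control", "just_under_control",
                "just_not_under_control", "totally_not_under_control")
    band <- as.character(cut(last_v, c(-Inf, config$control_bands, Inf),
                             labels = labels, right = FALSE))
  }
  data.frame(pid = cohort, controlled = controlled, last_hba1c = last_v,
             control_band = band, stringsAsFactors = FALSE)
}

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' Sex- and age-adjusted creatinine equation (no race term):
#' eGFR = 141 x min(Scr/k, 1)^a x max(Scr/k, 1)^-1.209 x 0.993^age x 1.018[F]
#' with k = 0.7 (F) / 0.9 (M) and a = -0.329 (F) / -0.411 (M).
#'
#' @param scr serum creatinine in mg/dL.
#' @param age age in years.
#' @param sex `"F"` or `"M"` (anything else yields `NA`).
#' @return eGFR in mL/min/1.73 m2.
#' @export
egfrCkdEpi <- function(scr, age, sex) {
  kappa <- ifelse(sex == "F", 0.7, ifelse(sex == "M", 0.9, NA_real_))
  alpha <- ifelse(sex == "F", -0.329, ifelse(sex == "M", -0.411, NA_real_))
  fem <- ifelse(sex == "F", 1.018, ifelse(sex == "M", 1, NA_real_))
  r <- scr / kappa
  out <- 141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age * fem
  out[!is.finite(age) | is.na(sex)] <- NA_real_
  out
}

#' Evaluate all cascade stages for a cohort
#'
#' @param x a `claims_bundle` or `linked_dataset`.
#' @param cohort patient keys (default: the full patient set of a linked
#'   dataset, which is the diagnosed cohort by construction).
#' @param config a `cascade_config`.
#' @return per-patient data frame: stage booleans (stage 2 is `TRUE` for
#'   every cohort member by construction), the six stage-5 indicators, eGFR,
#'   control band, and the two in-care component indicators.
#' @export
evaluateStages <- function(x, config, cohort = NULL) {
  if (is.null(cohort)) {
    if (inherits(x, "linked_dataset")) cohort <- x$patients$patient_id
    else cohort <- selectCohort(x, config)$cohort
  }
  cohort <- sort(unique(cohort))
  ic <- stageInCare(x, cohort, config, both = TRUE)
  fu <- stageFollowUp(x, cohort, config)
  ct <- stageControlled(x, cohort, config)
  out <- data.frame(
    pid = cohort,
    stage1_tested = unname(stageTested(x, cohort, config)),
    stage2_diagnosed = TRUE,
    stage3_in_care = ic$in_care,
    in_care_visit = ic$visit_indicator,
    in_care_rx = ic$rx_indicator,
    stage4_in_treatment = unname(stageInTreatment(x, cohort, config)),
    stringsAsFactors = FALSE)
  out <- cbind(out, fu[, setdiff(names(fu), "pid")],
               ct[, setdiff(names(ct), "pid")])
  names(out)[names(out) == "controlled"] <- "stage6_controlled"
  out
}

#' Build the cascade of care with stratified bars and leakages
#'
#' Evaluates every stage for the diagnosed cohort and aggregates the six-bar
#' cascade per stratum (overall, by practice type, by vulnerability, plus any
#' further patient columns named in `strata`). Bars for stages 1 and 3-5 use
#' the diagnosed cohort as the common denominator; the stage-6 bar uses the
#' patients with a known control status (linked HbA1c in x+1), with the
#' unknown count reported. Conditional drop rates between consecutive stages
#' are reported alongside.
#'
#' @param x a `claims_bundle` or `linked_dataset`.
#' @param config a `cascade_config`.
#' @param strata patient-level stratifiers; `"ptype"` and `"vulnerable"` are
#'   resolved automatically.
#' @param cohort optional explicit cohort (default as in `evaluateStages`).
#' @return a `cascade_result`: list with `patient` (per-patient stage table
#'   with strata columns), `bars`, `drops`, `exclusion_log` (when the cohort
#'   was selected here) and `config`.
#' @export
buildCascade <- function(x, config, strata = c("ptype", "vulnerable"),
                         cohort = NULL) {
  ds <- .ds_tables(x)
  exclusion_log <- NULL
  if (is.null(cohort) && inherits(x, "claims_bundle")) {
    selres <- selectCohort(x, config)
    cohort <- selres$cohort
    exclusion_log <- selres$exclusion_log
  }
  st <- evaluateStages(x, config, cohort)
  pat <- ds$patients
  m <- match(st$pid, pat$pid)
  st$vulnerable <- pat$vulnerable[m]
  st$sex <- pat$sex[m]
  st$age <- (config$year_x - 1L) - pat$birth_year[m]
  st$scheme <- pat$scheme[m]
  st$practice_id <- pat$practice_id[m]
  st$ptype <- ds$practices$ptype[match(st$practice_id,
                                       ds$practices$practice_id)]

  stage_cols <- c(stage1_tested = "tested", stage3_in_care = "in_care",
                  stage4_in_treatment = "in_treatment",
                  hba1c_2x = "fu_hba1c_2x", lipid = "fu_lipid",
                  microalbuminuria = "fu_microalbuminuria",
                  creatinine_egfr = "fu_creatinine_egfr",
                  foot_exam = "fu_foot_exam",
                  ophthalmologist = "fu_ophthalmologist",
                  stage5_all = "followed_up",
                  stage6_controlled = "under_control")
  one_stratum <- function(sub, var, level) {
    n <- nrow(sub)
    if (n == 0L) return(NULL)
    bars <- lapply(names(stage_cols), function(cl) {
      v <- sub[[cl]]
      den <- sum(!is.na(v))
      data.frame(stratum_var = var, stratum = level,
                 stage = stage_cols[[cl]], numerator = sum(v, na.rm = TRUE),
                 denominator = den,
                 pct = if (den) 100 * sum(v, na.rm = TRUE) / den else
                   NA_real_,
                 n_unknown = n - den, stringsAsFactors = FALSE)
    })
    cond <- function(num, den_mask) {
      den <- sum(den_mask, na.rm = TRUE)
      data.frame(n = sum(num & den_mask, na.rm = TRUE), den = den,
                 pct = if (den) 100 * sum(num & den_mask, na.rm = TRUE) / den
                 else NA_real_)
    }
    d1 <- cond(sub$stage1_tested, rep(TRUE, n))
    d3 <- cond(sub$stage3_in_care, rep(TRUE, n))
    d4 <- cond(sub$stage4_in_treatment, sub$stage3_in_care)
    d5 <- cond(sub$stage5_all, sub$stage4_in_treatment)
    known <- !is.na(sub$stage6_controlled)
    d6 <- cond(!is.na(sub$stage6_controlled) & sub$stage6_controlled %in% TRUE,
               sub$stage5_all & known)
    drops <- data.frame(
      stratum_var = var, stratum = level,
      stage = c("tested", "in_care", "in_treatment", "followed_up",
                "under_control"),
      conditional_on = c("cohort", "cohort", "in_care", "in_treatment",
                         "followed_up_known_control"),
      numerator = c(d1$n, d3$n, d4$n, d5$n, d6$n),
      denominator = c(d1$den, d3$den, d4$den, d5$den, d6$den),
      retained_pct = c(d1$pct, d3$pct, d4$pct, d5$pct, d6$pct),
      stringsAsFactors = FALSE)
    drops$drop_pct <- 100 - drops$retained_pct
    list(bars = do.call(rbind, bars), drops = drops)
  }

  pieces <- list(one_stratum(st, "overall", "overall"))
  for (sv in strata) {
    if (!sv %in% names(st)) {
      warning("unknown stratum variable '", sv, "' skipped")
      next
    }
    for (lv in sort(unique(as.character(st[[sv]])))) {
      sub <- st[as.character(st[[sv]]) == lv, , drop = FALSE]
      piece <- one_stratum(sub, sv, lv)
      if (is.null(piece))
        warning("stratum ", sv, "=", lv, " has no cohort members; omitted")
      pieces <- c(pieces, list(piece))
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  structure(list(patient = st,
                 bars = do.call(rbind, lapply(pieces, `[[`, "bars")),
                 drops = do.call(rbind, lapply(pieces, `[[`, "drops")),
                 exclusion_log = exclusion_log, config = config),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  ov <- x$bars[x$bars$stratum_var == "overall", ]
  cat(sprintf("cascade_result: %d cohort patients\n", nrow(x$patient)))
  main <- ov[ov$stage %in% c("tested", "in_care", "in_treatment",
                             "followed_up", "under_control"), ]
  for (i in seq_len(nrow(main)))
    cat(sprintf("  %-14s %5.1f%%  (%d/%d)\n", main$stage[i], main$pct[i],
                main$numerator[i], main$denominator[i]))
  invisible(x)
}

#' Serialize a cascade result to JSON (bars, drops, numerators/denominators)
#'
#' @param cascade a `cascade_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeCascade <- function(cascade, path) {
  stopifnot(inherits(cascade, "cascade_result"))
  jsonlite::write_json(list(bars = cascade$bars, drops = cascade$drops,
                            exclusion_log = as.list(cascade$exclusion_log)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
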