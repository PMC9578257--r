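# Hand-built micro-bundles for rule-level tests, and small independent
# oracles (brute-force cohort rules, IRLS logistic solver).

fx_patient <- function(ssn, birth_year = 1960L, sex = "F",
                       vulnerable = FALSE, scheme = "ffs",
                       practice_id = "PRF", region = "antwerp") {
  data.frame(ssn = ssn, patient_id = "", birth_year = as.integer(birth_year),
             sex = sex, vulnerable = vulnerable, scheme = scheme,
             practice_id = practice_id, region = region,
             stringsAsFactors = FALSE)
}

fx_practices <- function() {
  data.frame(practice_id = c("PRF", "PRM", "PRC"),
             ptype = c("mono_ffs", "multi_ffs", "multi_capitation"),
             region = "antwerp", n_gps = c(1L, 3L, 4L),
             gp_ids = c("PRF-G1", "PRM-G1;PRM-G2;PRM-G3",
                        "PRC-G1;PRC-G2;PRC-G3;PRC-G4"),
             stringsAsFactors = FALSE)
}

fx_claim <- function(ssn, category, date, prescriber = "gp", analyte = "") {
  data.frame(event_id = "", patient_fk = ssn, category = category,
             analyte = analyte, date = as.Date(date),
             prescriber_cat = prescriber, cost_ziv = 10, cost_pers = 0,
             suppl = 0, stringsAsFactors = FALSE)
}

fx_pharma <- function(ssn, atc, date, prescriber = "gp") {
  data.frame(event_id = "", patient_fk = ssn, atc_code = atc,
             drug_class = atcToDrugClass(atc), date = as.Date(date),
             prescriber_cat = prescriber, cost_ziv = 10, cost_pers = 0,
             suppl = 0, stringsAsFactors = FALSE)
}

fx_lab <- function(ssn, analyte, value, date, lab_id = "L01") {
  units <- c(hba1c = "mmol/mol", ldl_c = "mg/dL", total_chol = "mg/dL",
             hdl_c = "mg/dL", triglycerides = "mg/dL", creatinine = "mg/dL",
             albuminuria = "mg/g", glucose = "mg/dL")
  loinc <- c(hba1c = "59261-8", ldl_c = "13457-7", total_chol = "2093-3",
             hdl_c = "2085-9", triglycerides = "2571-8",
             creatinine = "2160-0", albuminuria = "14957-5",
             glucose = "2345-7")
  data.frame(result_id = "", lab_id = lab_id,
             lab_patient_key = paste0("K-", lab_id, "-", ssn),
             loinc_code = loinc[[analyte]], analyte = analyte, value = value,
             units = units[[analyte]], date = as.Date(date),
             stringsAsFactors = FALSE)
}

fx_bundle <- function(patients, claims = NULL, pharma = NULL, labs = NULL,
                      n_labs = 2L, participating = "L01") {
  number <- function(df, prefix) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    df$event_id <- sprintf("%s%05d", prefix, seq_len(nrow(df)))
    df
  }
  if (!is.null(labs) && nrow(labs))
    labs$result_id <- sprintf("R%05d", seq_len(nrow(labs)))
  lab_ids <- sprintf("L%02d", seq_len(n_labs))
  registry <- data.frame(lab_id = lab_ids,
                         participating = lab_ids %in% participating,
                         stringsAsFactors = FALSE)
  keymap <- if (!is.null(labs) && nrow(labs)) {
    unique(data.frame(lab_id = labs$lab_id,
                      lab_patient_key = labs$lab_patient_key,
                      ssn = sub("^K-L[0-9]+-", "", labs$lab_patient_key),
                      stringsAsFactors = FALSE))
  } else NULL
  claimsBundle(patients = patients, practices = fx_practices(),
               claims = number(claims, "C"), pharma = number(pharma, "D"),
               labs = labs, lab_registry = registry, lab_keymap = keymap)
}

# links a micro-bundle with every patient in the cohort (unless given)
fx_linked <- function(bundle, cohort = NULL, participating_labs = NULL,
                      seed = 1) {
  if (is.null(cohort)) cohort <- bundle$patients$ssn
  linkClaims(bundle, cohort, participating_labs = participating_labs,
             seed = seed)
}

# Brute-force per-patient evaluation of the cohort inclusion/exclusion rules,
# written independently of selectCohort (explicit row loops).
oracle_cohort <- function(bundle, year_x, age_min = 40L,
                          age_inclusive = FALSE) {
  sel <- year_x - 1L
  out <- character(0)
  for (i in seq_len(nrow(bundle$patients))) {
    p <- bundle$patients[i, ]
    age <- sel - p$birth_year
    if (if (age_inclusive) age < age_min else age <= age_min) next
    med <- FALSE; pass <- FALSE; t1d <- FALSE
    ph <- bundle$pharma
    for (j in seq_len(nrow(ph))) {
      if (ph$patient_fk[j] == p$ssn &&
          format(ph$date[j], "%Y") == as.character(sel) &&
          ph$drug_class[j] %in% c("metformin", "sulfonylurea", "insulin"))
        med <- TRUE
    }
    cl <- bundle$claims
    for (j in seq_len(nrow(cl))) {
      if (cl$patient_fk[j] != p$ssn) next
      y <- as.integer(format(cl$date[j], "%Y"))
      if (cl$category[j] == "prediabetes_pass" && y == sel) pass <- TRUE
      if (cl$category[j] %in% c("t1d_convention", "insulin_pump") &&
          (y == sel || y == sel - 1L)) t1d <- TRUE
    }
    if ((med || pass) && !t1d) out <- c(out, p$ssn)
  }
  sort(out)
}

# Newton-Raphson / IRLS logistic regression, independent of stats::glm.
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(coef = beta, se = se)
}

small_sim <- function(seed = 7, mean_patients = 120, ...) {
  simConfig(seed = seed,
            n_practices_per_type = c(mono_ffs = 4L, multi_ffs = 2L,
                                     multi_capitation = 2L),
            patients_per_practice = list(mean = mean_patients,
                                         dispersion = 8),
            ...)
}

# simulate an analysis frame directly from a known multilevel logistic model
.simulate_frame <- function(n_practices, n_per, beta_acic, sd_intercept,
                            seed) {
  set.seed(seed)
  acic <- round(runif(n_practices, 2, 9), 2)
  u <- rnorm(n_practices, 0, sd_intercept)
  pr <- plogis(qlogis(0.7) + beta_acic * rep(acic - mean(acic), each = n_per) +
                 rep(u, each = n_per))
  data.frame(
    pid = sprintf("PT%05d", seq_len(n_practices * n_per)),
    practice_id = rep(sprintf("PR%03d", seq_len(n_practices)),
                      each = n_per),
    acic_overall = rep(acic, each = n_per),
    acic_missing = FALSE,
    stage4_in_treatment = runif(n_practices * n_per) < pr,
    stringsAsFactors = FALSE)
}
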