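.ptypes <- c("mono_ffs", "multi_ffs", "multi_capitation")

.acic_default_items <- c(organization = 6L, community_linkages = 3L,
                         self_management_support = 4L, decision_support = 4L,
                         delivery_system_design = 6L,
                         clinical_information_systems = 5L)

#' Simulation configuration
#'
#' Study-design parameters of the synthetic claims generator. Defaults emulate
#' the sampling frame of a Flemish primary-care quality study: 66 practices of
#' three organizational types hosting a 40+ insured population of roughly
#' 86,000, a 4.2% identifiable type-2-diabetes prevalence, a three-year
#' observation window around treatment year `study_year_x`, and 12 regional
#' laboratories of which two thirds deliver data, the participating ones being
#' the larger labs covering about 74% of patients.
#'
#' @param seed integer RNG seed; generation is a pure function of the config.
#' @param n_practices_per_type named integer vector (`mono_ffs`, `multi_ffs`,
#'   `multi_capitation`).
#' @param patients_per_practice list with `mean` and `dispersion` (negative
#'   binomial size) of the per-practice 40+ patient count.
#' @param study_year_x treatment year x; selection year is x-1, control year
#'   x+1, the testing window x-3..x-1.
#' @param prevalence_t2d probability that a patient is an identifiable
#'   type-2-diabetes patient (realized among patients old enough to enter the
#'   cohort, scaled so the population fraction equals this value).
#' @param frac_prediabetes_pass fraction of T2D patients entering via the
#'   pre-diabetes care trajectory (no medication in the selection year).
#' @param p_vulnerable probability of the socio-economic vulnerability marker.
#' @param t1d_decoy_frac type-1 decoys (insulin users carrying a T1D
#'   convention or insulin-pump registration) as a fraction of T2D medication
#'   users.
#' @param stage_retention named probabilities `stage1`, `stage3` .. `stage6`.
#'   Stage 2 defines the cohort. Stages 3-6 are conditional retentions
#'   (probability of meeting the stage given the previous stage was met);
#'   stage 1 is unconditional.
#' @param retention_by_ptype optional named list: practice type -> named
#'   vector overriding individual stage retentions for that type.
#' @param retention_by_vulnerable optional named vector overriding stage
#'   retentions for vulnerable patients (applied after the ptype override).
#' @param n_labs number of laboratories.
#' @param lab_participation fraction of labs delivering data (8/12 default).
#' @param lab_assignment `"size_weighted"` (participating labs jointly cover
#'   `participating_coverage` of patients) or `"round_robin"` (uniform).
#' @param participating_coverage patient share of the participating labs
#'   under size-weighted assignment.
#' @param n_gps_mean named vector, mean GP head count per practice type.
#' @param hba1c_control list with `controlled_mean`, `controlled_sd`,
#'   `uncontrolled_mean`, `uncontrolled_sd` in mmol/mol; controlled values are
#'   drawn truncated below 53, uncontrolled truncated at or above 53.
#' @param p_screened_background probability that a non-diabetic patient has a
#'   billed glucose test in the testing window.
#' @param gp_visit_rate_background mean GP visits of non-diabetic FFS
#'   patients over the window.
#' @param p_hospitalization per-patient probability of one hospital stay.
#' @param cost_meanlog,cost_sdlog lognormal parameters for reimbursed costs.
#' @param acic list of ACIC generator parameters: `base_mean`,
#'   `capitation_shift` (mean shift of multi_capitation practices),
#'   `between_sd`, `item_sd`, `rater_sd`, and `items` (named integer vector of
#'   items per subscale).
#' @return a validated `sim_config` object (named list).
#' @export
simConfig <- function(seed = 1L,
                      n_practices_per_type = c(mono_ffs = 44L, multi_ffs = 12L,
                                               multi_capitation = 10L),
                      patients_per_practice = list(mean = 1300, dispersion = 8),
                      study_year_x = 2018L,
                      prevalence_t2d = 0.042,
                      frac_prediabetes_pass = 0.15,
                      p_vulnerable = 0.2,
                      t1d_decoy_frac = 0.10,
                      stage_retention = c(stage1 = 0.95, stage3 = 0.90,
                                          stage4 = 0.80, stage5 = 0.70,
                                          stage6 = 0.60),
                      retention_by_ptype = NULL,
                      retention_by_vulnerable = NULL,
                      n_labs = 12L,
                      lab_participation = 8 / 12,
                      lab_assignment = c("size_weighted", "round_robin"),
                      participating_coverage = 0.738,
                      n_gps_mean = c(mono_ffs = 2.3, multi_ffs = 7,
                                     multi_capitation = 9),
                      hba1c_control = list(controlled_mean = 46,
                                           controlled_sd = 4,
                                           uncontrolled_mean = 64,
                                           uncontrolled_sd = 8),
                      p_screened_background = 0.5,
                      gp_visit_rate_background = 1.5,
                      p_hospitalization = 0.05,
                      cost_meanlog = 3, cost_sdlog = 0.6,
                      acic = list()) {
  lab_assignment <- match.arg(lab_assignment)
  acic_defaults <- list(base_mean = 5.5, capitation_shift = 1.5,
                        between_sd = 1, item_sd = 1, rater_sd = 0.5,
                        items = .acic_default_items)
  acic <- utils::modifyList(acic_defaults, acic)
  cfg <- list(seed = as.integer(seed),
              n_practices_per_type = n_practices_per_type,
              patients_per_practice = patients_per_practice,
              study_year_x = as.integer(study_year_x),
              prevalence_t2d = prevalence_t2d,
              frac_prediabetes_pass = frac_prediabetes_pass,
              p_vulnerable = p_vulnerable,
              t1d_decoy_frac = t1d_decoy_frac,
              stage_retention = stage_retention,
              retention_by_ptype = retention_by_ptype,
              retention_by_vulnerable = retention_by_vulnerable,
              n_labs = as.integer(n_labs),
              lab_participation = lab_participation,
              lab_assignment = lab_assignment,
              participating_coverage = participating_coverage,
              n_gps_mean = n_gps_mean,
              hba1c_control = hba1c_control,
              p_screened_background = p_screened_background,
              gp_visit_rate_background = gp_visit_rate_background,
              p_hospitalization = p_hospitalization,
              cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
              acic = acic)
  class(cfg) <- "sim_config"
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  probs <- c(cfg$prevalence_t2d, cfg$frac_prediabetes_pass, cfg$p_vulnerable,
             cfg$t1d_decoy_frac, cfg$lab_participation,
             cfg$participating_coverage, cfg$p_screened_background,
             cfg$p_hospitalization, cfg$stage_retention)
  if (any(probs < 0 | probs > 1))
    stop("config error: all probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_labs < 1L) stop("config error: n_labs must be >= 1",
                            call. = FALSE)
  req <- c("stage1", "stage3", "stage4", "stage5", "stage6")
  if (!all(req %in% names(cfg$stage_retention)))
    stop("config error: stage_retention must name stages 1 and 3-6",
         call. = FALSE)
  if (!all(names(cfg$n_practices_per_type) %in% .ptypes) ||
      !all(.ptypes %in% names(cfg$n_practices_per_type)))
    stop("config error: n_practices_per_type must name exactly the three ",
         "practice types", call. = FALSE)
  if (!is.null(cfg$retention_by_ptype)) {
    bad <- setdiff(names(cfg$retention_by_ptype), .ptypes)
    if (length(bad))
      stop("config error: retention stratum without matching ptype: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are `simConfig()` arguments.
#' @return a `sim_config`.
#' @export
readSimConfig <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("n_practices_per_type", "stage_retention", "n_gps_mean",
               "retention_by_vulnerable"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$retention_by_ptype))
    args$retention_by_ptype <- lapply(args$retention_by_ptype, unlist)
  do.call(simConfig, args)
}

# date drawn uniformly within a calendar year (or a span of whole years)
.runif_date <- function(n, year_from, year_to = year_from) {
  d0 <- as.Date(sprintf("%d-01-01", year_from))
  d1 <- as.Date(sprintf("%d-12-31", year_to))
  d0 + floor(stats::runif(n) * (as.integer(d1 - d0) + 1L))
}

.runif_date_half <- function(n, year, half) {
  d0 <- as.Date(sprintf("%d-%s", year, if (half == 1L) "01-01" else "07-01"))
  d1 <- as.Date(sprintf("%d-%s", year, if (half == 1L) "06-30" else "12-31"))
  d0 + floor(stats::runif(n) * (as.integer(d1 - d0) + 1L))
}

# truncated normal draws via the inverse-cdf trick (vectorized)
.rnorm_below <- function(n, mean, sd, upper) {
  p <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n) * p)
}
.rnorm_above <- function(n, mean, sd, lower) {
  p <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p + stats::runif(n) * (1 - p))
}

.draw_costs <- function(n, cfg) {
  data.frame(
    cost_ziv = round(stats::rlnorm(n, cfg$cost_meanlog, cfg$cost_sdlog), 2),
    cost_pers = round(stats::rlnorm(n, cfg$cost_meanlog - 2, cfg$cost_sdlog), 2),
    suppl = round(stats::rlnorm(n, cfg$cost_meanlog - 3, cfg$cost_sdlog) *
                    stats::rbinom(n, 1L, 0.3), 2))
}

.atc_pool <- list(metformin = c("A10BA02"),
                  sulfonylurea = c("A10BB01", "A10BB09", "A10BB12"),
                  insulin = c("A10AB01", "A10AC01", "A10AE04"))

# effective per-patient retention for one stage, applying the ptype override
# then the vulnerability override
.effective_retention <- function(cfg, stage, ptype, vulnerable) {
  r <- rep(cfg$stage_retention[[stage]], length(ptype))
  if (!is.null(cfg$retention_by_ptype)) {
    for (pt in names(cfg$retention_by_ptype)) {
      o <- cfg$retention_by_ptype[[pt]]
      if (stage %in% names(o)) r[ptype == pt] <- o[[stage]]
    }
  }
  o <- cfg$retention_by_vulnerable
  if (!is.null(o) && stage %in% names(o)) r[vulnerable] <- o[[stage]]
  r
}

#' Simulate a synthetic claims bundle with ground-truth labels
#'
#' Generates GP practices, their insured 40+ patient populations and
#' longitudinal claims, pharmaceutical, laboratory and hospitalization events
#' over the window x-3 .. x+1 around `study_year_x`. Every intended cascade
#' status in the returned truth labels is realized as events that make the
#' corresponding operational rule evaluate to that status: T2D patients carry
#' antidiabetic dispenses or a pre-diabetes pass in the selection year; type-1
#' decoys carry insulin plus a T1D-convention or insulin-pump registration;
#' capitation patients never receive GP-visit claims (a registration artifact
#' of the payment system) but, when in care, receive GP-prescribed medication
#' or lab events; glycaemic control is realized as the last HbA1c of year x+1
#' falling below or at/above 53 mmol/mol. Generation is a pure function of
#' `config` (byte-identical bundles under the same seed).
#'
#' @param config a `sim_config`.
#' @return list with elements `bundle` (a validated `claims_bundle`, keyed by
#'   `ssn` pre-linkage) and `truth` (data frame of per-patient ground-truth
#'   labels: `is_t2d`, `has_prediabetes_pass`, `is_t1d`, intended stage
#'   statuses; stage labels are `NA` for non-T2D patients).
#' @export
simulateClaims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  x <- cfg$study_year_x
  sel <- x - 1L

  ## -- practices -----------------------------------------------------------
  ptype <- rep(names(cfg$n_practices_per_type), cfg$n_practices_per_type)
  np <- length(ptype)
  practice_id <- sprintf("PR%03d", seq_len(np))
  region <- sample(c("antwerp", "ghent", "kempenland"), np, replace = TRUE)
  n_gps <- 1L + stats::rpois(np, pmax(cfg$n_gps_mean[ptype] - 1, 0))
  gp_ids <- vapply(seq_len(np), function(i)
    paste0(practice_id[i], "-G", seq_len(n_gps[i]), collapse = ";"),
    character(1))
  practices <- data.frame(practice_id = practice_id, ptype = ptype,
                          region = region, n_gps = n_gps, gp_ids = gp_ids,
                          stringsAsFactors = FALSE)

  ## -- patients ------------------------------------------------------------
  n_pat <- pmax(1L, stats::rnbinom(np, mu = cfg$patients_per_practice$mean,
                                   size = cfg$patients_per_practice$dispersion))
  N <- sum(n_pat)
  p_practice <- rep(practice_id, n_pat)
  p_ptype <- rep(ptype, n_pat)
  p_region <- rep(region, n_pat)
  ssn <- sprintf("%05d%06d", sample(10000:99999, N, replace = TRUE),
                 sample.int(N))
  age_sel <- sample(40:94, N, replace = TRUE,
                    prob = exp(-(0:54) / 20))
  birth_year <- sel - age_sel
  sex <- sample(c("F", "M"), N, replace = TRUE)
  vulnerable <- stats::runif(N) < cfg$p_vulnerable
  scheme <- ifelse(p_ptype == "multi_capitation", "capitation", "ffs")
  patients <- data.frame(ssn = ssn, patient_id = "", birth_year = birth_year,
                         sex = sex, vulnerable = vulnerable, scheme = scheme,
                         practice_id = p_practice, region = p_region,
                         stringsAsFactors = FALSE)

  ## -- disease truth -------------------------------------------------------
  eligible <- age_sel >= 41L          # strict "above 40" at year x-1
  p_t2d <- min(1, cfg$prevalence_t2d / max(mean(eligible), 1e-9))
  is_t2d <- eligible & stats::runif(N) < p_t2d
  has_pass <- is_t2d & stats::runif(N) < cfg$frac_prediabetes_pass
  med_user <- is_t2d & !has_pass
  n_decoy <- round(cfg$t1d_decoy_frac * sum(med_user))
  decoy_pool <- which(!is_t2d & eligible)
  is_t1d <- rep(FALSE, N)
  if (n_decoy > 0 && length(decoy_pool))
    is_t1d[sample(decoy_pool, min(n_decoy, length(decoy_pool)))] <- TRUE

  ## -- intended cascade statuses (chain of conditional retentions) ---------
  r <- function(stage) .effective_retention(cfg, stage, p_ptype, vulnerable)
  s1 <- is_t2d & stats::runif(N) < r("stage1")
  s3 <- is_t2d & stats::runif(N) < r("stage3")
  s4 <- s3 & stats::runif(N) < r("stage4")
  s5 <- s4 & stats::runif(N) < r("stage5")
  s6 <- s4 & stats::runif(N) < r("stage6")  # control status, realized in x+1

  ind_names <- c("hba1c_2x", "lipid", "microalbuminuria", "creatinine_egfr",
                 "foot_exam", "ophthalmologist")
  ind <- matrix(FALSE, N, 6, dimnames = list(NULL, ind_names))
  ind[s5, ] <- TRUE
  partial <- which(s4 & !s5)
  if (length(partial)) {
    draw <- matrix(stats::runif(length(partial) * 6) < 0.55,
                   length(partial), 6)
    allt <- rowSums(draw) == 6L
    if (any(allt))
      draw[cbind(which(allt), sample.int(6, sum(allt), replace = TRUE))] <- FALSE
    ind[partial, ] <- draw
  }

  ## -- event assembly ------------------------------------------------------
  claims <- list(); pharma <- list(); labtests <- list()
  add_claims <- function(idx, category, date, prescriber, analyte = "") {
    n <- length(idx)
    if (!n) return(invisible(NULL))
    claims[[length(claims) + 1L]] <<- cbind(
      data.frame(patient_fk = ssn[idx], category = category,
                 analyte = analyte, date = date, prescriber_cat = prescriber,
                 stringsAsFactors = FALSE),
      .draw_costs(n, cfg))
  }
  add_pharma <- function(idx, drug_class, date, prescriber) {
    n <- length(idx)
    if (!n) return(invisible(NULL))
    atc <- vapply(drug_class, function(dc)
      .atc_pool[[dc]][sample.int(length(.atc_pool[[dc]]), 1L)], character(1))
    pharma[[length(pharma) + 1L]] <<- cbind(
      data.frame(patient_fk = ssn[idx], atc_code = unname(atc),
                 drug_class = drug_class, date = date,
                 prescriber_cat = prescriber, stringsAsFactors = FALSE),
      .draw_costs(n, cfg))
  }
  # a laboratory test produces both a billed claim and a lab-side result row
  add_labtest <- function(idx, analyte, date, value, prescriber = "gp") {
    n <- length(idx)
    if (!n) return(invisible(NULL))
    labtests[[length(labtests) + 1L]] <<- data.frame(
      patient_idx = idx, analyte = analyte, date = date, value = value,
      prescriber_cat = prescriber, stringsAsFactors = FALSE)
  }

  cap <- scheme == "capitation"

  # selection-year antidiabetic dispenses (cohort entry for medication users)
  mu_idx <- which(med_user)
  if (length(mu_idx)) {
    ndisp <- 1L + stats::rpois(length(mu_idx), 1.5)
    idx <- rep(mu_idx, ndisp)
    dc <- sample(.t2d_drug_classes, length(idx), replace = TRUE,
                 prob = c(0.60, 0.25, 0.15))
    presc <- ifelse(cap[idx],
                    ifelse(s3[idx], "gp", "specialist"),
                    ifelse(stats::runif(length(idx)) < 0.8, "gp",
                           "specialist"))
    add_pharma(idx, dc, .runif_date(length(idx), sel), presc)
  }

  # pre-diabetes pass registrations
  pp_idx <- which(has_pass)
  add_claims(pp_idx, "prediabetes_pass", .runif_date(length(pp_idx), sel),
             "other")

  # stage 3 realization: FFS -> GP visit(s); capitation pass-entry patients
  # in care get a GP-prescribed billed lab test (their medication carries the
  # GP prescriber only for medication users)
  ffs3 <- which(s3 & !cap)
  if (length(ffs3)) {
    nv <- 1L + stats::rpois(length(ffs3), 1)
    idx <- rep(ffs3, nv)
    add_claims(idx, "gp_visit", .runif_date(length(idx), sel), "gp")
  }
  cap3_pass <- which(s3 & cap & has_pass)
  add_labtest(cap3_pass, "total_chol",
              .runif_date(length(cap3_pass), sel),
              round(pmax(stats::rnorm(length(cap3_pass), 190, 35), 80), 1))

  # stage 1 realization: glucose/HbA1c test billed in the testing window
  s1_idx <- which(s1)
  if (length(s1_idx)) {
    an <- sample(c("glucose", "hba1c"), length(s1_idx), replace = TRUE)
    val <- ifelse(an == "glucose",
                  round(pmax(stats::rnorm(length(s1_idx), 115, 25), 40), 1),
                  round(pmin(pmax(stats::rnorm(length(s1_idx), 55, 9), 20),
                             150), 1))
    add_labtest(s1_idx, an, .runif_date(length(s1_idx), x - 3L, sel), val)
  }

  # stage 4 realization: treatment-year dispenses, or education/dietician
  # consults for the pre-diabetes trajectory
  t4_med <- which(s4 & med_user)
  if (length(t4_med)) {
    ndisp <- 1L + stats::rpois(length(t4_med), 1.5)
    idx <- rep(t4_med, ndisp)
    dc <- sample(.t2d_drug_classes, length(idx), replace = TRUE,
                 prob = c(0.60, 0.25, 0.15))
    presc <- ifelse(stats::runif(length(idx)) < 0.8, "gp", "specialist")
    add_pharma(idx, dc, .runif_date(length(idx), x), presc)
  }
  t4_pass <- which(s4 & has_pass)
  if (length(t4_pass)) {
    categ <- sample(c("diabetes_education", "dietician_consult"),
                    length(t4_pass), replace = TRUE)
    add_claims(t4_pass, categ, .runif_date(length(t4_pass), x), "gp")
  }

  # stage 5 follow-up indicators in the 12 months of year x
  h_mean <- 55; h_sd <- 8
  hb2 <- which(ind[, "hba1c_2x"])
  if (length(hb2)) {
    add_labtest(hb2, "hba1c", .runif_date_half(length(hb2), x, 1L),
                round(pmin(pmax(stats::rnorm(length(hb2), h_mean, h_sd), 20),
                           150), 1))
    add_labtest(hb2, "hba1c", .runif_date_half(length(hb2), x, 2L),
                round(pmin(pmax(stats::rnorm(length(hb2), h_mean, h_sd), 20),
                           150), 1))
  }
  hb_not <- which(s4 & !ind[, "hba1c_2x"])
  if (length(hb_not)) {
    u <- stats::runif(length(hb_not))
    one <- hb_not[u >= 0.35 & u < 0.75]       # a single measurement
    two <- hb_not[u >= 0.75]                  # two, both in the same half
    add_labtest(one, "hba1c", .runif_date(length(one), x),
                round(pmin(pmax(stats::rnorm(length(one), h_mean, h_sd), 20),
                           150), 1))
    if (length(two)) {
      half <- sample(1:2, length(two), replace = TRUE)
      for (h in 1:2) {
        tw <- two[half == h]
        for (k in 1:2)
          add_labtest(tw, "hba1c", .runif_date_half(length(tw), x, h),
                      round(pmin(pmax(stats::rnorm(length(tw), h_mean, h_sd),
                                      20), 150), 1))
      }
    }
  }
  lp <- which(ind[, "lipid"])
  if (length(lp)) {
    panel <- stats::runif(length(lp)) < 0.25
    ld <- lp[!panel]
    add_labtest(ld, "ldl_c", .runif_date(length(ld), x),
                round(pmax(stats::rnorm(length(ld), 110, 30), 20), 1))
    pn <- lp[panel]
    if (length(pn)) {
      pd <- .runif_date(length(pn), x)
      add_labtest(pn, "total_chol", pd,
                  round(pmax(stats::rnorm(length(pn), 190, 35), 80), 1))
      add_labtest(pn, "hdl_c", pd,
                  round(pmax(stats::rnorm(length(pn), 50, 12), 15), 1))
      add_labtest(pn, "triglycerides", pd,
                  round(pmax(stats::rnorm(length(pn), 150, 60), 30), 1))
    }
  }
  ma <- which(ind[, "microalbuminuria"])
  add_labtest(ma, "albuminuria", .runif_date(length(ma), x),
              round(stats::rlnorm(length(ma), log(15), 0.8), 1))
  cr <- which(ind[, "creatinine_egfr"])
  add_labtest(cr, "creatinine", .runif_date(length(cr), x),
              round(stats::rlnorm(length(cr), log(0.95), 0.25), 2))
  fe <- which(ind[, "foot_exam"])
  add_claims(fe, "foot_exam", .runif_date(length(fe), x), "gp")
  op <- which(ind[, "ophthalmologist"])
  add_claims(op, "ophthalmologist_visit", .runif_date(length(op), x),
             "specialist")

  # stage 6 realization: last HbA1c of year x+1 below / at-or-above threshold
  t6 <- which(s4)
  if (length(t6)) {
    hc <- cfg$hba1c_control
    v_last <- numeric(length(t6))
    ctl <- s6[t6]
    v_last[ctl] <- pmin(round(.rnorm_below(sum(ctl), hc$controlled_mean,
                                           hc$controlled_sd, 53), 1), 52.9)
    v_last[!ctl] <- pmax(round(.rnorm_above(sum(!ctl), hc$uncontrolled_mean,
                                            hc$uncontrolled_sd, 53), 1), 53)
    v_last <- pmin(pmax(v_last, 20), 190)
    d_last <- .runif_date_half(length(t6), x + 1L, 2L)
    # an optional earlier measurement, sometimes on the other side of the
    # threshold, exercising the most-recent-wins rule
    extra <- stats::runif(length(t6)) < 0.3
    ei <- which(extra)
    if (length(ei)) {
      flip <- stats::runif(length(ei)) < 0.5
      v_e <- ifelse(xor(ctl[ei], flip),
                    pmin(round(.rnorm_below(length(ei), hc$controlled_mean,
                                            hc$controlled_sd, 53), 1), 52.9),
                    pmax(round(.rnorm_above(length(ei), hc$uncontrolled_mean,
                                            hc$uncontrolled_sd, 53), 1), 53))
      v_e <- pmin(pmax(v_e, 20), 190)
      add_labtest(t6[ei], "hba1c", .runif_date_half(length(ei), x + 1L, 1L),
                  v_e)
    }
    add_labtest(t6, "hba1c", d_last, v_last)
  }

  # type-1 decoys: insulin dispenses plus a T1D registration in x-1 or x-2
  dc_idx <- which(is_t1d)
  if (length(dc_idx)) {
    ndisp <- 1L + stats::rpois(length(dc_idx), 2)
    idx <- rep(dc_idx, ndisp)
    add_pharma(idx, rep("insulin", length(idx)),
               .runif_date(length(idx), sel), rep("specialist", length(idx)))
    categ <- sample(c("t1d_convention", "insulin_pump"), length(dc_idx),
                    replace = TRUE)
    yr <- sample(c(sel - 1L, sel), length(dc_idx), replace = TRUE)
    add_claims(dc_idx, categ,
               as.Date(sprintf("%d-01-01", yr)) +
                 floor(stats::runif(length(dc_idx)) * 365),
               "specialist")
  }

  # background care of the non-diabetic population
  bg <- which(!is_t2d & !is_t1d)
  scr <- bg[stats::runif(length(bg)) < cfg$p_screened_background]
  add_labtest(scr, "glucose", .runif_date(length(scr), x - 3L, sel),
              round(pmax(stats::rnorm(length(scr), 95, 15), 40), 1))
  bg_ffs <- bg[!cap[bg]]
  nv <- stats::rpois(length(bg_ffs), cfg$gp_visit_rate_background)
  idx <- rep(bg_ffs, nv)
  add_claims(idx, "gp_visit", .runif_date(length(idx), x - 3L, x + 1L), "gp")

  # hospitalizations (carried for completeness; no cascade rule uses them)
  hosp_idx <- which(stats::runif(N) < cfg$p_hospitalization)
  hospital <- if (length(hosp_idx)) {
    admit <- .runif_date(length(hosp_idx), sel, x + 1L)
    data.frame(event_id = sprintf("H%06d", seq_along(hosp_idx)),
               patient_fk = ssn[hosp_idx], admit_date = admit,
               discharge_date = admit + stats::rpois(length(hosp_idx), 3),
               cost_ziv = round(stats::rlnorm(length(hosp_idx),
                                              cfg$cost_meanlog + 3,
                                              cfg$cost_sdlog), 2),
               stringsAsFactors = FALSE)
  } else NULL

  ## -- laboratories and lab-side result rows -------------------------------
  lab_id_all <- sprintf("L%02d", seq_len(cfg$n_labs))
  n_part <- round(cfg$n_labs * cfg$lab_participation)
  participating <- lab_id_all %in%
    lab_id_all[sort(sample.int(cfg$n_labs, n_part))]
  lab_registry <- data.frame(lab_id = lab_id_all,
                             participating = participating,
                             stringsAsFactors = FALSE)
  if (cfg$lab_assignment == "round_robin") {
    patient_lab <- lab_id_all[(seq_len(N) - 1L) %% cfg$n_labs + 1L]
  } else {
    w <- ifelse(participating,
                cfg$participating_coverage / max(n_part, 1L),
                (1 - cfg$participating_coverage) /
                  max(cfg$n_labs - n_part, 1L))
    patient_lab <- sample(lab_id_all, N, replace = TRUE, prob = w)
  }
  lab_key <- keyedPseudonym(ssn, key = paste0("labkey-", patient_lab),
                            prefix = "LK")

  lt <- if (length(labtests)) do.call(rbind, labtests) else NULL
  if (!is.null(lt)) {
    labs <- data.frame(
      result_id = sprintf("R%07d", seq_len(nrow(lt))),
      lab_id = patient_lab[lt$patient_idx],
      lab_patient_key = lab_key[lt$patient_idx],
      loinc_code = unname(.loinc_map[lt$analyte]),
      analyte = lt$analyte, value = lt$value,
      units = unname(.analyte_units[lt$analyte]), date = lt$date,
      stringsAsFactors = FALSE)
    # the billed-claim shadow of every lab test
    bill <- cbind(data.frame(patient_fk = ssn[lt$patient_idx],
                             category = "lab_test_billed",
                             analyte = lt$analyte, date = lt$date,
                             prescriber_cat = lt$prescriber_cat,
                             stringsAsFactors = FALSE),
                  .draw_costs(nrow(lt), cfg))
    claims[[length(claims) + 1L]] <- bill
  } else labs <- NULL

  claims_df <- if (length(claims)) do.call(rbind, claims) else NULL
  pharma_df <- if (length(pharma)) do.call(rbind, pharma) else NULL
  if (!is.null(claims_df)) {
    o <- order(claims_df$patient_fk, claims_df$date, claims_df$category)
    claims_df <- claims_df[o, , drop = FALSE]
    claims_df <- cbind(event_id = sprintf("C%07d", seq_len(nrow(claims_df))),
                       claims_df, stringsAsFactors = FALSE)
  }
  if (!is.null(pharma_df)) {
    o <- order(pharma_df$patient_fk, pharma_df$date, pharma_df$atc_code)
    pharma_df <- pharma_df[o, , drop = FALSE]
    pharma_df <- cbind(event_id = sprintf("D%07d", seq_len(nrow(pharma_df))),
                       pharma_df, stringsAsFactors = FALSE)
  }
  lab_keymap <- unique(data.frame(lab_id = patient_lab,
                                  lab_patient_key = lab_key, ssn = ssn,
                                  stringsAsFactors = FALSE))

  bundle <- claimsBundle(patients = patients, practices = practices,
                         claims = claims_df, pharma = pharma_df, labs = labs,
                         hospital = hospital, lab_registry = lab_registry,
                         lab_keymap = lab_keymap)

  truth <- data.frame(
    ssn = ssn, is_t2d = is_t2d, has_prediabetes_pass = has_pass,
    is_t1d = is_t1d,
    stage1_tested = ifelse(is_t2d, s1, NA),
    stage3_in_care = ifelse(is_t2d, s3, NA),
    stage4_in_treatment = ifelse(is_t2d, s4, NA),
    stringsAsFactors = FALSE)
  for (j in ind_names)
    truth[[paste0("stage5_", j)]] <- ifelse(is_t2d, ind[, j], NA)
  truth$stage5_all <- ifelse(is_t2d, s5, NA)
  truth$stage6_controlled <- ifelse(s4, s6, NA)

  list(bundle = bundle, truth = truth)
}

#' Generate two-rater ACIC interview item scores per practice
#'
#' Each practice is scored independently by two raters on every item of the
#' six Chronic Care Model subscales (items 0-11), with a consensus score per
#' item (the agreed value where the raters agree, the rounded mean otherwise).
#' Practices of type `multi_capitation` are drawn with a configurable mean
#' shift so stratified comparisons can be exercised.
#'
#' @param config a `sim_config` (uses `config$acic` and `config$seed`).
#' @param practices the practices table of a bundle.
#' @return data frame `practice_id`, `rater_id` (`A`, `B`, `consensus`),
#'   `subscale`, `item_index`, `score`.
#' @export
generateAcicSurveys <- function(config, practices) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ac <- config$acic
  items <- ac$items
  if (nrow(practices) == 0L)
    return(data.frame(practice_id = character(0), rater_id = character(0),
                      subscale = character(0), item_index = integer(0),
                      score = integer(0), stringsAsFactors = FALSE))
  n_items <- sum(items)
  sub <- rep(names(items), items)
  item_index <- unlist(lapply(items, seq_len), use.names = FALSE)
  out <- vector("list", nrow(practices))
  for (i in seq_len(nrow(practices))) {
    latent <- ac$base_mean +
      ac$capitation_shift * (practices$ptype[i] == "multi_capitation") +
      stats::rnorm(1, 0, ac$between_sd)
    score_a <- pmin(pmax(round(latent + stats::rnorm(1, 0, ac$rater_sd) +
                                 stats::rnorm(n_items, 0, ac$item_sd)), 0), 11)
    score_b <- pmin(pmax(round(latent + stats::rnorm(1, 0, ac$rater_sd) +
                                 stats::rnorm(n_items, 0, ac$item_sd)), 0), 11)
    cons <- ifelse(score_a == score_b, score_a,
                   round((score_a + score_b) / 2))
    out[[i]] <- data.frame(
      practice_id = practices$practice_id[i],
      rater_id = rep(c("A", "B", "consensus"), each = n_items),
      subscale = rep(sub, 3L), item_index = rep(item_index, 3L),
      score = as.integer(c(score_a, score_b, cons)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
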