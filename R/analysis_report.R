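#' Percentage of a count over a denominator
#'
#' The reporting layer's percentage routine, rounded to the printed
#' precision.
#'
#' @param numerator,denominator counts.
#' @param digits decimals (default 1).
#' @return percentage on the 0-100 scale.
#' @examples
#' pct(5643, 7645)  # 73.8
#' @export
pct <- function(numerator, denominator, digits = 1) {
  round(100 * numerator / denominator, digits)
}

#' Build the patient-level analysis frame
#'
#' Joins the per-patient cascade stage table with the practice-level ACIC
#' scores into the one-row-per-cohort-patient frame used by the drop
#' regressions and the multilevel models. Drop indicators are defined
#' conditionally: `drop_in_care` on the full cohort, `drop_in_treatment`
#' among patients in care, `drop_followed_up` among patients in treatment,
#' and `drop_under_control` among followed-up patients with a known control
#' status (`NA` elsewhere).
#'
#' @param cascade a `cascade_result`.
#' @param acic_scores per-practice score table from `acicScoreTable()`
#'   (consensus rater).
#' @return an `analysis_frame` data frame, canonically sorted by patient id,
#'   with `acic_missing` flagging patients whose practice has no ACIC scores
#'   (excluded from multilevel fits); per-column missingness is attached as
#'   `attr(, "missingness")`.
#' @export
buildFrame <- function(cascade, acic_scores) {
  stopifnot(inherits(cascade, "cascade_result"))
  st <- cascade$patient
  fr <- data.frame(
    pid = st$pid,
    stage1_tested = st$stage1_tested,
    stage3_in_care = st$stage3_in_care,
    stage4_in_treatment = st$stage4_in_treatment,
    stage5_all = st$stage5_all,
    stage6_controlled = st$stage6_controlled,
    drop_in_care = !st$stage3_in_care,
    drop_in_treatment = ifelse(st$stage3_in_care, !st$stage4_in_treatment,
                               NA),
    drop_followed_up = ifelse(st$stage4_in_treatment, !st$stage5_all, NA),
    drop_under_control = ifelse(st$stage5_all & !is.na(st$stage6_controlled),
                                !st$stage6_controlled, NA),
    vulnerable = st$vulnerable, sex = st$sex, age = st$age,
    scheme = st$scheme, practice_id = st$practice_id, ptype = st$ptype,
    stringsAsFactors = FALSE)
  sc <- acic_scores
  m <- match(fr$practice_id, sc$practice_id)
  for (cl in c(.acic_subscales, "acic_overall"))
    if (cl %in% names(sc)) fr[[cl]] <- sc[[cl]][m]
  fr$acic_missing <- is.na(m)
  fr <- fr[order(fr$pid), , drop = FALSE]
  rownames(fr) <- NULL
  attr(fr, "missingness") <- vapply(fr, function(v) sum(is.na(v)),
                                    integer(1))
  class(fr) <- c("analysis_frame", "data.frame")
  fr
}

.glm_fit_row <- function(fit, model_id, outcome, n) {
  sm <- summary(fit)$coefficients
  sep <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(sm[, "Std. Error"] > 100, na.rm = TRUE)
  data.frame(model_id = model_id, outcome = outcome,
             term = rownames(sm), estimate = sm[, "Estimate"],
             std_error = sm[, "Std. Error"],
             odds_ratio = exp(sm[, "Estimate"]),
             p_value = sm[, "Pr(>|z|)"], n = n,
             converged = fit$converged && !sep,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bivariate and multivariable logistic regressions on a cascade drop
#'
#' Fits one bivariate logistic model per covariate and one multivariable
#' model with all covariates, with the dichotomous drop (or stage) indicator
#' as outcome. Degenerate outcomes (a single observed level) and apparent
#' separation are flagged rather than estimated. p-values are reported
#' without multiplicity correction (noted in the metadata).
#'
#' @param frame an `analysis_frame`.
#' @param outcome name of a logical outcome column (e.g.
#'   `"drop_in_treatment"`).
#' @param covariates covariate column names; defaults to sex, age,
#'   vulnerability and scheme at the patient level plus practice type and
#'   overall ACIC at the practice level (when present).
#' @return a `model_result` list: `coefficients` (one row per model term,
#'   with odds ratios and standard errors), `outcome`, `n`, `meta`.
#' @export
dropRegressions <- function(frame, outcome,
                            covariates = intersect(
                              c("sex", "age", "vulnerable", "scheme",
                                "ptype", "acic_overall"), names(frame))) {
  stopifnot(outcome %in% names(frame))
  dat <- frame[!is.na(frame[[outcome]]), , drop = FALSE]
  y <- dat[[outcome]]
  res <- list()
  degenerate <- length(unique(y)) < 2L
  if (!degenerate) {
    for (cv in covariates) {
      sub <- dat[!is.na(dat[[cv]]), c(outcome, cv)]
      if (length(unique(sub[[cv]])) < 2L) next
      fit <- stats::glm(stats::reformulate(cv, outcome), data = sub,
                        family = stats::binomial())
      res[[length(res) + 1L]] <-
        .glm_fit_row(fit, paste0("bivariate_", cv), outcome, nrow(sub))
    }
    keep <- covariates[vapply(covariates, function(cv)
      length(unique(dat[[cv]][!is.na(dat[[cv]])])) > 1L, logical(1))]
    sub <- dat[stats::complete.cases(dat[, c(outcome, keep)]),
               c(outcome, keep)]
    fit <- stats::glm(stats::reformulate(keep, outcome), data = sub,
                      family = stats::binomial())
    res[[length(res) + 1L]] <-
      .glm_fit_row(fit, "multivariable", outcome, nrow(sub))
  }
  structure(list(
    coefficients = if (length(res)) do.call(rbind, res) else NULL,
    outcome = outcome, n = nrow(dat),
    degenerate_outcome = degenerate,
    converged = !degenerate &&
      all(vapply(res, function(r) all(r$converged), logical(1))),
    meta = list(multiple_testing_correction = "none",
                note = "p-values are unadjusted")),
    class = "model_result")
}

#' Random-intercept multilevel logistic model
#'
#' Patients (level 1) clustered within GP practices (level 2): a logistic
#' model with a practice random intercept, patient-level fixed effects and
#' practice-level fixed effects (including the overall ACIC score), fitted
#' with `lme4::glmer`. Rows flagged `acic_missing` are excluded whenever a
#' practice covariate is requested.
#'
#' @param frame an `analysis_frame`.
#' @param outcome logical outcome column name (stage or drop indicator).
#' @param patient_covariates,practice_covariates fixed-effect column names.
#' @return a `model_result` list: `coefficients` (fixed effects with odds
#'   ratios), `ranef_variance` (practice intercept variance),
#'   `n_patients`, `n_practices`, `converged`.
#' @export
multilevelFit <- function(frame, outcome,
                          patient_covariates = c("sex", "age", "vulnerable",
                                                 "scheme"),
                          practice_covariates = "acic_overall") {
  stopifnot(outcome %in% names(frame))
  covs <- c(patient_covariates, practice_covariates)
  covs <- covs[vapply(covs, function(cv)
    cv %in% names(frame) && length(unique(stats::na.omit(frame[[cv]]))) > 1L,
    logical(1))]
  dat <- frame
  if (length(practice_covariates) && "acic_missing" %in% names(dat))
    dat <- dat[!dat$acic_missing, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat[, c(outcome, covs, "practice_id")]),
             , drop = FALSE]
  if (length(unique(dat$practice_id)) < 2L)
    stop("multilevel model needs >= 2 practices with outcome data; ",
         "use dropRegressions() for a single practice", call. = FALSE)
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(covs, "(1 | practice_id)"),
                                     collapse = " + ")))
  fit <- suppressWarnings(
    lme4::glmer(f, data = dat, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE)))
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  structure(list(
    coefficients = data.frame(
      term = rownames(sm), estimate = sm[, "Estimate"],
      std_error = sm[, "Std. Error"], odds_ratio = exp(sm[, "Estimate"]),
      p_value = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE,
      row.names = NULL),
    outcome = outcome,
    ranef_variance = vc$vcov[vc$grp == "practice_id"][1],
    n_patients = nrow(dat),
    n_practices = length(unique(dat$practice_id)),
    converged = conv,
    meta = list(multiple_testing_correction = "none")),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result: outcome %s", x$outcome))
  if (!is.null(x$n_patients))
    cat(sprintf(" (%d patients, %d practices, intercept var %.4f)",
                x$n_patients, x$n_practices, x$ranef_variance))
  cat("\n")
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 3)
  invisible(x)
}

.spider_data <- function(acic_scores, practices, strata = "ptype") {
  sc <- acic_scores
  sc$ptype <- practices$ptype[match(sc$practice_id, practices$practice_id)]
  rows <- list()
  mk <- function(sub, level) {
    vals <- colMeans(sub[, .acic_subscales, drop = FALSE])
    data.frame(stratum = level, subscale = .acic_subscales,
               score = as.vector(vals), stringsAsFactors = FALSE)
  }
  rows[["overall"]] <- mk(sc, "overall")
  if ("ptype" %in% strata)
    for (lv in sort(unique(sc$ptype)))
      rows[[lv]] <- mk(sc[sc$ptype == lv, , drop = FALSE], lv)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render the stratified quality report
#'
#' Produces the two signature figures of the framework — one spiderweb
#' (radar) of the six ACIC subscale scores per stratum on the 0-11 scale, and
#' one cascade-of-care bar chart per stratum — together with machine-readable
#' twins of every figure (the exact data frames the figures draw). Empty
#' strata are skipped with a notice. The output is a pure function of its
#' inputs.
#'
#' @param cascade a `cascade_result`.
#' @param acic_scores per-practice consensus score table
#'   (`acicScoreTable()`).
#' @param practices practices table (for the practice-type stratification of
#'   the spiderweb).
#' @param out_dir optional directory; when given, figures are written as PNG
#'   and the data twins as CSV/JSON.
#' @return list with `figures` (ggplot objects `spiderweb`, `cascade_bars`)
#'   and `data` (`spider`, `bars`, `drops`).
#' @export
renderReport <- function(cascade, acic_scores, practices, out_dir = NULL) {
  stopifnot(inherits(cascade, "cascade_result"))
  spider <- .spider_data(acic_scores, practices)
  bars <- cascade$bars
  main_stages <- c("tested", "in_care", "in_treatment", "followed_up",
                   "under_control")
  bdat <- bars[bars$stage %in% main_stages, , drop = FALSE]
  bdat$stage <- factor(bdat$stage, levels = main_stages)
  bdat$panel <- ifelse(bdat$stratum_var == "overall", "overall",
                       paste0(bdat$stratum_var, ": ", bdat$stratum))

  close_loop <- function(df) {
    df$subscale <- factor(df$subscale, levels = .acic_subscales)
    df
  }
  gg_spider <- ggplot2::ggplot(close_loop(spider),
                               ggplot2::aes(x = subscale,
                                            y = score,
                                            group = stratum,
                                            colour = stratum)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.7) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::coord_polar() +
    ggplot2::scale_y_continuous(limits = c(0, 11), breaks = c(0, 3, 6, 9, 11)) +
    ggplot2::labs(title = "ACIC subscale scores", y = "score (0-11)",
                  x = NULL) +
    ggplot2::theme_minimal()

  gg_bars <- ggplot2::ggplot(bdat,
                             ggplot2::aes(x = stage, y = pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", pct)), vjust = -0.3, size = 2.8) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_continuous(limits = c(0, 105)) +
    ggplot2::labs(title = "Cascade of care", y = "% of diagnosed cohort",
                  x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35,
                                                       hjust = 1))
  out <- list(figures = list(spiderweb = gg_spider, cascade_bars = gg_bars),
              data = list(spider = spider, bars = bars,
                          drops = cascade$drops))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(spider, file.path(out_dir, "acic_spider.csv"),
                     row.names = FALSE)
    utils::write.csv(bars, file.path(out_dir, "cascade_bars.csv"),
                     row.names = FALSE)
    utils::write.csv(cascade$drops, file.path(out_dir, "cascade_drops.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(spider = spider, bars = bars,
                              drops = cascade$drops),
                         file.path(out_dir, "report_data.json"),
                         auto_unbox = TRUE, digits = NA)
    ggplot2::ggsave(file.path(out_dir, "acic_spiderweb.png"), gg_spider,
                    width = 7, height = 6, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "cascade_bars.png"), gg_bars,
                    width = 9, height = 6, dpi = 120)
  }
  out
}
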