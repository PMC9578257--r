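.acic_subscales <- c("organization", "community_linkages",
                     "self_management_support", "decision_support",
                     "delivery_system_design", "clinical_information_systems")

#' An ACIC assessment
#'
#' One rater's Assessment of Chronic Illness Care item scores for one
#' practice: integer item scores in 0-11 for each of the six Chronic Care
#' Model subscales, each subscale carrying at least three items (the
#' clinical-information-systems subscale carries five by default).
#'
#' @param subscales named list mapping each of the six subscales to an
#'   integer vector of item scores.
#' @param practice_id,rater_id identifiers (rater `"A"`, `"B"` or
#'   `"consensus"`).
#' @return an `acic_assessment` object.
#' @export
acicAssessment <- function(subscales, practice_id = NA_character_,
                           rater_id = NA_character_) {
  missing_sub <- setdiff(.acic_subscales, names(subscales))
  if (length(missing_sub))
    stop("missing subscale(s): ", paste(missing_sub, collapse = ", "),
         call. = FALSE)
  subscales <- subscales[.acic_subscales]
  for (nm in .acic_subscales) {
    it <- subscales[[nm]]
    if (length(it) < 3L)
      stop("subscale '", nm, "' must have >= 3 items", call. = FALSE)
    if (any(is.na(it)) || any(it < 0 | it > 11))
      stop("item scores of '", nm, "' must lie in [0, 11]", call. = FALSE)
  }
  structure(list(practice_id = practice_id, rater_id = rater_id,
                 subscales = subscales), class = "acic_assessment")
}

#' Subscale scores of an ACIC assessment
#'
#' Each subscale score is the arithmetic mean of its item scores (range
#' 0-11).
#'
#' @param assessment an `acic_assessment`.
#' @return named numeric vector, one mean per subscale.
#' @export
acicSubscaleScores <- function(assessment) {
  stopifnot(inherits(assessment, "acic_assessment"))
  vapply(assessment$subscales, mean, numeric(1))
}

#' Overall ACIC score
#'
#' The unweighted mean of the six subscale means; higher values indicate
#' better organizational support for chronic illness care (11 is optimal).
#'
#' @param assessment an `acic_assessment`.
#' @return a number in 0-11.
#' @export
acicOverallScore <- function(assessment) {
  mean(acicSubscaleScores(assessment))
}

#' Two-rater consensus of ACIC assessments
#'
#' Where the raters agree the agreed score is kept; where they disagree the
#' score is taken from `resolution`, an explicit per-item resolution table
#' (keeping the consensus step deterministic); disagreements without a
#' resolution entry are flagged unresolved (score `NA`).
#'
#' @param rater_a,rater_b `acic_assessment`s covering identical items.
#' @param resolution optional data frame `subscale`, `item_index`, `score`.
#' @return list with `assessment` (consensus `acic_assessment`; built only
#'   when every item resolved) , `scores` (data frame `subscale`,
#'   `item_index`, `score`, `unresolved`).
#' @export
acicConsensus <- function(rater_a, rater_b, resolution = NULL) {
  stopifnot(inherits(rater_a, "acic_assessment"),
            inherits(rater_b, "acic_assessment"))
  if (!identical(lapply(rater_a$subscales, length),
                 lapply(rater_b$subscales, length)))
    stop("raters cover different item sets", call. = FALSE)
  rows <- list()
  for (nm in .acic_subscales) {
    a <- rater_a$subscales[[nm]]; b <- rater_b$subscales[[nm]]
    sc <- ifelse(a == b, a, NA_real_)
    unres <- a != b
    if (any(unres) && !is.null(resolution)) {
      for (i in which(unres)) {
        hit <- resolution$subscale == nm & resolution$item_index == i
        if (any(hit)) {
          sc[i] <- resolution$score[hit][1]
          unres[i] <- FALSE
        }
      }
    }
    rows[[nm]] <- data.frame(subscale = nm, item_index = seq_along(a),
                             score = sc, unresolved = unres,
                             stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  assessment <- if (!any(scores$unresolved))
    acicAssessment(split(scores$score, scores$subscale)[.acic_subscales],
                   practice_id = rater_a$practice_id, rater_id = "consensus")
  else NULL
  list(assessment = assessment, scores = scores)
}

#' Score an ACIC item table per practice
#'
#' Takes the long item-score table produced by `generateAcicSurveys()` (or a
#' conforming real-use file: `practice_id`, `rater_id`, `subscale`,
#' `item_index`, `score`) and computes subscale means and the overall score
#' per practice and rater.
#'
#' @param items long item-score data frame.
#' @param rater which rater's scores to use (default `"consensus"`; `NULL`
#'   scores every rater present).
#' @return data frame, one row per practice (and rater): six subscale score
#'   columns plus `acic_overall`.
#' @export
acicScoreTable <- function(items, rater = "consensus") {
  if (!is.null(rater)) items <- items[items$rater_id %in% rater, ]
  if (nrow(items) == 0L)
    return(data.frame(practice_id = character(0), rater_id = character(0)))
  key <- interaction(items$practice_id, items$rater_id, drop = TRUE)
  out <- lapply(split(items, key), function(g) {
    subs <- split(g$score, g$subscale)[.acic_subscales]
    a <- acicAssessment(subs, practice_id = g$practice_id[1],
                        rater_id = g$rater_id[1])
    ss <- acicSubscaleScores(a)
    cbind(data.frame(practice_id = g$practice_id[1],
                     rater_id = g$rater_id[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(ss)),
          data.frame(acic_overall = mean(ss)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$practice_id, out$rater_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
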