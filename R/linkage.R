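# -- keyed pseudonymization ---------------------------------------------------
# Two independent 32-bit FNV-1a passes over "key:value" bytes, concatenated to
# a 16-hex-digit token. All arithmetic is kept below 2^53 so the doubles are
# exact. Injectivity is the contract: residual collisions are disambiguated
# deterministically with an occurrence-order suffix.

.fnv1a <- function(x, offset, prime) {
  h <- rep(offset, length(x))
  width <- max(nchar(x), 1L)
  for (i in seq_len(width)) {
    ch <- substring(x, i, i)
    live <- ch != ""
    if (!any(live)) break
    byte <- ifelse(live, utf8ToInt(paste(ifelse(live, ch, "a"),
                                         collapse = ""))[seq_along(x)], 0)
    # xor only touches the low 8 bits
    lo8 <- h %% 256
    h <- ifelse(live, h - lo8 + bitwXor(as.integer(lo8), as.integer(byte)), h)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ifelse(live, (lo * prime + ((hi * prime) %% 65536) * 65536) %%
                  4294967296, h)
  }
  h
}

.hex32 <- function(h)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))

#' Keyed pseudonymization of identifiers
#'
#' Deterministic keyed-hash pseudonyms emulating the identifier encryption a
#' trusted third party applies: the same (identifier, key) pair always yields
#' the same token, tokens do not reveal the identifier, and the mapping is
#' injective within a call (hash collisions are resolved with a deterministic
#' suffix). Not a cryptographic primitive; injectivity and determinism are the
#' contract.
#'
#' @param x character vector of identifiers.
#' @param key secret key string (recycled; may vary per element, e.g. one key
#'   per laboratory).
#' @param prefix prefix of the returned tokens.
#' @return character vector of pseudonyms, same length as `x`.
#' @export
keyedPseudonym <- function(x, key, prefix = "PS") {
  stopifnot(length(x) == 0L || all(nzchar(x)))
  if (!length(x)) return(character(0))
  material <- paste0(rep_len(key, length(x)), ":", x)
  h1 <- .fnv1a(material, 2166136261, 16777619)
  h2 <- .fnv1a(material, 31786111, 16777379)
  tok <- paste0(prefix, .hex32(h1), .hex32(h2))
  # deterministic disambiguation of residual collisions among distinct inputs
  dup <- duplicated(tok) & !duplicated(paste0(material, "\r", tok))
  if (any(dup)) {
    seqno <- stats::ave(seq_along(tok), tok, FUN = seq_along)
    tok[dup] <- paste0(tok[dup], "-", seqno[dup])
  }
  # identical inputs must map to identical tokens
  tok[match(material, material)]
}

.collect_audit <- function() {
  steps <- list()
  list(add = function(step, actor, detail, n) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, actor = actor, detail = detail, n = n,
      stringsAsFactors = FALSE)
  },
  table = function() do.call(rbind, steps))
}

#' Emulate the pseudonymized two-TTP record linkage
#'
#' Deterministically links the claims-side bundle with the lab-side results
#' for a cohort, emulating the organizational flow in three computational
#' stages: (1) a first trusted third party replaces the national identifier by
#' a keyed pseudonym on both the claims side and the lab side; (2) a second
#' trusted third party replaces each pseudonym by a single-use random
#' transport number; (3) the researcher side assigns the final `patient_id`
#' per transport number and joins. No retained table pairs the national
#' identifier with the final pseudonym, and the returned dataset contains no
#' national identifiers at all.
#'
#' Patients whose laboratory does not participate keep their full claims-side
#' record (including billed lab-test claims, so which tests were done remains
#' known) and get `linkage_status = "unlinked_lab_nonparticipating"`. Lab
#' results whose lab-side key maps to no cohort member are dropped and
#' counted.
#'
#' @param bundle a validated, pre-linkage `claims_bundle` (keyed by `ssn`).
#' @param cohort_ids character vector of cohort `ssn`s (subset of patients).
#' @param participating_labs character vector of participating `lab_id`s;
#'   default: the labs flagged participating in the bundle's lab registry.
#' @param seed integer seed for the transport-number stage.
#' @param ttp_key secret key of the first trusted third party.
#' @return a `linked_dataset`: list of re-keyed tables (`patients`, `claims`,
#'   `pharma`, `labs`, `hospital`), a per-patient `status` table
#'   (`patient_id`, `linkage_status`), the emulation `audit` log, and
#'   `n_dropped_lab_results`.
#' @export
linkClaims <- function(bundle, cohort_ids,
                       participating_labs = NULL, seed = 1L,
                       ttp_key = "ttp-a-secret") {
  stopifnot(inherits(bundle, "claims_bundle"))
  pat <- bundle$patients
  if (anyDuplicated(pat$ssn))
    stop("integrity error: duplicate ssn in patients table", call. = FALSE)
  if (!all(cohort_ids %in% pat$ssn))
    stop("cohort_ids must be a subset of the patients table", call. = FALSE)
  if (is.null(participating_labs))
    participating_labs <-
      bundle$lab_registry$lab_id[bundle$lab_registry$participating]
  if (!all(participating_labs %in% bundle$lab_registry$lab_id))
    stop("participating_labs must be a subset of the lab registry",
         call. = FALSE)
  audit <- .collect_audit()
  set.seed(seed)

  cohort_ids <- sort(unique(cohort_ids))
  n <- length(cohort_ids)

  # stage 1 - TTP-A: keyed encryption of the national identifier (both sides)
  ps1 <- keyedPseudonym(cohort_ids, key = ttp_key, prefix = "EA")
  audit$add("encrypt_claims_side", "TTP-A",
            "ssn -> keyed pseudonym for the claims-side cohort", n)
  km <- bundle$lab_keymap
  km_cohort <- km[km$ssn %in% cohort_ids, , drop = FALSE]
  km_ps1 <- keyedPseudonym(km_cohort$ssn, key = ttp_key, prefix = "EA")
  audit$add("encrypt_lab_side", "TTP-A",
            "lab patient keys resolved and encrypted with the same key",
            nrow(km_cohort))

  # stage 2 - TTP-B: single-use random transport numbers
  rn <- paste0("RN", .hex32(sample.int(65536, n, replace = TRUE) - 1L),
               .hex32(sample.int(65536, n, replace = TRUE) - 1L),
               sprintf("%06d", sample.int(n)))
  audit$add("transport_numbers", "TTP-B",
            "pseudonym -> single-use random transport number", n)

  # stage 3 - researcher side: final pseudonyms in transport-number order
  ord <- order(rn)
  patient_id <- character(n)
  patient_id[ord] <- sprintf("PT%06d", seq_len(n))
  audit$add("final_pseudonyms", "researcher",
            "transport number -> patient_id; join performed", n)

  id_of_ssn <- stats::setNames(patient_id, cohort_ids)       # via ps1 chain
  stopifnot(!anyDuplicated(ps1))                             # injectivity

  rekey_events <- function(df) {
    df <- df[df$patient_fk %in% cohort_ids, , drop = FALSE]
    df$patient_fk <- unname(id_of_ssn[df$patient_fk])
    df[order(df$patient_fk, df$event_id), , drop = FALSE]
  }
  pat_c <- pat[match(cohort_ids, pat$ssn), , drop = FALSE]
  pat_c$patient_id <- unname(id_of_ssn[pat_c$ssn])
  pat_c$ssn <- NULL
  pat_c <- pat_c[order(pat_c$patient_id),
                 c("patient_id", "birth_year", "sex", "vulnerable", "scheme",
                   "practice_id", "region")]
  rownames(pat_c) <- NULL

  lb <- bundle$labs
  key_id <- paste(km_cohort$lab_id, km_cohort$lab_patient_key)
  lab_pid <- unname(id_of_ssn[km_cohort$ssn])
  m <- match(paste(lb$lab_id, lb$lab_patient_key), key_id)
  in_cohort <- !is.na(m)
  in_part <- lb$lab_id %in% participating_labs
  dropped <- sum(in_part & !in_cohort)
  keep <- in_part & in_cohort
  labs_c <- lb[keep, , drop = FALSE]
  labs_c$patient_id <- lab_pid[m[keep]]
  labs_c$lab_patient_key <- NULL
  labs_c <- labs_c[order(labs_c$patient_id, labs_c$result_id),
                   c("result_id", "patient_id", "lab_id", "loinc_code",
                     "analyte", "value", "units", "date")]
  rownames(labs_c) <- NULL
  audit$add("drop_unmatched_lab_results", "researcher",
            "participating-lab results keyed to no cohort member dropped",
            dropped)

  # per-patient linkage status: the assigned lab(s) must participate
  pat_labs <- split(km_cohort$lab_id, unname(id_of_ssn[km_cohort$ssn]))
  has_part <- vapply(pat_labs, function(l) any(l %in% participating_labs),
                     logical(1))
  status <- data.frame(
    patient_id = pat_c$patient_id,
    linkage_status = ifelse(
      pat_c$patient_id %in% names(has_part)[has_part],
      "linked", "unlinked_lab_nonparticipating"),
    stringsAsFactors = FALSE)
  audit$add("linkage_status", "researcher", "linked fraction computed",
            sum(status$linkage_status == "linked"))

  structure(list(patients = pat_c,
                 practices = bundle$practices,
                 claims = rekey_events(bundle$claims),
                 pharma = rekey_events(bundle$pharma),
                 hospital = rekey_events(bundle$hospital),
                 labs = labs_c,
                 status = status,
                 audit = audit$table(),
                 n_dropped_lab_results = dropped),
            class = "linked_dataset")
}

#' @export
print.linked_dataset <- function(x, ...) {
  n <- nrow(x$status)
  nl <- sum(x$status$linkage_status == "linked")
  cat(sprintf("linked_dataset: %d cohort patients, %d linked (%.1f%%)\n",
              n, nl, if (n) 100 * nl / n else NA_real_))
  cat(sprintf("  lab results: %d (dropped unmatched: %d)\n",
              nrow(x$labs), x$n_dropped_lab_results))
  invisible(x)
}

#' Fraction of cohort patients linked to lab data
#'
#' @param linked a `linked_dataset`.
#' @return proportion in `[0, 1]`.
#' @export
linkedFraction <- function(linked) {
  stopifnot(inherits(linked, "linked_dataset"))
  mean(linked$status$linkage_status == "linked")
}

#' Audit researcher-facing output for identifier leaks
#'
#' Content-based scan (invariant to row and column order) of every
#' researcher-facing table of a linked dataset — or of every text file in an
#' output directory — for occurrences of any national identifier (`ssn`) of
#' the source bundle.
#'
#' @param linked a `linked_dataset`, or a directory path of written outputs.
#' @param bundle the pre-linkage `claims_bundle` whose `ssn`s define the
#'   sensitive set.
#' @return list with `pass` (logical) and `violations` (data frame
#'   `location`, `column`, `row`, `ssn`; zero rows on pass).
#' @export
privacyAudit <- function(linked, bundle) {
  ssns <- unique(bundle$patients$ssn)
  viol <- list()
  scan_df <- function(df, where) {
    for (cl in names(df)) {
      v <- as.character(df[[cl]])
      hit <- which(!is.na(v) & v %in% ssns)
      # also substring occurrences (an ssn embedded in a longer field)
      if (!length(hit)) {
        cand <- grepl("[0-9]{11}", v)
        if (any(cand)) {
          sub <- regmatches(v[cand], gregexpr("[0-9]{11}", v[cand]))
          emb <- vapply(sub, function(s) any(s %in% ssns), logical(1))
          hit <- which(cand)[emb]
        }
      }
      for (r in hit)
        viol[[length(viol) + 1L]] <<- data.frame(
          location = where, column = cl, row = r,
          ssn = "<redacted>", stringsAsFactors = FALSE)
    }
  }
  if (is.character(linked) && length(linked) == 1L && dir.exists(linked)) {
    for (f in list.files(linked, recursive = TRUE, full.names = TRUE)) {
      lines <- readLines(f, warn = FALSE)
      hit <- which(vapply(lines, function(l)
        any(vapply(ssns, function(s) grepl(s, l, fixed = TRUE), logical(1))),
        logical(1), USE.NAMES = FALSE))
      for (r in hit)
        viol[[length(viol) + 1L]] <- data.frame(
          location = f, column = NA_character_, row = r,
          ssn = "<redacted>", stringsAsFactors = FALSE)
    }
  } else {
    stopifnot(inherits(linked, "linked_dataset"))
    for (nm in c("patients", "claims", "pharma", "hospital", "labs",
                 "status", "audit"))
      scan_df(linked[[nm]], nm)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(location = character(0), column = character(0),
               row = integer(0), ssn = character(0))
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Write a linked dataset to CSV files plus an audit log
#'
#' @param linked a `linked_dataset`.
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
writeLinked <- function(linked, out_dir) {
  stopifnot(inherits(linked, "linked_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("patients", "practices", "claims", "pharma", "hospital",
               "labs", "status")) {
    df <- linked[[nm]]
    for (cl in names(df)) if (inherits(df[[cl]], "Date"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  aj <- file.path(out_dir, "audit.json")
  jsonlite::write_json(list(steps = linked$audit,
                            n_dropped_lab_results =
                              linked$n_dropped_lab_results),
                       aj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, aj))
}
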