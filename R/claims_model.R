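#' @import stats
#' @import utils
NULL

# Canonical column order for every entity table. Dates are ISO-8601 calendar
# dates; money columns are non-negative and rounded to cents at generation.
.cc_schemas <- list(
  patients = list(
    cols = c("ssn", "patient_id", "birth_year", "sex", "vulnerable",
             "scheme", "practice_id", "region"),
    types = c(ssn = "character", patient_id = "character",
              birth_year = "integer", sex = "character",
              vulnerable = "logical", scheme = "character",
              practice_id = "character", region = "character")
  ),
  practices = list(
    cols = c("practice_id", "ptype", "region", "n_gps", "gp_ids"),
    types = c(practice_id = "character", ptype = "character",
              region = "character", n_gps = "integer", gp_ids = "character")
  ),
  claims = list(
    cols = c("event_id", "patient_fk", "category", "analyte", "date",
             "prescriber_cat", "cost_ziv", "cost_pers", "suppl"),
    types = c(event_id = "character", patient_fk = "character",
              category = "character", analyte = "character", date = "Date",
              prescriber_cat = "character", cost_ziv = "double",
              cost_pers = "double", suppl = "double")
  ),
  pharma = list(
    cols = c("event_id", "patient_fk", "atc_code", "drug_class", "date",
             "prescriber_cat", "cost_ziv", "cost_pers", "suppl"),
    types = c(event_id = "character", patient_fk = "character",
              atc_code = "character", drug_class = "character", date = "Date",
              prescriber_cat = "character", cost_ziv = "double",
              cost_pers = "double", suppl = "double")
  ),
  labs = list(
    cols = c("result_id", "lab_id", "lab_patient_key", "loinc_code",
             "analyte", "value", "units", "date"),
    types = c(result_id = "character", lab_id = "character",
              lab_patient_key = "character", loinc_code = "character",
              analyte = "character", value = "double", units = "character",
              date = "Date")
  ),
  hospital = list(
    cols = c("event_id", "patient_fk", "admit_date", "discharge_date",
             "cost_ziv"),
    types = c(event_id = "character", patient_fk = "character",
              admit_date = "Date", discharge_date = "Date",
              cost_ziv = "double")
  ),
  lab_registry = list(
    cols = c("lab_id", "participating"),
    types = c(lab_id = "character", participating = "logical")
  ),
  lab_keymap = list(
    cols = c("lab_id", "lab_patient_key", "ssn"),
    types = c(lab_id = "character", lab_patient_key = "character",
              ssn = "character")
  )
)

.claim_categories <- c("gp_visit", "dietician_consult", "diabetes_education",
                       "foot_exam", "ophthalmologist_visit", "lab_test_billed",
                       "prediabetes_pass", "t1d_convention", "insulin_pump",
                       "other")

.analytes <- c("hba1c", "ldl_c", "total_chol", "hdl_c", "triglycerides",
               "creatinine", "albuminuria", "glucose")

.loinc_map <- c(hba1c = "59261-8", ldl_c = "13457-7", total_chol = "2093-3",
                hdl_c = "2085-9", triglycerides = "2571-8",
                creatinine = "2160-0", albuminuria = "14957-5",
                glucose = "2345-7")

.analyte_units <- c(hba1c = "mmol/mol", ldl_c = "mg/dL", total_chol = "mg/dL",
                    hdl_c = "mg/dL", triglycerides = "mg/dL",
                    creatinine = "mg/dL", albuminuria = "mg/g",
                    glucose = "mg/dL")

.t2d_drug_classes <- c("metformin", "sulfonylurea", "insulin")

#' Map ATC codes to coarse antidiabetic drug classes
#'
#' Anatomical Therapeutic Chemical (ATC) prefixes identify the drug classes
#' used as type-2-diabetes diagnosis proxies in claims data: `A10BA` maps to
#' metformin, `A10BB` to sulfonylureas and `A10A` to insulins; every other
#' code maps to `"other"`.
#'
#' @param atc_code character vector of ATC codes.
#' @return character vector of drug classes
#'   (`"metformin"`, `"sulfonylurea"`, `"insulin"`, `"other"`).
#' @examples
#' atcToDrugClass(c("A10BA02", "A10BB01", "A10AB05", "C10AA05"))
#' @export
atcToDrugClass <- function(atc_code) {
  out <- rep("other", length(atc_code))
  out[startsWith(atc_code, "A10A")] <- "insulin"
  out[startsWith(atc_code, "A10BA")] <- "metformin"
  out[startsWith(atc_code, "A10BB")] <- "sulfonylurea"
  out
}

#' Convert HbA1c between IFCC and DCCT units
#'
#' Laboratory HbA1c is stored in IFCC units (mmol/mol); the DCCT percentage
#' is provided for display only via the master-equation linear relation
#' DCCT(%) = IFCC / 10.929 + 2.15. All threshold logic in the package uses
#' mmol/mol.
#'
#' @param mmol_mol numeric vector of HbA1c values in mmol/mol.
#' @return numeric vector of HbA1c values in DCCT %.
#' @examples
#' hba1cToDCCT(53)  # ~7.0 %
#' @export
hba1cToDCCT <- function(mmol_mol) mmol_mol / 10.929 + 2.15

.coerce_table <- function(df, entity) {
  sch <- .cc_schemas[[entity]]
  missing_cols <- setdiff(sch$cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error in '%s': missing column(s) %s", entity,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[, sch$cols, drop = FALSE]
  for (cl in names(sch$types)) {
    df[[cl]] <- switch(sch$types[[cl]],
      character = as.character(df[[cl]]),
      integer = as.integer(df[[cl]]),
      double = as.numeric(df[[cl]]),
      logical = as.logical(df[[cl]]),
      Date = as.Date(df[[cl]]))
  }
  rownames(df) <- NULL
  df
}

.empty_table <- function(entity) {
  sch <- .cc_schemas[[entity]]
  df <- lapply(sch$types, function(tp) switch(tp,
    character = character(0), integer = integer(0), double = numeric(0),
    logical = logical(0), Date = as.Date(character(0))))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Assemble a claims bundle
#'
#' Bundles the entity tables of the multilevel claims data model — insured
#' persons, GP practices, care-event claims, dispensed pharmaceuticals,
#' laboratory results, hospitalizations — plus the laboratory registry and the
#' lab-side identifier custody table, into a validated `claims_bundle` object.
#' Missing event tables default to empty tables of the documented schema.
#'
#' @param patients,practices,claims,pharma,labs,hospital,lab_registry,lab_keymap
#'   data frames following the documented column schemas (see
#'   `bundleSchemas()`).
#' @param validate run `validateBundle()` on the result (default `TRUE`).
#' @return an object of class `claims_bundle`: a named list of coerced tables
#'   with the validation report in `attr(, "validation")`.
#' @seealso [validateBundle()], [readTables()], [writeTables()]
#' @export
claimsBundle <- function(patients, practices, claims = NULL, pharma = NULL,
                         labs = NULL, hospital = NULL, lab_registry = NULL,
                         lab_keymap = NULL, validate = TRUE) {
  tabs <- list(patients = patients, practices = practices, claims = claims,
               pharma = pharma, labs = labs, hospital = hospital,
               lab_registry = lab_registry, lab_keymap = lab_keymap)
  for (nm in names(tabs)) {
    tabs[[nm]] <- if (is.null(tabs[[nm]])) .empty_table(nm) else
      .coerce_table(tabs[[nm]], nm)
  }
  bundle <- structure(tabs, class = "claims_bundle")
  if (validate) {
    attr(bundle, "validation") <- validateBundle(bundle)
  }
  bundle
}

#' Column schemas of the claims data model
#'
#' @return named list, one entry per entity table, giving the documented
#'   column order and column types.
#' @export
bundleSchemas <- function() {
  lapply(.cc_schemas, function(s) list(cols = s$cols, types = s$types))
}

#' Validate a claims bundle
#'
#' Checks the invariants of the data model: unique identifiers, referential
#' integrity of every foreign key, ATC/drug-class consistency, value and unit
#' constraints on laboratory results (HbA1c in 10-200 mmol/mol), non-negative
#' costs, hospital discharge on or after admission, and the
#' capitation-registration constraint (the `capitation` insurance scheme only
#' for patients of `multi_capitation` practices).
#'
#' @param bundle a `claims_bundle`.
#' @param stop_on_error raise an error on the first violation (default) or
#'   return the full report.
#' @return invisibly, a data frame report with one row per violated rule
#'   (zero rows when valid): columns `rule`, `table`, `n_rows`, `detail`.
#' @export
validateBundle <- function(bundle, stop_on_error = TRUE) {
  stopifnot(inherits(bundle, "claims_bundle"))
  viol <- list()
  add <- function(rule, table, rows, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, table = table, n_rows = length(rows),
      detail = paste0(detail, if (length(rows))
        paste0(" [rows: ", paste(utils::head(rows, 5), collapse = ","),
               if (length(rows) > 5) ",..." else "", "]") else ""),
      stringsAsFactors = FALSE)
  }
  pat <- bundle$patients; prc <- bundle$practices

  dup <- which(duplicated(pat$ssn) & !is.na(pat$ssn) & nzchar(pat$ssn))
  if (length(dup)) add("unique_ssn", "patients", dup, "duplicated ssn")
  pid <- pat$patient_id[!is.na(pat$patient_id) & nzchar(pat$patient_id)]
  if (anyDuplicated(pid)) add("unique_patient_id", "patients",
                              which(duplicated(pid)), "duplicated patient_id")
  if (anyDuplicated(prc$practice_id))
    add("unique_practice_id", "practices",
        which(duplicated(prc$practice_id)), "duplicated practice_id")

  bad <- which(!pat$practice_id %in% prc$practice_id)
  if (length(bad)) add("fk_practice", "patients", bad,
                       "practice_id not in practices")
  bad <- which(pat$scheme == "capitation" &
               prc$ptype[match(pat$practice_id, prc$practice_id)] !=
                 "multi_capitation")
  if (length(bad)) add("scheme_capitation", "patients", bad,
                       "capitation scheme outside capitation practice")
  bad <- which(!prc$ptype %in% c("mono_ffs", "multi_ffs", "multi_capitation"))
  if (length(bad)) add("ptype_domain", "practices", bad, "unknown ptype")
  ngl <- lengths(strsplit(prc$gp_ids, ";", fixed = TRUE))
  bad <- which(prc$n_gps != ngl | prc$n_gps < 1L)
  if (length(bad)) add("n_gps", "practices", bad,
                       "n_gps must equal length(gp_ids) and be >= 1")

  pkeys <- pat$ssn
  for (tb in c("claims", "pharma", "hospital")) {
    bad <- which(!bundle[[tb]]$patient_fk %in% pkeys)
    if (length(bad)) add("fk_patient", tb, bad, "dangling patient_fk")
  }
  bad <- which(!bundle$claims$category %in% .claim_categories)
  if (length(bad)) add("category_domain", "claims", bad, "unknown category")
  lt <- bundle$claims$category == "lab_test_billed"
  bad <- which(lt & !bundle$claims$analyte %in% .analytes)
  if (length(bad)) add("analyte_domain", "claims", bad,
                       "billed lab test without known analyte")

  ph <- bundle$pharma
  bad <- which(ph$drug_class != atcToDrugClass(ph$atc_code))
  if (length(bad)) add("atc_class", "pharma", bad,
                       "drug_class inconsistent with atc_code prefix")

  lb <- bundle$labs
  bad <- which(!lb$analyte %in% .analytes)
  if (length(bad)) add("analyte_domain", "labs", bad, "unknown analyte")
  bad <- which(!is.finite(lb$value) | lb$value < 0)
  if (length(bad)) add("value_range", "labs", bad,
                       "lab value must be finite and >= 0")
  bad <- which(lb$analyte == "hba1c" & (lb$value < 10 | lb$value > 200))
  if (length(bad)) add("hba1c_range", "labs", bad,
                       "hba1c outside [10, 200] mmol/mol")
  bad <- which(lb$units != .analyte_units[lb$analyte])
  if (length(bad)) add("units", "labs", bad, "units not matched to analyte")
  bad <- which(!lb$lab_id %in% bundle$lab_registry$lab_id)
  if (length(bad) && nrow(bundle$lab_registry))
    add("fk_lab", "labs", bad, "lab_id not in lab_registry")

  hp <- bundle$hospital
  bad <- which(hp$discharge_date < hp$admit_date)
  if (length(bad)) add("hospital_dates", "hospital", bad,
                       "discharge before admission")
  for (tb in c("claims", "pharma")) {
    m <- bundle[[tb]][, c("cost_ziv", "cost_pers", "suppl")]
    bad <- which(apply(m < 0, 1, any))
    if (length(bad)) add("cost_nonneg", tb, bad, "negative cost")
  }

  report <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(0), table = character(0),
               n_rows = integer(0), detail = character(0))
  if (stop_on_error && nrow(report)) {
    stop("bundle validation failed:\n",
         paste(sprintf("  [%s/%s] %s", report$table, report$rule,
                       report$detail), collapse = "\n"), call. = FALSE)
  }
  invisible(report)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("claims_bundle\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  v <- attr(x, "validation")
  if (!is.null(v))
    cat(if (nrow(v) == 0) "  validated: OK\n" else
        sprintf("  validated: %d violation(s)\n", nrow(v)))
  invisible(x)
}

.entity_files <- c(patients = "patients.csv", practices = "practices.csv",
                   claims = "claims.csv", pharma = "pharma.csv",
                   labs = "labs.csv", hospital = "hospital.csv",
                   lab_registry = "lab_registry.csv",
                   lab_keymap = "lab_keymap.csv")

#' Write a claims bundle to CSV files
#'
#' One UTF-8 CSV per entity table, documented column order, ISO-8601 dates.
#' Writing is deterministic: re-writing a bundle read back from disk produces
#' byte-identical files.
#'
#' @param bundle a validated `claims_bundle`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, named character vector of the written file paths.
#' @export
writeTables <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, .entity_files)
  names(paths) <- names(.entity_files)
  for (nm in names(paths)) {
    df <- bundle[[nm]]
    for (cl in names(df)) if (inherits(df[[cl]], "Date"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    utils::write.csv(df, paths[[nm]], row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  }
  invisible(paths)
}

#' Read a claims bundle from CSV files
#'
#' Reads the per-entity CSV files produced by `writeTables()` (or conforming
#' real-use extracts), coerces column types, and validates referential
#' integrity and the data-model invariants.
#'
#' @param dir directory containing the entity CSVs, or a named character
#'   vector of file paths (names = entity names).
#' @param validate validate after reading (default `TRUE`).
#' @return a `claims_bundle`.
#' @export
readTables <- function(dir, validate = TRUE) {
  paths <- if (length(dir) == 1L && is.null(names(dir)))
    stats::setNames(file.path(dir, .entity_files), names(.entity_files))
  else dir
  tabs <- list()
  for (nm in names(.entity_files)) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      tabs[[nm]] <- .empty_table(nm)
      next
    }
    df <- utils::read.csv(p, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
    tabs[[nm]] <- .coerce_table(df, nm)
  }
  do.call(claimsBundle, c(tabs, list(validate = validate)))
}
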