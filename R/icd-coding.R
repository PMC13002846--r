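# Parsing and normalisation of inpatient diagnosis records: ICD-10
# aggregation to 3-character categories, chapter-level exclusions,
# patient consolidation, WHO stage proxies and comorbidity counts.

#' Normalise a raw ICD-10 code to its 3-character category
#'
#' Uppercases, strips whitespace and the dot-separated subcode, and
#' truncates to the first letter plus two digits (so `"B20.7"` and
#' `"B207"` both aggregate to `"B20"`). Subcodes with supplementary
#' trailing characters are truncated at position 3.
#'
#' @param raw_code character vector of raw ICD-10 codes.
#' @return character vector of 3-character categories.
#' @export
normalize_code <- function(raw_code) {
  stop_if(length(raw_code) == 0L, "raw_code must be non-empty")
  x <- toupper(gsub("[[:space:]]", "", as.character(raw_code)))
  x <- sub("\\..*$", "", x)
  x <- substr(x, 1L, 3L)
  bad <- !grepl("^[A-Z][0-9]{2}$", x)
  stop_if(any(bad), "malformed ICD-10 code(s): ",
          paste(unique(raw_code[bad]), collapse = ", "))
  x
}

#' Chapter-level exclusion policy
#'
#' Categories whose leading letter falls in the policy are dropped from the
#' comorbidity analysis. The default excludes mental disorders (F),
#' injuries and external causes (S, T, V-Y) and congenital diseases (Q).
#'
#' @param excluded_letters character vector of single uppercase chapter
#'   letters.
#' @return an object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(excluded_letters = c("F", "Q", "S", "T",
                                                  "V", "W", "X", "Y")) {
  stop_if(!all(grepl("^[A-Z]$", excluded_letters)),
          "excluded_letters must be single uppercase letters")
  structure(list(excluded_letters = unique(excluded_letters)),
            class = "exclusion_policy")
}

#' Apply a chapter exclusion policy to a category set
#'
#' @param categories character vector of normalised 3-character categories.
#' @param policy an [exclusion_policy()].
#' @return the retained categories (a subset of the input).
#' @export
filter_exclusions <- function(categories, policy = exclusion_policy()) {
  stop_if(!inherits(policy, "exclusion_policy"),
          "policy must be an exclusion_policy")
  categories[!substr(categories, 1L, 1L) %in% policy$excluded_letters]
}

#' Read a raw diagnosis-row CSV
#'
#' Expects a UTF-8 CSV with header and columns `patient_id`,
#' `admission_id`, `year`, `gender`, `age`, `residence`, `los_days`,
#' `icd10_code` (the format written by [write_cohort_csv()]).
#'
#' @param path CSV path.
#' @return a data frame of diagnosis rows.
#' @export
read_diagnoses <- function(path) {
  stop_if(!file.exists(path), "diagnosis file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  needed <- c("patient_id", "admission_id", "year", "gender", "age",
              "residence", "los_days", "icd10_code")
  missing <- setdiff(needed, names(df))
  stop_if(length(missing) > 0L, "diagnosis CSV missing column(s): ",
          paste(missing, collapse = ", "))
  stop_if(nrow(df) == 0L, "diagnosis CSV contains no rows")
  stop_if(any(df$los_days < 0), "los_days must be non-negative")
  df
}

#' Consolidate diagnosis rows into patient records
#'
#' Normalises every raw code, applies the exclusion policy, and collapses
#' to one record per patient carrying demographics, the admission list and
#' the set of retained aggregated categories. Patients left with no
#' retained category are dropped (they contribute nothing to comorbidity
#' analyses); the returned object records the counts at each step.
#'
#' @param diagnoses data frame from [read_diagnoses()].
#' @param policy an [exclusion_policy()].
#' @param stage_map optional named integer vector (category -> stage in
#'   2:4) used to assign the WHO clinical stage proxy; see
#'   [read_stage_map()].
#' @param index_codes categories regarded as the index disease and
#'   excluded from comorbidity counts (default none).
#' @return an object of class `patient_records`: a list with `patients`
#'   (one row per patient: demographics, `n_admissions`, `first_year`,
#'   `total_los`, `who_stage`, `n_comorbidities`), `categories` (named
#'   list patient -> retained category set), `admissions` (patient,
#'   admission, year, los), and `filter_counts`.
#' @export
consolidate_patients <- function(diagnoses, policy = exclusion_policy(),
                                 stage_map = NULL, index_codes = character()) {
  n_rows_in <- nrow(diagnoses)
  diagnoses$category <- normalize_code(diagnoses$icd10_code)
  patients_in <- length(unique(diagnoses$patient_id))
  keep <- !substr(diagnoses$category, 1L, 1L) %in% policy$excluded_letters
  dx <- diagnoses[keep, ]
  stop_if(nrow(dx) == 0L, "no diagnoses remain after exclusion filtering")

  cat_sets <- lapply(split(dx$category, dx$patient_id),
                     function(x) sort(unique(x)))
  ids <- names(cat_sets)
  adm_sets <- lapply(split(dx$category, dx$admission_id),
                     function(x) sort(unique(x)))

  adm <- unique(diagnoses[c("patient_id", "admission_id", "year", "los_days")])
  adm <- adm[adm$patient_id %in% ids, ]
  adm <- adm[order(adm$patient_id, adm$admission_id), ]
  adm_by_patient <- split(adm, adm$patient_id)[ids]

  demo <- unique(diagnoses[c("patient_id", "gender", "age", "residence")])
  demo <- demo[match(ids, demo$patient_id), ]

  who_stage <- vapply(cat_sets, assign_who_stage, integer(1),
                      stage_map = stage_map)
  n_com <- vapply(cat_sets, comorbidity_count, integer(1),
                  index_codes = index_codes)

  patients <- data.frame(
    patient_id = ids,
    gender = demo$gender,
    age = demo$age,
    residence = demo$residence,
    n_admissions = vapply(adm_by_patient, nrow, integer(1)),
    first_year = vapply(adm_by_patient, function(a) min(a$year), numeric(1)),
    total_los = vapply(adm_by_patient, function(a) sum(a$los_days), numeric(1)),
    who_stage = who_stage,
    n_comorbidities = n_com,
    stringsAsFactors = FALSE)
  rownames(patients) <- NULL

  structure(list(patients = patients, categories = cat_sets,
                 admission_categories = adm_sets,
                 admissions = adm,
                 filter_counts = c(diagnosis_rows_in = n_rows_in,
                                   patients_in = patients_in,
                                   patients_retained = length(ids))),
            class = "patient_records")
}

#' @export
print.patient_records <- function(x, ...) {
  cat("patient_records:", nrow(x$patients), "patients,",
      nrow(x$admissions), "admissions,",
      length(unique(unlist(x$categories))), "distinct categories\n")
  invisible(x)
}

#' WHO clinical stage proxy from discharge categories
#'
#' Maximum mapped stage over the patient's aggregated categories; patients
#' with no stage-defining category are stage 1. Stage 3/4 serves as the
#' advanced-HIV-disease proxy when CD4 counts are unavailable.
#'
#' @param categories a patient's category set.
#' @param stage_map named integer vector, category -> stage in `{2,3,4}`;
#'   `NULL` uses the packaged default ([read_stage_map()]).
#' @return an integer stage in `{1,2,3,4}`.
#' @export
assign_who_stage <- function(categories, stage_map = NULL) {
  if (is.null(stage_map)) stage_map <- read_stage_map()
  stop_if(!all(stage_map %in% 2:4),
          "stage_map values must lie in {2, 3, 4}")
  hit <- stage_map[intersect(categories, names(stage_map))]
  if (length(hit) == 0L) 1L else as.integer(max(hit))
}

#' Read a WHO stage map CSV
#'
#' Two columns `category,stage`. The packaged default
#' (`inst/extdata/who_stage_map.csv`) is a small editable mapping of
#' 3-character categories to WHO clinical stages derived from WHO staging
#' guidance; it is a configurable resource, not authoritative clinical
#' content.
#'
#' @param path CSV path; default the packaged map.
#' @return named integer vector, category -> stage.
#' @export
read_stage_map <- function(path = system.file("extdata", "who_stage_map.csv",
                                              package = "comorbnet")) {
  stop_if(!nzchar(path) || !file.exists(path),
          "stage map file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("category", "stage") %in% names(df)),
          "stage map needs columns category,stage")
  stats::setNames(as.integer(df$stage), df$category)
}

#' Count comorbidities in a category set
#'
#' Number of retained categories excluding the configured index-disease
#' codes; with no index codes this is simply the category-set size.
#'
#' @param categories a patient's category set.
#' @param index_codes categories to exclude from the count.
#' @return integer count.
#' @export
comorbidity_count <- function(categories, index_codes = character()) {
  length(setdiff(categories, index_codes))
}

#' Build a transaction set for itemset mining
#'
#' @param records a `patient_records` object.
#' @param level `"patient"` (default; one transaction per patient, union
#'   of categories over admissions — the unit at which comorbidity counts
#'   are reported) or `"admission"` (one transaction per admission).
#' @param min_categories keep only transactions with at least this many
#'   categories; the default 1 keeps everyone. Use 2 to restrict to the
#'   multimorbidity cohort.
#' @return an object of class `transaction_set`: list with `transactions`
#'   (named list of category sets), `universe` (sorted distinct
#'   categories) and `n`.
#' @export
build_transactions <- function(records, level = c("patient", "admission"),
                               min_categories = 1L) {
  stop_if(!inherits(records, "patient_records"),
          "records must be a patient_records object")
  stop_if(length(records$categories) == 0L, "no patient records supplied")
  level <- match.arg(level)
  tx <- if (level == "patient") records$categories
        else records$admission_categories
  tx <- tx[lengths(tx) >= min_categories]
  stop_if(length(tx) == 0L, "no transactions left at min_categories = ",
          min_categories)
  new_transaction_set(tx)
}

#' Build transactions directly from diagnosis rows
#'
#' Admission-level alternative to [build_transactions()]: one transaction
#' per admission, after normalisation and exclusion filtering.
#'
#' @param diagnoses data frame from [read_diagnoses()].
#' @param policy an [exclusion_policy()].
#' @param level `"patient"` or `"admission"`.
#' @param min_categories minimum transaction size to retain.
#' @return a `transaction_set`.
#' @export
transactions_from_diagnoses <- function(diagnoses,
                                        policy = exclusion_policy(),
                                        level = c("admission", "patient"),
                                        min_categories = 1L) {
  level <- match.arg(level)
  diagnoses$category <- normalize_code(diagnoses$icd10_code)
  keep <- !substr(diagnoses$category, 1L, 1L) %in% policy$excluded_letters
  dx <- diagnoses[keep, ]
  stop_if(nrow(dx) == 0L, "no diagnoses remain after exclusion filtering")
  key <- if (level == "admission") dx$admission_id else dx$patient_id
  tx <- lapply(split(dx$category, key), function(x) sort(unique(x)))
  tx <- tx[lengths(tx) >= min_categories]
  stop_if(length(tx) == 0L, "no transactions left at min_categories = ",
          min_categories)
  new_transaction_set(tx)
}

new_transaction_set <- function(tx) {
  structure(list(transactions = tx,
                 universe = sort(unique(unlist(tx))),
                 n = length(tx)),
            class = "transaction_set")
}

#' Construct a transaction set from plain category sets
#'
#' Convenience constructor used throughout the tests and examples.
#'
#' @param sets list of character vectors (duplicates within a set are
#'   collapsed); names become transaction ids.
#' @return a `transaction_set`.
#' @export
transaction_set <- function(sets) {
  stop_if(length(sets) == 0L, "sets must be non-empty")
  tx <- lapply(sets, function(x) sort(unique(as.character(x))))
  if (is.null(names(tx))) names(tx) <- sprintf("T%03d", seq_along(tx))
  new_transaction_set(tx)
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("transaction_set:", x$n, "transactions over",
      length(x$universe), "categories\n")
  invisible(x)
}

#' Write transactions to CSV
#'
#' Columns `transaction_id` and `categories` (semicolon-joined), for
#' interoperability with external itemset miners.
#'
#' @param tset a `transaction_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_transactions_csv <- function(tset, path) {
  df <- data.frame(
    transaction_id = names(tset$transactions),
    categories = vapply(tset$transactions, paste, character(1),
                        collapse = ";"),
    stringsAsFactors = FALSE)
  write_csv_strict(df, path)
}
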