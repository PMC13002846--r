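# Cohort generation and closed-form expectations under the noisy-OR model.

#' Generate a synthetic inpatient cohort
#'
#' Draws `n_patients` patients under the noisy-OR latent-block model of the
#' supplied [cohort_spec()]: each patient joins each block independently,
#' categories activate given the joined blocks, the admission period comes
#' from the period mixture, and demographics are drawn independently of the
#' disease process. Every diagnosis category is then scattered onto one of
#' the patient's admissions, so the patient-level union of admission
#' diagnoses recovers the full category set. Generation is fully
#' reproducible from `spec$seed` and never touches the caller's RNG stream.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with
#'   `patients` (one row per patient: `patient_id`, `gender`, `age`,
#'   `residence`, `period`, `n_admissions`), `admissions` (one row per
#'   admission: `patient_id`, `admission_id`, `year`, `los_days`),
#'   `diagnoses` (one row per patient-admission-diagnosis, the raw
#'   diagnosis-row table), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stop_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  universe <- names(spec$background_prevalence)
  m <- length(universe)
  demo <- spec$demographics

  # Disease process: noisy-OR over latent block memberships.
  # keep_prob[patient, item] = P(item absent | memberships)
  keep_prob <- matrix(rep(1 - spec$background_prevalence, each = n),
                      nrow = n, ncol = m, dimnames = list(NULL, universe))
  for (b in spec$blocks) {
    z <- stats::runif(n) < b$membership_prob
    if (any(z)) {
      idx <- match(names(b$item_probs), universe)
      keep_prob[z, idx] <- keep_prob[z, idx, drop = FALSE] *
        rep(1 - b$item_probs, each = sum(z))
    }
  }
  present <- matrix(stats::runif(n * m), nrow = n) < (1 - keep_prob)
  categories <- lapply(seq_len(n), function(i) universe[present[i, ]])

  # Demographics, independent of the disease process.
  patient_id <- sprintf("P%05d", seq_len(n))
  gender <- ifelse(stats::runif(n) < demo$male_prob, "male", "female")
  residence <- ifelse(stats::runif(n) < demo$rural_prob, "rural", "urban")
  band <- sample.int(length(demo$age_weights), n, replace = TRUE,
                     prob = demo$age_weights)
  age <- floor(demo$age_breaks[band] +
                 stats::runif(n) * (demo$age_breaks[band + 1L] -
                                      demo$age_breaks[band]))

  # Admission process: shifted geometric count, years within the drawn period.
  p_geom <- 1 / demo$mean_admissions
  n_adm <- 1L + stats::rgeom(n, p_geom)
  period_labels <- names(spec$period_weights)
  period <- period_labels[sample.int(length(period_labels), n, replace = TRUE,
                                     prob = spec$period_weights)]
  sdlog <- sqrt(log(1 + (demo$los_sd / demo$los_mean)^2))
  meanlog <- log(demo$los_mean) - sdlog^2 / 2

  adm_patient <- rep(seq_len(n), n_adm)
  adm_seq <- sequence(n_adm)
  yrs <- t(vapply(period[adm_patient], parse_period_label, integer(2)))
  year <- yrs[, 1] + floor(stats::runif(length(adm_patient)) *
                             (yrs[, 2] - yrs[, 1] + 1))
  los <- pmax(1, round(stats::rlnorm(length(adm_patient), meanlog, sdlog)))
  admissions <- data.frame(
    patient_id = patient_id[adm_patient],
    admission_id = sprintf("%s-A%02d", patient_id[adm_patient], adm_seq),
    year = as.integer(year),
    los_days = as.integer(los),
    stringsAsFactors = FALSE)

  # Scatter each patient's categories across their admissions (uniformly).
  n_cat <- lengths(categories)
  dx_patient <- rep(seq_len(n), n_cat)
  slot <- unlist(lapply(seq_len(n), function(i) {
    if (n_cat[i] == 0L) integer(0)
    else sample.int(n_adm[i], n_cat[i], replace = TRUE)
  }))
  dx_code <- unlist(categories)
  adm_row <- match(paste(dx_patient, slot), paste(adm_patient, adm_seq))
  diagnoses <- data.frame(
    patient_id = patient_id[dx_patient],
    admission_id = admissions$admission_id[adm_row],
    year = admissions$year[adm_row],
    gender = gender[dx_patient],
    age = age[dx_patient],
    residence = residence[dx_patient],
    los_days = admissions$los_days[adm_row],
    icd10_code = dx_code,
    stringsAsFactors = FALSE)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$admission_id,
                               diagnoses$icd10_code), ]
  rownames(diagnoses) <- NULL

  structure(list(
    patients = data.frame(patient_id = patient_id, gender = gender, age = age,
                          residence = residence, period = period,
                          n_admissions = n_adm, stringsAsFactors = FALSE),
    admissions = admissions,
    diagnoses = diagnoses,
    categories = stats::setNames(categories, patient_id),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$patients), "patients,",
      nrow(x$admissions), "admissions,", nrow(x$diagnoses),
      "diagnosis rows,", length(x$spec$background_prevalence),
      "categories in universe\n")
  invisible(x)
}

#' Write a cohort as a raw diagnosis-row CSV
#'
#' One row per patient-admission-diagnosis with columns `patient_id`,
#' `admission_id`, `year`, `gender`, `age`, `residence`, `los_days`,
#' `icd10_code` — the input format of [read_diagnoses()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stop_if(!inherits(cohort, "synthetic_cohort"),
          "cohort must be a synthetic_cohort")
  write_csv_strict(cohort$diagnoses, path)
}

#' Exact itemset expectation under the noisy-OR model
#'
#' Closed-form probability that a patient carries all categories in
#' `items` (singletons and pairs). Writing
#' `A_i = (1 - p_i) * prod_{b joined} (1 - q_{b,i})` for the absence
#' indicator expectation, block independence gives
#' `P(i) = 1 - E[A_i]` and `P(i & j) = 1 - E[A_i] - E[A_j] + E[A_i A_j]`,
#' with `E[A_i A_j]` factorising over blocks because items are
#' conditionally independent given the memberships.
#'
#' @param spec a [cohort_spec()].
#' @param items character vector of 1 or 2 category names.
#' @return the expected support (a probability).
#' @export
expected_support <- function(spec, items) {
  stop_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  stop_if(length(items) < 1L || length(items) > 2L,
          "items must contain 1 or 2 categories")
  universe <- names(spec$background_prevalence)
  missing <- setdiff(items, universe)
  stop_if(length(missing) > 0L,
          "items not in the category universe: ",
          paste(missing, collapse = ", "))
  e_absent <- function(i) {
    a <- 1 - spec$background_prevalence[[i]]
    for (b in spec$blocks) {
      a <- a * (1 - b$membership_prob * block_q(b, i))
    }
    a
  }
  if (length(items) == 1L) return(1 - e_absent(items))
  i <- items[1]; j <- items[2]
  e_joint_absent <- (1 - spec$background_prevalence[[i]]) *
    (1 - spec$background_prevalence[[j]])
  for (b in spec$blocks) {
    qi <- block_q(b, i)
    qj <- block_q(b, j)
    e_joint_absent <- e_joint_absent *
      (1 - b$membership_prob + b$membership_prob * (1 - qi) * (1 - qj))
  }
  1 - e_absent(i) - e_absent(j) + e_joint_absent
}

#' Enumerate the planted ground truth of a cohort specification
#'
#' Expected marginal supports for every category, expected pair supports
#' for every within-block pair, and the set of pairs with a planted
#' positive association (expected joint support exceeding the product of
#' marginals).
#'
#' @param spec a [cohort_spec()].
#' @return a list with `marginal_supports` (named numeric over the full
#'   universe), `pair_supports` (data frame `item_a`, `item_b`,
#'   `expected_support`), and `positive_pairs` (data frame `item_a`,
#'   `item_b`).
#' @export
planted_truth <- function(spec) {
  stop_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  universe <- names(spec$background_prevalence)
  marginals <- vapply(universe, function(i) expected_support(spec, i),
                      numeric(1))
  pairs <- unique(do.call(rbind, lapply(spec$blocks, function(b) {
    it <- sort(names(b$item_probs))
    if (length(it) < 2L) return(NULL)
    cmb <- utils::combn(it, 2)
    data.frame(item_a = cmb[1, ], item_b = cmb[2, ], stringsAsFactors = FALSE)
  })))
  if (is.null(pairs)) {
    pairs <- data.frame(item_a = character(), item_b = character(),
                        expected_support = numeric())
    positive <- pairs[c("item_a", "item_b")]
  } else {
    pairs$expected_support <- mapply(function(a, b)
      expected_support(spec, c(a, b)), pairs$item_a, pairs$item_b)
    indep <- marginals[pairs$item_a] * marginals[pairs$item_b]
    positive <- pairs[pairs$expected_support > indep + 1e-12,
                      c("item_a", "item_b")]
    rownames(pairs) <- rownames(positive) <- NULL
  }
  list(marginal_supports = marginals, pair_supports = pairs,
       positive_pairs = positive)
}
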