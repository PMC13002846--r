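# Synthetic cohort specification: a noisy-OR latent-block generative model.
#
# Each patient independently joins each comorbidity block b with probability
# pi_b; given the joined blocks, disease category i is present with
# probability 1 - (1 - p_i) * prod_{b joined, i in b} (1 - q_{b,i}),
# where p_i is the background prevalence. Blocks plant positive pairwise
# (and higher-order) associations among their members while leaving
# closed-form 1- and 2-item expectations available for validation.

#' Define a comorbidity block
#'
#' A latent cluster of disease categories that tend to co-occur. Patients
#' join the block with probability `membership_prob`; members then activate
#' each listed category with its conditional probability on top of the
#' background prevalence (noisy-OR).
#'
#' @param block_id character label.
#' @param membership_prob probability in `[0, 1]` that a patient joins.
#' @param item_probs named numeric vector mapping disease category to the
#'   conditional activation probability given membership.
#' @return an object of class `comorbidity_block`.
#' @export
comorbidity_block <- function(block_id, membership_prob, item_probs) {
  stop_if(!is.character(block_id) || length(block_id) != 1L,
          "block_id must be a single character label")
  stop_if(!is_probability(membership_prob) || length(membership_prob) != 1L,
          "membership_prob must be a single probability in [0, 1] (block ",
          block_id, ")")
  stop_if(length(item_probs) == 0L || is.null(names(item_probs)) ||
            any(!nzchar(names(item_probs))),
          "item_probs must be a non-empty named vector (block ", block_id, ")")
  stop_if(!is_probability(item_probs),
          "item_probs must all lie in [0, 1] (block ", block_id, ")")
  structure(list(block_id = block_id,
                 membership_prob = membership_prob,
                 item_probs = item_probs),
            class = "comorbidity_block")
}

#' Specify a synthetic inpatient cohort
#'
#' Bundles everything the generator needs: cohort size, background
#' prevalences, comorbidity blocks, the admission-period mixture and
#' demographic marginals. Periods are named like `"2019-2020"`; the label
#' carries the year range the admission years are drawn from.
#'
#' @param n_patients positive patient count.
#' @param background_prevalence named numeric vector, category -> probability.
#' @param blocks list of [comorbidity_block()] objects.
#' @param period_weights named numeric vector, period label -> mixing
#'   probability; must sum to 1. Labels must be `"YYYY-YYYY"` year ranges.
#' @param demographics list of demographic marginals; see
#'   [default_demographics()].
#' @param seed integer seed driving every random draw of the generator.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        background_prevalence,
                        blocks = list(),
                        period_weights = c("2019-2020" = 1),
                        demographics = default_demographics(),
                        seed = 1L) {
  stop_if(!is.numeric(n_patients) || length(n_patients) != 1L ||
            n_patients < 1 || n_patients != floor(n_patients),
          "n_patients must be a positive integer count")
  stop_if(is.null(names(background_prevalence)) ||
            any(!nzchar(names(background_prevalence))),
          "background_prevalence must be a named vector")
  stop_if(!is_probability(background_prevalence),
          "background_prevalence values must lie in [0, 1]")
  stop_if(!all(vapply(blocks, inherits, logical(1), "comorbidity_block")),
          "blocks must be a list of comorbidity_block objects")
  universe <- names(background_prevalence)
  for (b in blocks) {
    missing <- setdiff(names(b$item_probs), universe)
    stop_if(length(missing) > 0L,
            "block ", b$block_id, " references categories outside the ",
            "universe: ", paste(missing, collapse = ", "))
  }
  stop_if(abs(sum(period_weights) - 1) > 1e-9,
          "period_weights must sum to 1")
  stop_if(!is_probability(period_weights), "period_weights must lie in [0, 1]")
  stop_if(is.null(names(period_weights)), "period_weights must be named")
  lapply(names(period_weights), parse_period_label)  # validates the labels
  structure(list(n_patients = as.integer(n_patients),
                 background_prevalence = background_prevalence,
                 blocks = blocks,
                 period_weights = period_weights,
                 demographics = demographics,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default demographic marginals
#'
#' Marginal distributions for gender, age, residence, length of stay and
#' admission count. The disease process is independent of demographics.
#' The admission count is a shifted geometric (`1 + Geom(p)`) with mean
#' `mean_admissions`; length of stay is a rounded lognormal with the given
#' mean and standard deviation in days.
#'
#' @param male_prob probability of male gender.
#' @param rural_prob probability of rural residence.
#' @param age_breaks,age_weights age-band boundaries (years) and band
#'   probabilities; age is uniform within its band.
#' @param mean_admissions mean number of admissions per patient.
#' @param los_mean,los_sd mean and SD of length of stay in days.
#' @return a list consumed by [cohort_spec()].
#' @export
default_demographics <- function(male_prob = 0.7266,
                                 rural_prob = 0.7870,
                                 age_breaks = c(0, 20, 40, 60, 90),
                                 age_weights = c(0.0046, 0.1761, 0.5023, 0.3170),
                                 mean_admissions = 2.1,
                                 los_mean = 10.9,
                                 los_sd = 6.5) {
  stop_if(length(age_weights) != length(age_breaks) - 1L,
          "age_weights must have one entry per age band")
  list(male_prob = male_prob, rural_prob = rural_prob,
       age_breaks = age_breaks, age_weights = age_weights / sum(age_weights),
       mean_admissions = mean_admissions, los_mean = los_mean, los_sd = los_sd)
}

# "2019-2020" -> c(2019, 2020); also accepts a single year "2023".
parse_period_label <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  yrs <- suppressWarnings(as.integer(parts))
  stop_if(any(is.na(yrs)) || length(yrs) < 1L || length(yrs) > 2L,
          "period label must look like 'YYYY' or 'YYYY-YYYY': ", label)
  if (length(yrs) == 1L) yrs <- c(yrs, yrs)
  stop_if(yrs[1] > yrs[2], "period label has year_min > year_max: ", label)
  yrs
}

#' Read a cohort specification from a YAML file
#'
#' The file mirrors the [cohort_spec()] arguments:
#' `n_patients`, `seed`, `background_prevalence` (map), `period_weights`
#' (map), and `blocks` (list of `{block_id, membership_prob, item_probs}`).
#' `demographics` entries override the defaults.
#'
#' @param path path to a YAML file.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  stop_if(!file.exists(path), "spec file not found: ", path)
  y <- yaml::read_yaml(path)
  blocks <- lapply(y$blocks %||% list(), function(b) {
    comorbidity_block(b$block_id, b$membership_prob, unlist(b$item_probs))
  })
  demo <- default_demographics()
  for (k in names(y$demographics %||% list())) demo[[k]] <- y$demographics[[k]]
  cohort_spec(n_patients = y$n_patients,
              background_prevalence = unlist(y$background_prevalence),
              blocks = blocks,
              period_weights = unlist(y$period_weights),
              demographics = demo,
              seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort specification emulating the study conditions
#'
#' A calibrated default: 3,000 patients; 25 hub disease categories whose
#' marginal prevalences follow the published top-25 prevalence profile of
#' an HIV inpatient cohort (electrolyte disorders E87 at ~86%, HIV-related
#' infections B20 at ~70%, candidiasis B37 at ~66%, hypoproteinemia E46 at
#' ~63%, anemia D64, ...); three planted comorbidity blocks (opportunistic
#' infection, metabolic-nutritional, pneumonia-metabolic) generating the
#' strong pairwise associations among the hubs; and a long tail of rare
#' categories bringing the universe to ~600 categories and the per-patient
#' category-count distribution to a right-skewed shape with median near 9.
#' Background prevalences of block members are solved so the noisy-OR
#' marginals match the target profile. Admission periods are mixed
#' 2019-2020 / 2021-2022 / 2023-2024 with weights matching the published
#' yearly admission proportions.
#'
#' @param n_patients cohort size (default 3000).
#' @param n_tail_categories size of the rare-category tail (default 575).
#' @param seed generator seed.
#' @return a `cohort_spec`.
#' @export
study_cohort_spec <- function(n_patients = 3000, n_tail_categories = 575,
                              seed = 20190101L) {
  hub_targets <- c(
    E87 = 0.8557, B20 = 0.6970, B37 = 0.6591, E46 = 0.6320, D64 = 0.55,
    B99 = 0.34, J18 = 0.30, B49 = 0.25, N19 = 0.22, B59 = 0.20, A15 = 0.20,
    B48 = 0.18, K72 = 0.17, K29 = 0.16, J84 = 0.14, B34 = 0.14, K76 = 0.13,
    B25 = 0.13, K73 = 0.12, D70 = 0.12, D69 = 0.11, E79 = 0.10, J90 = 0.10,
    E78 = 0.09, N20 = 0.08)
  blocks <- list(
    comorbidity_block("infection", 0.45, c(
      B20 = 0.85, B37 = 0.75, B99 = 0.45, B49 = 0.30, B59 = 0.25,
      A15 = 0.20, B48 = 0.15, B25 = 0.15, B34 = 0.15)),
    comorbidity_block("metabolic", 0.55, c(
      E87 = 0.85, E46 = 0.75, D64 = 0.65, D70 = 0.20, D69 = 0.18,
      K72 = 0.15, N19 = 0.15)),
    comorbidity_block("pneumonia", 0.25, c(
      J18 = 0.70, E87 = 0.50, E46 = 0.40, J90 = 0.25, J84 = 0.20)),
    # general hospitalization-burden cluster: widens and right-skews the
    # per-patient count distribution (severe admissions carry bundles of
    # mid-prevalence conditions) without pushing any member past the
    # mining support threshold
    comorbidity_block("burden", 0.35, stats::setNames(
      rep(0.45, 14), c("A41", "G03", "H10", "I10", "I63", "J96", "K29",
                       "K59", "K80", "L02", "M54", "N17", "N28", "R50"))))
  burden <- stats::setNames(rep(0.01, 14), names(blocks[[4]]$item_probs))
  burden <- burden[setdiff(names(burden), names(hub_targets))]
  background <- calibrate_background(hub_targets, blocks)
  # Rare-category tail: geometric decay keeps every tail prevalence well
  # below mining thresholds while filling out the per-patient counts.
  tail_codes <- make_tail_codes(n_tail_categories,
                                exclude = c(names(hub_targets), names(burden)))
  tail_prev <- 0.006 * 0.99^(seq_len(n_tail_categories) - 1)
  names(tail_prev) <- tail_codes
  cohort_spec(
    n_patients = n_patients,
    background_prevalence = c(background, burden, tail_prev),
    blocks = blocks,
    period_weights = c("2019-2020" = 0.3662, "2021-2022" = 0.3784,
                       "2023-2024" = 0.2554),
    seed = seed)
}

#' Solve background prevalences for target marginals
#'
#' Under the noisy-OR model the marginal prevalence of category i is
#' `1 - (1 - p_i) * prod_b (1 - pi_b * q_{b,i})`. Given target marginals
#' this inverts for the background `p_i` (clamped at 0 when the blocks
#' alone exceed the target).
#'
#' @param targets named numeric vector of target marginal prevalences.
#' @param blocks list of `comorbidity_block`s.
#' @return named numeric vector of background prevalences.
#' @export
calibrate_background <- function(targets, blocks) {
  out <- vapply(names(targets), function(i) {
    shrink <- 1
    for (b in blocks) {
      shrink <- shrink * (1 - b$membership_prob * block_q(b, i))
    }
    max(0, 1 - (1 - targets[[i]]) / shrink)
  }, numeric(1))
  names(out) <- names(targets)
  out
}

# Conditional activation probability of item i in block b (0 if not a member).
block_q <- function(b, i) {
  if (i %in% names(b$item_probs)) b$item_probs[[i]] else 0
}

# Deterministic valid 3-character categories outside the excluded chapters
# (F, Q, S, T, V-Y) and not colliding with `exclude`.
make_tail_codes <- function(n, exclude = character()) {
  letters_ok <- setdiff(LETTERS, c("F", "Q", "S", "T", "V", "W", "X", "Y"))
  all_codes <- as.vector(t(outer(letters_ok, sprintf("%02d", 0:99), paste0)))
  pool <- setdiff(all_codes, exclude)
  stop_if(n > length(pool), "tail too large: only ", length(pool),
          " codes available")
  pool[seq_len(n)]
}
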