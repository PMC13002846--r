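# Period stratification and cross-period comparison of mined patterns.

#' Define admission periods
#'
#' @param labels character labels, e.g. `c("2019-2020", "2021-2022")`;
#'   each label carries its own year range (`"YYYY-YYYY"` or `"YYYY"`).
#' @return data frame of class `period_defs` with `label`, `year_min`,
#'   `year_max`; periods must not overlap.
#' @export
period_defs <- function(labels = c("2019-2020", "2021-2022", "2023-2024")) {
  yrs <- t(vapply(labels, parse_period_label, integer(2)))
  df <- data.frame(label = labels, year_min = yrs[, 1], year_max = yrs[, 2],
                   stringsAsFactors = FALSE)
  df <- df[order(df$year_min), ]
  if (nrow(df) > 1L) {
    stop_if(any(df$year_min[-1] <= df$year_max[-nrow(df)]),
            "periods overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("period_defs", "data.frame")
  df
}

year_to_period <- function(years, periods) {
  idx <- vapply(years, function(y) {
    hit <- which(periods$year_min <= y & y <= periods$year_max)
    stop_if(length(hit) == 0L, "admission year ", y,
            " is outside every defined period")
    hit[1]
  }, integer(1))
  periods$label[idx]
}

#' Assign patients to admission periods
#'
#' @param records a `patient_records` object.
#' @param periods a [period_defs()] frame covering every admission year.
#' @param policy `"first_admission"` (default): one label per patient from
#'   the earliest admission year, so each patient belongs to exactly one
#'   period; `"per_admission"`: one label per admission, so a patient may
#'   contribute to several periods.
#' @return for `"first_admission"`, a named character vector
#'   (patient -> label); for `"per_admission"`, a named list
#'   (patient -> label vector over admissions).
#' @export
assign_period <- function(records, periods = period_defs(),
                          policy = c("first_admission", "per_admission")) {
  stop_if(!inherits(records, "patient_records"),
          "records must be a patient_records object")
  policy <- match.arg(policy)
  if (policy == "first_admission") {
    lab <- year_to_period(records$patients$first_year, periods)
    stats::setNames(lab, records$patients$patient_id)
  } else {
    adm <- split(records$admissions$year, records$admissions$patient_id)
    lapply(adm, function(y) unique(year_to_period(y, periods)))
  }
}

#' Split a patient-level transaction set by period
#'
#' Uses the first-admission period assignment so each patient's
#' transaction lands in exactly one period (no leakage across strata).
#'
#' @param records a `patient_records` object.
#' @param periods a [period_defs()] frame.
#' @param min_categories minimum transaction size (2 restricts each
#'   stratum to its multimorbidity cohort).
#' @return named list of `transaction_set`s, one per period label.
#' @export
split_transactions_by_period <- function(records, periods = period_defs(),
                                         min_categories = 1L) {
  lab <- assign_period(records, periods, "first_admission")
  out <- lapply(periods$label, function(p) {
    ids <- names(lab)[lab == p]
    tx <- records$categories[ids]
    tx <- tx[lengths(tx) >= min_categories]
    if (length(tx) == 0L) return(NULL)
    new_transaction_set(tx)
  })
  stats::setNames(out, periods$label)
}

#' Canonicalise a rule into an orientation-free pattern
#'
#' X -> Y and Y -> X describe the same unordered comorbidity pattern; the
#' canonical form sorts each side and orders the two sides
#' lexicographically, yielding one identity per unordered rule.
#'
#' @param antecedent,consequent character vectors of categories.
#' @return a single string key, e.g. `"A01+B20|C55"`.
#' @export
canonical_pattern <- function(antecedent, consequent) {
  a <- itemset_key(antecedent); b <- itemset_key(consequent)
  if (a <= b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

#' Top-k canonical patterns of a rule set
#'
#' Rules are ranked by the given key ([rank_rules()] tie-breaking),
#' canonicalised, deduplicated in rank order, and the first `k` distinct
#' patterns kept.
#'
#' @param ruleset a `rule_set`.
#' @param k number of patterns.
#' @param key ranking metric (default support).
#' @return character vector of at most `k` canonical pattern keys.
#' @export
top_patterns <- function(ruleset, k = 20L, key = "support") {
  ranked <- rank_rules(ruleset, key = key, k = nrow(ruleset$rules))
  if (nrow(ranked) == 0L) return(character(0))
  pats <- mapply(canonical_pattern, ranked$antecedent, ranked$consequent)
  utils::head(unique(pats), k)
}

#' Jaccard similarity of two periods' top-k comorbidity patterns
#'
#' Takes each rule set's top `k` support-ranked canonical patterns and
#' computes `|A n B| / |A u B|`.
#'
#' @param rules_a,rules_b `rule_set`s mined with the same configuration.
#' @param k patterns per side (default 20).
#' @param labels optional character pair naming the two periods.
#' @return list of class `period_comparison` with `labels`, `jaccard`,
#'   `top_k`, `patterns_a`, `patterns_b`, `shared_patterns`.
#' @export
jaccard_topk <- function(rules_a, rules_b, k = 20L,
                         labels = c("A", "B")) {
  stop_if(k < 1, "k must be at least 1")
  pa <- top_patterns(rules_a, k)
  pb <- top_patterns(rules_b, k)
  stop_if(length(pa) == 0L && length(pb) == 0L,
          "both pattern sets are empty: Jaccard undefined")
  structure(list(labels = labels,
                 jaccard = length(intersect(pa, pb)) /
                   length(union(pa, pb)),
                 top_k = as.integer(k),
                 patterns_a = pa, patterns_b = pb,
                 shared_patterns = intersect(pa, pb)),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("period_comparison %s vs %s: Jaccard %.3f (top %d, %d shared)\n",
              x$labels[1], x$labels[2], x$jaccard, x$top_k,
              length(x$shared_patterns)))
  invisible(x)
}

#' Pairwise Jaccard comparisons across periods
#'
#' @param rulesets named list of `rule_set`s (one per period).
#' @param k patterns per side.
#' @return data frame `period_a`, `period_b`, `k`, `jaccard`, `n_shared`.
#' @export
jaccard_matrix <- function(rulesets, k = 20L) {
  labs <- names(rulesets)
  stop_if(length(labs) < 2L, "need at least two period rule sets")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    cmp <- jaccard_topk(rulesets[[pr[1]]], rulesets[[pr[2]]], k, pr)
    data.frame(period_a = pr[1], period_b = pr[2], k = as.integer(k),
               jaccard = cmp$jaccard,
               n_shared = length(cmp$shared_patterns),
               stringsAsFactors = FALSE)
  }))
}
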