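# Association-rule construction and the five rule metrics.

#' Rule metrics from supports
#'
#' Given the joint support `s` of X and Y, the antecedent support `s_x`
#' and the consequent support `s_y`:
#' confidence `= s / s_x`; lift `= s / (s_x * s_y)`; leverage
#' `= s - s_x * s_y`; conviction `= (1 - s_y) / (1 - confidence)`,
#' reported as `Inf` at confidence 1 (the formula's pole).
#'
#' @param s joint support of the combined items, in `[0, min(s_x, s_y)]`.
#' @param s_x antecedent support, in `(0, 1]`.
#' @param s_y consequent support, in `(0, 1]`.
#' @return named list with `confidence`, `lift`, `leverage`, `conviction`.
#' @export
rule_metrics <- function(s, s_x, s_y) {
  stop_if(s_x <= 0 || s_x > 1, "s_x must lie in (0, 1]")
  stop_if(s_y <= 0 || s_y > 1, "s_y must lie in (0, 1]")
  stop_if(s < 0, "s must be non-negative")
  stop_if(s > min(s_x, s_y) + 1e-12,
          "inconsistent supports: s exceeds min(s_x, s_y)")
  confidence <- s / s_x
  conviction <- if (confidence >= 1 - 1e-15) Inf
                else (1 - s_y) / (1 - confidence)
  list(confidence = confidence,
       lift = s / (s_x * s_y),
       leverage = s - s_x * s_y,
       conviction = conviction)
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset Z with at least 2 items, emits every
#' bipartition Z = X | Y with X, Y non-empty — both directions, since
#' X -> Y and Y -> X carry different confidence and conviction — and keeps
#' rules meeting the confidence and lift thresholds. Support thresholds
#' are inherited from the mining step.
#'
#' @param frequent a `frequent_itemsets` data frame (must contain every
#'   subset of each member, which downward closure guarantees).
#' @param config a [mining_config()].
#' @param n transaction count (defaults to the attribute carried by
#'   `frequent`).
#' @return an object of class `rule_set`: list with `rules` (data frame
#'   with list columns `antecedent`, `consequent`, keys, the five
#'   metrics), `config`, `n`.
#' @export
generate_rules <- function(frequent, config = mining_config(),
                           n = attr(frequent, "n_transactions")) {
  stop_if(!inherits(frequent, "frequent_itemsets"),
          "frequent must come from mine_frequent()/brute_force_frequent()")
  support_of <- stats::setNames(frequent$support, frequent$key)
  rows <- list()
  for (r in which(frequent$length >= 2L)) {
    z <- frequent$items[[r]]
    s <- frequent$support[r]
    kk <- length(z)
    for (mask in 1:(2^kk - 2L)) {
      x <- z[bitwAnd(mask, 2^(seq_len(kk) - 1L)) > 0]
      y <- setdiff(z, x)
      kx <- itemset_key(x); ky <- itemset_key(y)
      s_x <- unname(support_of[kx]); s_y <- unname(support_of[ky])
      stop_if(is.na(s_x) || is.na(s_y),
              "internal inconsistency: subset support missing for ",
              kx, " / ", ky)
      m <- rule_metrics(s, s_x, s_y)
      if (m$confidence >= config$min_confidence - 1e-12 &&
          m$lift >= config$min_lift - 1e-12) {
        rows[[length(rows) + 1L]] <- list(
          antecedent = x, consequent = y,
          antecedent_key = kx, consequent_key = ky,
          support_antecedent = s_x, support_consequent = s_y,
          support = s, confidence = m$confidence, lift = m$lift,
          leverage = m$leverage, conviction = m$conviction)
      }
    }
  }
  rules <- if (length(rows) == 0L) {
    df <- data.frame(antecedent_key = character(),
                     consequent_key = character(),
                     support_antecedent = numeric(),
                     support_consequent = numeric(), support = numeric(),
                     confidence = numeric(), lift = numeric(),
                     leverage = numeric(), conviction = numeric(),
                     stringsAsFactors = FALSE)
    df$antecedent <- list(); df$consequent <- list()
    df
  } else {
    df <- data.frame(
      antecedent_key = vapply(rows, `[[`, character(1), "antecedent_key"),
      consequent_key = vapply(rows, `[[`, character(1), "consequent_key"),
      support_antecedent = vapply(rows, `[[`, numeric(1), "support_antecedent"),
      support_consequent = vapply(rows, `[[`, numeric(1), "support_consequent"),
      support = vapply(rows, `[[`, numeric(1), "support"),
      confidence = vapply(rows, `[[`, numeric(1), "confidence"),
      lift = vapply(rows, `[[`, numeric(1), "lift"),
      leverage = vapply(rows, `[[`, numeric(1), "leverage"),
      conviction = vapply(rows, `[[`, numeric(1), "conviction"),
      stringsAsFactors = FALSE)
    df$antecedent <- lapply(rows, `[[`, "antecedent")
    df$consequent <- lapply(rows, `[[`, "consequent")
    df
  }
  structure(list(rules = rules, config = config, n = n), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("rule_set:", nrow(x$rules), "rules over", x$n, "transactions",
      "(min_support", x$config$min_support,
      "min_confidence", x$config$min_confidence,
      "min_lift", x$config$min_lift, ")\n")
  invisible(x)
}

#' Rank rules by a metric
#'
#' Stable descending sort with deterministic tie-breaking: the chosen key,
#' then descending support, then descending lift, then lexicographic
#' antecedent and consequent keys.
#'
#' @param ruleset a `rule_set`.
#' @param key one of `"support"`, `"lift"`, `"confidence"`.
#' @param k number of rules to return (the whole ranking if larger).
#' @return the rules data frame, top `k` rows.
#' @export
rank_rules <- function(ruleset, key = c("support", "lift", "confidence"),
                       k = nrow(ruleset$rules)) {
  stop_if(!inherits(ruleset, "rule_set"), "ruleset must be a rule_set")
  key <- match.arg(key)
  stop_if(k < 1, "k must be at least 1")
  r <- ruleset$rules
  if (nrow(r) == 0L) return(r)
  ord <- order(-r[[key]], -r$support, -r$lift,
               r$antecedent_key, r$consequent_key)
  out <- r[ord, ]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Write association rules to CSV
#'
#' Mirrors the published table layout: antecedent, consequent, support by
#' antecedent, support by consequent, support, confidence, lift, leverage,
#' conviction. Item lists are `"+"`-joined; infinite conviction is
#' serialised as `"inf"`.
#'
#' @param ruleset a `rule_set` (or a ranked rules data frame).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rules_csv <- function(ruleset, path) {
  r <- if (inherits(ruleset, "rule_set")) ruleset$rules else ruleset
  write_csv_strict(data.frame(
    antecedent = r$antecedent_key,
    consequent = r$consequent_key,
    support_by_antecedent = r$support_antecedent,
    support_by_consequent = r$support_consequent,
    support = r$support,
    confidence = r$confidence,
    lift = r$lift,
    leverage = r$leverage,
    conviction = ifelse(is.infinite(r$conviction), "inf",
                        as.character(r$conviction)),
    stringsAsFactors = FALSE), path)
}
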