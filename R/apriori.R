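# Level-wise Apriori frequent-itemset mining, written from scratch.
#
# Support counting uses per-itemset transaction-id vectors: the tid list
# of a (k)-itemset is the intersection of a (k-1)-itemset's tids with the
# joined item's tids, so each level costs one sorted-intersection per
# candidate. Counts are exact; the representation is internal.

#' Mining configuration
#'
#' Thresholds for frequent-itemset and rule mining. The defaults —
#' minimum support 0.20, minimum confidence 0.20, minimum lift 1.0,
#' maximum itemset length 4 — capture frequent comorbidity combinations
#' (>= 20% of transactions), keep exploratory low-confidence rules,
#' exclude negative associations, and cap patterns at 4 diseases to avoid
#' rule explosion.
#'
#' @param min_support minimum itemset support, in `(0, 1]`.
#' @param min_confidence minimum rule confidence, in `(0, 1]`.
#' @param min_lift minimum rule lift, non-negative.
#' @param max_len maximum itemset length, `>= 2`.
#' @return an object of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.20, min_confidence = 0.20,
                          min_lift = 1.0, max_len = 4L) {
  stop_if(!is.numeric(min_support) || min_support <= 0 || min_support > 1,
          "min_support must lie in (0, 1]")
  stop_if(!is.numeric(min_confidence) || min_confidence <= 0 ||
            min_confidence > 1, "min_confidence must lie in (0, 1]")
  stop_if(!is.numeric(min_lift) || min_lift < 0,
          "min_lift must be non-negative")
  stop_if(!is.numeric(max_len) || max_len < 2,
          "max_len must be at least 2")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, max_len = as.integer(max_len)),
            class = "mining_config")
}

#' Mine frequent itemsets with the Apriori algorithm
#'
#' Level-wise search: frequent singletons first, then candidate
#' (k+1)-itemsets generated by joining frequent k-itemsets that share a
#' (k-1)-prefix, pruned by the downward-closure property (every
#' k-subset must itself be frequent) before support counting.
#'
#' @param tset a `transaction_set`.
#' @param config a [mining_config()].
#' @return a data frame of class `frequent_itemsets` with columns `items`
#'   (list column of sorted category vectors), `key` (`"+"`-joined items),
#'   `support`, `count` and `length`, sorted by (length, descending
#'   support, lexicographic items). Itemsets of every size from 1 to
#'   `max_len` are included; pattern-style outputs should drop size 1.
#' @export
mine_frequent <- function(tset, config = mining_config()) {
  stop_if(!inherits(tset, "transaction_set"), "tset must be a transaction_set")
  stop_if(!inherits(config, "mining_config"), "config must be a mining_config")
  n <- tset$n
  stop_if(n < 1L, "transaction set is empty")
  min_count <- config$min_support * n - 1e-9

  # tid lists per item, ascending
  tids <- lapply(tset$universe, function(it) {
    which(vapply(tset$transactions, function(tx) it %in% tx, logical(1)))
  })
  names(tids) <- tset$universe

  level_items <- as.list(tset$universe[lengths(tids) >= min_count])
  level_tids <- tids[lengths(tids) >= min_count]
  out_items <- list(); out_support <- numeric(); out_count <- integer()

  k <- 1L
  while (length(level_items) > 0L) {
    ord <- order(vapply(level_items, itemset_key, character(1)))
    level_items <- level_items[ord]; level_tids <- level_tids[ord]
    out_items <- c(out_items, level_items)
    out_count <- c(out_count, lengths(level_tids))
    out_support <- c(out_support, lengths(level_tids) / n)
    if (k >= config$max_len) break

    freq_keys <- vapply(out_items, itemset_key, character(1))
    next_items <- list(); next_tids <- list()
    if (length(level_items) >= 2L) {
      prefixes <- vapply(level_items, function(x)
        paste(x[-length(x)], collapse = "+"), character(1))
      lasts <- vapply(level_items, function(x) x[length(x)], character(1))
      for (grp in split(seq_along(level_items), prefixes)) {
        if (length(grp) < 2L) next
        for (a in seq_along(grp)[-length(grp)]) {
          for (b in (a + 1L):length(grp)) {
            i <- grp[a]; j <- grp[b]
            cand <- sort(c(level_items[[i]], lasts[j]))
            # downward-closure prune: all k-subsets must be frequent
            subs_ok <- all(vapply(seq_along(cand), function(d)
              itemset_key(cand[-d]) %in% freq_keys, logical(1)))
            if (!subs_ok) next
            tt <- intersect(level_tids[[i]], level_tids[[j]])
            if (length(tt) >= min_count) {
              next_items[[length(next_items) + 1L]] <- cand
              next_tids[[length(next_tids) + 1L]] <- tt
            }
          }
        }
      }
    }
    level_items <- next_items; level_tids <- next_tids
    k <- k + 1L
  }
  make_frequent_df(out_items, out_support, out_count, n)
}

#' Brute-force frequent-itemset oracle
#'
#' Enumerates every subset of the universe up to `max_len` and counts
#' support directly against each transaction. Exponential; guarded to
#' universes of at most 20 items. Shares the ordering contract of
#' [mine_frequent()], for which it serves as the independent reference.
#'
#' @inheritParams mine_frequent
#' @return a `frequent_itemsets` data frame.
#' @export
brute_force_frequent <- function(tset, config = mining_config()) {
  stop_if(!inherits(tset, "transaction_set"), "tset must be a transaction_set")
  stop_if(tset$n < 1L, "transaction set is empty")
  stop_if(length(tset$universe) > 20L,
          "brute force guard: universe exceeds 20 items")
  n <- tset$n
  min_count <- config$min_support * n - 1e-9
  items <- list(); support <- numeric(); count <- integer()
  for (k in seq_len(min(config$max_len, length(tset$universe)))) {
    cmb <- utils::combn(sort(tset$universe), k, simplify = FALSE)
    for (cand in cmb) {
      cnt <- sum(vapply(tset$transactions,
                        function(tx) all(cand %in% tx), logical(1)))
      if (cnt >= min_count) {
        items[[length(items) + 1L]] <- cand
        count <- c(count, cnt); support <- c(support, cnt / n)
      }
    }
  }
  make_frequent_df(items, support, count, n)
}

make_frequent_df <- function(items, support, count, n) {
  df <- data.frame(key = vapply(items, itemset_key, character(1)),
                   support = support, count = as.integer(count),
                   length = lengths(items), stringsAsFactors = FALSE)
  df$items <- items
  df <- df[order(df$length, -df$support, df$key),
           c("items", "key", "support", "count", "length")]
  rownames(df) <- NULL
  attr(df, "n_transactions") <- n
  class(df) <- c("frequent_itemsets", "data.frame")
  df
}

#' Write frequent itemsets to CSV
#'
#' Columns `items` (`"+"`-joined), `support`, `count`, `length`.
#'
#' @param frequent a `frequent_itemsets` data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_frequent_csv <- function(frequent, path) {
  write_csv_strict(data.frame(items = frequent$key,
                              support = frequent$support,
                              count = frequent$count,
                              length = frequent$length,
                              stringsAsFactors = FALSE), path)
}
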