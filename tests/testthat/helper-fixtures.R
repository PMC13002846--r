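# Shared fixtures: random transaction sets, small cohorts, and the
# exhaustive betweenness oracle used against the network module.

# Random transaction set over at most `max_items` items.
random_transaction_set <- function(n_tx = 20, max_items = 8) {
  items <- LETTERS[seq_len(sample(3:max_items, 1))]
  sets <- replicate(n_tx, {
    k <- sample(seq_along(items), 1)
    sample(items, k)
  }, simplify = FALSE)
  transaction_set(sets)
}

# Tiny two-block cohort spec used across module tests.
toy_block_spec <- function(n = 500, seed = 42) {
  cohort_spec(
    n_patients = n,
    background_prevalence = c(A01 = 0.3, B20 = 0.1, B37 = 0.1, E87 = 0.2,
                              C10 = 0.05),
    blocks = list(
      comorbidity_block("inf", 0.5, c(B20 = 0.9, B37 = 0.8)),
      comorbidity_block("met", 0.4, c(E87 = 0.7, A01 = 0.3))),
    period_weights = c("2019-2020" = 0.4, "2021-2022" = 0.35,
                       "2023-2024" = 0.25),
    seed = seed)
}

# Empirical support of an itemset over a cohort's patient category sets.
empirical_support <- function(cohort, items) {
  mean(vapply(cohort$categories, function(s) all(items %in% s), logical(1)))
}

# Random connected-ish undirected weighted graph as an edge frame.
random_edge_frame <- function(max_nodes = 8) {
  n <- sample(4:max_nodes, 1)
  nodes <- LETTERS[seq_len(n)]
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < 0.45
  if (!any(keep)) keep[sample(nrow(pairs), 2)] <- TRUE
  data.frame(u = pairs[keep, 1], v = pairs[keep, 2],
             weight = sample(1:9, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Exhaustive betweenness oracle: enumerates every shortest path between
# every node pair by depth-first walks over BFS predecessor sets, credits
# interior nodes fractionally, and normalises by (n-1)(n-2)/2.
# Independent of both igraph and the package implementation.
oracle_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$u, edges$v)))
  n <- length(nodes)
  adj <- stats::setNames(lapply(nodes, function(v) {
    sort(unique(c(edges$v[edges$u == v], edges$u[edges$v == v])))
  }), nodes)
  score <- stats::setNames(rep(0, n), nodes)
  if (n < 3) return(score)
  all_shortest_paths <- function(s, t) {
    dist <- stats::setNames(rep(Inf, n), nodes); dist[s] <- 0
    preds <- stats::setNames(vector("list", n), nodes)
    frontier <- s
    while (length(frontier) > 0 && is.infinite(dist[t])) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          if (!(w %in% nxt)) nxt <- c(nxt, w)
          dist[w] <- dist[v] + 1
          preds[[w]] <- c(preds[[w]], v)
        } else if (dist[w] == dist[v] + 1) {
          preds[[w]] <- c(preds[[w]], v)
        }
      }
      frontier <- nxt
    }
    if (is.infinite(dist[t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      out <- list()
      for (p in preds[[v]]) {
        for (pth in walk(p)) out[[length(out) + 1]] <- c(pth, v)
      }
      out
    }
    walk(t)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_shortest_paths(nodes[i], nodes[j])
    if (length(paths) == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(nodes[i], nodes[j]))
      score[interior] <- score[interior] + 1 / length(paths)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

anchor_rows <- function() {
  utils::read.csv(system.file("extdata", "rule_anchor_rows.csv",
                              package = "comorbnet"),
                  stringsAsFactors = FALSE)
}
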