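# Co-occurrence edges, edge-selection policies, centralities, export.

test_that("co-occurrence weights match hand counts and pair supports", {
  ts <- transaction_set(list(c("A", "B"), c("A", "B", "C"), c("B", "C")))
  ed <- cooccurrence_edges(ts)
  w <- stats::setNames(ed$weight, paste(ed$u, ed$v))
  expect_equal(w[["A B"]], 2L)
  expect_equal(w[["B C"]], 2L)
  expect_equal(w[["A C"]], 1L)
  # identity with pair-itemset counts from the miner
  f <- mine_frequent(ts, mining_config(0.01))
  pairs <- f[f$length == 2, ]
  for (r in seq_len(nrow(pairs))) {
    key <- paste(pairs$items[[r]][1], pairs$items[[r]][2])
    expect_equal(unname(w[[key]]), pairs$count[r])
  }
  # single-item transactions only: no edges
  expect_equal(nrow(cooccurrence_edges(transaction_set(list("A", "B")))), 0)
})

test_that("edge selection policies keep top-k or honour the node budget", {
  ed <- data.frame(u = c("A", "B", "C"), v = c("B", "C", "D"),
                   weight = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  net_k <- build_network(ed, edge_selection_policy("top_k_edges", k = 2))
  expect_equal(nrow(net_k$edges), 2)
  expect_lte(nrow(net_k$nodes), 4)
  # node budget min = max = 3: stepwise rule retains (A,B),(B,C)
  net_b <- build_network(ed, edge_selection_policy("node_budget",
                                                   node_min = 3, node_max = 3))
  expect_equal(nrow(net_b$nodes), 3)
  expect_setequal(net_b$nodes$category, c("A", "B", "C"))
  # k beyond the edge count returns the whole graph
  net_all <- build_network(ed, edge_selection_policy("top_k_edges", k = 99))
  expect_equal(nrow(net_all$edges), 3)
  expect_error(build_network(ed[0, ], edge_selection_policy()), "empty")
})

test_that("node budget skips oversize edges and lands inside the budget", {
  set.seed(5)
  spec <- study_cohort_spec(n_patients = 800, seed = 99)
  co <- generate_cohort(spec)
  tset <- transaction_set(Filter(function(x) length(x) >= 2, co$categories))
  ed <- cooccurrence_edges(tset)
  expect_gte(length(unique(c(ed$u, ed$v))), 24)
  net <- build_network(ed, edge_selection_policy("node_budget"))
  expect_gte(nrow(net$nodes), 24)
  expect_lte(nrow(net$nodes), 34)
})

test_that("betweenness matches closed forms on canonical graphs", {
  path3 <- data.frame(u = c("A", "B"), v = c("B", "C"), weight = c(1L, 1L))
  b3 <- betweenness_centrality(
    build_network(path3, edge_selection_policy("top_k_edges", k = 9)))
  expect_equal(unname(b3[c("A", "B", "C")]), c(0, 1, 0))
  path4 <- data.frame(u = c("A", "B", "C"), v = c("B", "C", "D"),
                      weight = rep(1L, 3))
  b4 <- betweenness_centrality(
    build_network(path4, edge_selection_policy("top_k_edges", k = 9)))
  expect_equal(unname(b4[["B"]]), 2 / 3)
  star <- data.frame(u = rep("Z", 4), v = c("A", "B", "C", "D"),
                     weight = rep(1L, 4))
  bs <- betweenness_centrality(
    build_network(star, edge_selection_policy("top_k_edges", k = 9)))
  expect_equal(unname(bs[["Z"]]), 1)
  expect_equal(unname(bs[c("A", "B", "C", "D")]), rep(0, 4))
  # fewer than 3 nodes: degenerate normalisation, all zeros
  b2 <- betweenness_centrality(
    build_network(path3[1, ], edge_selection_policy("top_k_edges", k = 9)))
  expect_equal(unname(b2), c(0, 0))
})

test_that("betweenness matches the exhaustive path-enumeration oracle", {
  set.seed(314)
  for (i in 1:50) {
    ed <- random_edge_frame(8)
    net <- build_network(ed, edge_selection_policy("top_k_edges",
                                                   k = nrow(ed)))
    got <- betweenness_centrality(net)
    want <- oracle_betweenness(ed)
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 tolerance = 1e-10)
  }
})

test_that("summary identities: degrees, density, clustering", {
  tri <- data.frame(u = c("A", "A", "B"), v = c("B", "C", "C"),
                    weight = c(1L, 1L, 1L))
  net <- build_network(tri, edge_selection_policy("top_k_edges", k = 9))
  s <- net$summary
  expect_equal(s$density, 1)
  expect_equal(s$avg_clustering, 1)
  expect_equal(s$avg_weighted_degree, 2)
  star <- data.frame(u = rep("Z", 3), v = c("A", "B", "C"),
                     weight = rep(1L, 3))
  expect_equal(build_network(star, edge_selection_policy("top_k_edges",
                                                         k = 9))$summary$avg_clustering, 0)
  pathw <- data.frame(u = c("A", "B"), v = c("B", "C"), weight = c(5L, 3L))
  netw <- build_network(pathw, edge_selection_policy("top_k_edges", k = 9))
  expect_equal(sort(netw$nodes$weighted_degree), c(3, 5, 8))
  expect_equal(netw$summary$avg_weighted_degree, 16 / 3)
  # random graphs: sum of degrees = 2E, density in [0, 1]
  set.seed(6)
  for (i in 1:20) {
    ed <- random_edge_frame(8)
    n2 <- build_network(ed, edge_selection_policy("top_k_edges",
                                                  k = nrow(ed)))
    expect_equal(sum(n2$nodes$degree), 2 * nrow(n2$edges))
    expect_gte(n2$summary$density, 0); expect_lte(n2$summary$density, 1)
  }
})

test_that("networks round-trip through GEXF, GraphML and edge CSV", {
  tri <- data.frame(u = c("A", "A", "B"), v = c("B", "C", "C"),
                    weight = c(3L, 2L, 1L))
  net <- build_network(tri, edge_selection_policy("top_k_edges", k = 9))
  for (fmt in c("gexf", "graphml", "edge_csv")) {
    path <- tempfile(fileext = paste0(".", sub("_csv", ".csv", fmt)))
    export_network(net, path, fmt)
    back <- import_network(path, fmt)
    expect_equal(back$edges[c("u", "v", "weight")],
                 net$edges[c("u", "v", "weight")])
    expect_equal(back$summary, net$summary)
  }
  expect_error(export_network(net, tempfile(), "dot"), "arg")
  # edge CSV of a 2-edge path has 2 rows
  pathw <- build_network(data.frame(u = c("A", "B"), v = c("B", "C"),
                                    weight = c(5L, 3L)),
                         edge_selection_policy("top_k_edges", k = 9))
  f <- tempfile(fileext = ".csv")
  export_network(pathw, f, "edge_csv")
  expect_equal(nrow(utils::read.csv(f)), 2)
})
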