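# Weighted disease co-occurrence networks: edge construction, the two
# edge-selection policies, node centralities and graph-level summaries.
# Graph algorithms are delegated to igraph behind this module's surface;
# betweenness is computed on the unweighted topology and normalised to
# [0, 1].

#' Co-occurrence edges of a transaction set
#'
#' One undirected edge per unordered category pair appearing together in
#' at least one transaction; the weight is the number of transactions
#' containing both (so weight = pair support x n).
#'
#' @param tset a `transaction_set`.
#' @return data frame `u`, `v` (u < v lexicographically), `weight`,
#'   sorted by descending weight then lexicographic pair.
#' @export
cooccurrence_edges <- function(tset) {
  stop_if(!inherits(tset, "transaction_set"), "tset must be a transaction_set")
  stop_if(tset$n < 1L, "transaction set is empty")
  counts <- new.env(parent = emptyenv())
  for (tx in tset$transactions) {
    if (length(tx) < 2L) next
    cmb <- utils::combn(tx, 2)  # tx already sorted
    keys <- paste(cmb[1, ], cmb[2, ], sep = "\r")
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    return(data.frame(u = character(), v = character(), weight = integer(),
                      stringsAsFactors = FALSE))
  }
  uv <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(u = uv[, 1], v = uv[, 2],
                   weight = vapply(keys, function(k) counts[[k]], integer(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$u, df$v), ]
  rownames(df) <- NULL
  df
}

#' Edge-selection policy for network construction
#'
#' `top_k_edges` keeps the `k` highest-weight edges (the per-period
#' networks). `node_budget` adds edges in rank order until the node count
#' first reaches `node_min`, skipping any edge that would push it past
#' `node_max` (the overview networks of roughly 24-34 disease nodes).
#'
#' @param mode `"top_k_edges"` or `"node_budget"`.
#' @param k edge count for `top_k_edges` (default 20).
#' @param node_min,node_max node budget bounds (defaults 24, 34).
#' @return an object of class `edge_selection_policy`.
#' @export
edge_selection_policy <- function(mode = c("top_k_edges", "node_budget"),
                                  k = 20L, node_min = 24L, node_max = 34L) {
  mode <- match.arg(mode)
  stop_if(k < 1, "k must be at least 1")
  stop_if(node_min > node_max, "node_min must not exceed node_max")
  structure(list(mode = mode, k = as.integer(k),
                 node_min = as.integer(node_min),
                 node_max = as.integer(node_max)),
            class = "edge_selection_policy")
}

#' Build a comorbidity network from ranked co-occurrence edges
#'
#' Applies the edge-selection policy, then computes node metrics (degree,
#' weighted degree, betweenness centrality) and graph-level summaries
#' (density, average weighted degree, average clustering coefficient).
#'
#' @param edges data frame from [cooccurrence_edges()] (ranked: descending
#'   weight, lexicographic pair).
#' @param policy an [edge_selection_policy()].
#' @return an object of class `comorbidity_network`: list with `nodes`
#'   (data frame `category`, `degree`, `weighted_degree`, `betweenness`),
#'   `edges` (retained edge frame), `summary` (n_nodes, n_edges, density,
#'   avg_weighted_degree, avg_clustering).
#' @export
build_network <- function(edges, policy = edge_selection_policy()) {
  stop_if(!inherits(policy, "edge_selection_policy"),
          "policy must be an edge_selection_policy")
  stop_if(nrow(edges) == 0L, "edge list is empty")
  edges <- edges[order(-edges$weight, edges$u, edges$v), ]
  if (policy$mode == "top_k_edges") {
    kept <- utils::head(edges, policy$k)
  } else {
    nodes <- character(0)
    take <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      new_nodes <- union(nodes, c(edges$u[i], edges$v[i]))
      if (length(new_nodes) > policy$node_max) next  # skip and continue
      take[i] <- TRUE
      nodes <- new_nodes
      if (length(nodes) >= policy$node_min) break
    }
    kept <- edges[take, ]
  }
  rownames(kept) <- NULL
  g <- igraph::graph_from_data_frame(kept, directed = FALSE)
  node_names <- igraph::V(g)$name
  degree <- igraph::degree(g)
  wdegree <- igraph::strength(g, weights = igraph::E(g)$weight)
  btw <- betweenness_centrality_graph(g)
  nodes_df <- data.frame(category = node_names,
                         degree = as.integer(degree),
                         weighted_degree = as.numeric(wdegree),
                         betweenness = as.numeric(btw),
                         stringsAsFactors = FALSE)
  nodes_df <- nodes_df[order(-nodes_df$weighted_degree, nodes_df$category), ]
  rownames(nodes_df) <- NULL
  net <- structure(list(nodes = nodes_df, edges = kept, summary = NULL),
                   class = "comorbidity_network")
  net$summary <- network_summary(net)
  net
}

# Normalised betweenness on the unweighted topology of an igraph object.
betweenness_centrality_graph <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3L) {
    return(stats::setNames(rep(0, n), igraph::V(g)$name))
  }
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  raw / ((n - 1) * (n - 2) / 2)
}

#' Betweenness centrality of a comorbidity network
#'
#' Fraction of unweighted shortest paths between other node pairs passing
#' through each node, with fractional credit for equal-length
#' multiplicities, normalised by `(n-1)(n-2)/2`; all zeros when the
#' network has fewer than 3 nodes. Disconnected graphs are handled
#' per reachable pair.
#'
#' @param network a `comorbidity_network`.
#' @return named numeric vector, node -> value in `[0, 1]`.
#' @export
betweenness_centrality <- function(network) {
  stop_if(!inherits(network, "comorbidity_network"),
          "network must be a comorbidity_network")
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE)
  betweenness_centrality_graph(g)
}

#' Graph-level summary of a comorbidity network
#'
#' @param network a `comorbidity_network` with at least 2 nodes.
#' @return data frame with `n_nodes`, `n_edges`, `density`
#'   (`2E / (N(N-1))`), `avg_weighted_degree`, `avg_clustering`
#'   (mean local clustering coefficient, unweighted, degree-<2 nodes
#'   contributing 0).
#' @export
network_summary <- function(network) {
  stop_if(!inherits(network, "comorbidity_network"),
          "network must be a comorbidity_network")
  n <- nrow(network$nodes)
  stop_if(n < 2L, "network summary requires at least 2 nodes")
  e <- nrow(network$edges)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0
  data.frame(n_nodes = n, n_edges = e,
             density = 2 * e / (n * (n - 1)),
             avg_weighted_degree = mean(network$nodes$weighted_degree),
             avg_clustering = mean(cc))
}

#' @export
print.comorbidity_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("comorbidity_network: %d nodes, %d edges, density ",
                     "%.3f, avg weighted degree %.1f, avg clustering %.3f\n"),
              s$n_nodes, s$n_edges, s$density, s$avg_weighted_degree,
              s$avg_clustering))
  invisible(x)
}

#' Export a comorbidity network
#'
#' GEXF (Gephi-compatible) and GraphML carry node attributes `degree`,
#' `weighted_degree`, `betweenness` and the edge attribute `weight`;
#' `edge_csv` writes `source,target,weight`.
#'
#' @param network a `comorbidity_network`.
#' @param path output file path.
#' @param format `"gexf"`, `"graphml"` or `"edge_csv"`.
#' @return the path, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("gexf", "graphml", "edge_csv")) {
  stop_if(!inherits(network, "comorbidity_network"),
          "network must be a comorbidity_network")
  format <- match.arg(format)
  if (format == "edge_csv") {
    return(write_csv_strict(data.frame(source = network$edges$u,
                                       target = network$edges$v,
                                       weight = network$edges$weight,
                                       stringsAsFactors = FALSE), path))
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE)
    idx <- match(igraph::V(g)$name, network$nodes$category)
    igraph::V(g)$degree <- network$nodes$degree[idx]
    igraph::V(g)$weighted_degree <- network$nodes$weighted_degree[idx]
    igraph::V(g)$betweenness <- network$nodes$betweenness[idx]
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  write_gexf(network, path)
}

# Minimal GEXF 1.2 writer (undirected, static) readable by Gephi.
write_gexf <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nd <- network$nodes
  node_xml <- sprintf(paste0(
    '      <node id="%s" label="%s">\n        <attvalues>\n',
    '          <attvalue for="0" value="%d"/>\n',
    '          <attvalue for="1" value="%.10g"/>\n',
    '          <attvalue for="2" value="%.10g"/>\n',
    '        </attvalues>\n      </node>'),
    esc(nd$category), esc(nd$category), nd$degree, nd$weighted_degree,
    nd$betweenness)
  ed <- network$edges
  edge_xml <- sprintf(
    '      <edge id="e%d" source="%s" target="%s" weight="%.10g"/>',
    seq_len(nrow(ed)) - 1L, esc(ed$u), esc(ed$v), as.numeric(ed$weight))
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="degree" type="integer"/>',
    '      <attribute id="1" title="weighted_degree" type="double"/>',
    '      <attribute id="2" title="betweenness" type="double"/>',
    '    </attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>',
    '</gexf>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Read a network back from an exported file
#'
#' Round-trip companion of [export_network()]; reconstructs the edge list
#' (and recomputes node metrics) from GEXF, GraphML or edge CSV.
#'
#' @param path file path.
#' @param format `"gexf"`, `"graphml"` or `"edge_csv"`.
#' @return a `comorbidity_network`.
#' @export
import_network <- function(path, format = c("gexf", "graphml", "edge_csv")) {
  format <- match.arg(format)
  edges <- switch(format,
    edge_csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      data.frame(u = df$source, v = df$target, weight = df$weight,
                 stringsAsFactors = FALSE)
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      el <- igraph::as_data_frame(g, what = "edges")
      data.frame(u = el$from, v = el$to, weight = el$weight,
                 stringsAsFactors = FALSE)
    },
    gexf = {
      doc <- xml2::read_xml(path)
      ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
      en <- xml2::xml_find_all(doc, ".//g:edge", ns)
      data.frame(u = xml2::xml_attr(en, "source"),
                 v = xml2::xml_attr(en, "target"),
                 weight = as.numeric(xml2::xml_attr(en, "weight")),
                 stringsAsFactors = FALSE)
    })
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  edges <- edges[order(-edges$weight, edges$u, edges$v), ]
  rownames(edges) <- NULL
  build_network(edges, edge_selection_policy("top_k_edges", k = nrow(edges)))
}
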