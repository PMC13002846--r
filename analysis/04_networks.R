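#!/usr/bin/env Rscript
# Step 4 — weighted disease co-occurrence networks.
#
# Overview network under the node-budget policy (edges added by
# descending co-occurrence weight until 24-34 disease nodes) and one
# top-20-edge network per admission period; node centralities (degree,
# weighted degree, betweenness) and graph-level summaries are written
# alongside Gephi-compatible GEXF exports.

library(comorbnet)

records <- consolidate_patients(read_diagnoses("results/cohort.csv"))
tset <- build_transactions(records, "patient", min_categories = 2L)

nets <- list(overall = build_network(cooccurrence_edges(tset),
                                     edge_selection_policy("node_budget")))
tsets <- Filter(Negate(is.null),
                split_transactions_by_period(records, period_defs(),
                                             min_categories = 2L))
for (p in names(tsets)) {
  nets[[p]] <- build_network(cooccurrence_edges(tsets[[p]]),
                             edge_selection_policy("top_k_edges", k = 20))
}

summaries <- do.call(rbind, lapply(names(nets), function(nm) {
  cbind(data.frame(network = nm), nets[[nm]]$summary)
}))
utils::write.csv(summaries, "results/network_summaries.csv",
                 row.names = FALSE)

for (nm in names(nets)) {
  safe <- gsub("-", "_", nm)
  export_network(nets[[nm]], sprintf("results/network_%s.gexf", safe), "gexf")
  utils::write.csv(nets[[nm]]$nodes,
                   sprintf("results/network_%s_nodes.csv", safe),
                   row.names = FALSE)
  hubs <- utils::head(nets[[nm]]$nodes, 3)
  message(sprintf("%s: %d nodes, %d edges, density %.3f; hub nodes: %s", nm,
                  nets[[nm]]$summary$n_nodes, nets[[nm]]$summary$n_edges,
                  nets[[nm]]$summary$density,
                  paste(sprintf("%s (wdeg %.0f, btw %.3f)", hubs$category,
                                hubs$weighted_degree, hubs$betweenness),
                        collapse = ", ")))
}
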