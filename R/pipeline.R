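# End-to-end pipeline: diagnosis CSV -> coding -> mining -> temporal
# comparison -> networks -> statistical tables, with a run log.

#' Pipeline configuration
#'
#' @param input path to the diagnosis-row CSV.
#' @param output_dir directory for the output bundle (created if absent).
#' @param policy an [exclusion_policy()].
#' @param index_codes index-disease categories excluded from comorbidity
#'   counts (default none: the count covers all retained categories, with
#'   HIV codes excludable via this argument).
#' @param mining a [mining_config()].
#' @param periods a [period_defs()] frame.
#' @param network_policy policy for the overview network (default
#'   `node_budget` 24-34).
#' @param period_network_policy policy for per-period networks (default
#'   top 20 edges).
#' @param top_k_patterns patterns per side in the Jaccard comparison.
#' @param min_categories multimorbidity threshold for the analysis cohort
#'   (default 2: patients with at least two retained conditions).
#' @param stage_map named stage vector, or `NULL` for the packaged default.
#' @param seed seed echoed in the log (the analysis path is seed-free).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir,
                            policy = exclusion_policy(),
                            index_codes = character(),
                            mining = mining_config(),
                            periods = period_defs(),
                            network_policy = edge_selection_policy("node_budget"),
                            period_network_policy =
                              edge_selection_policy("top_k_edges", k = 20L),
                            top_k_patterns = 20L,
                            min_categories = 2L,
                            stage_map = NULL,
                            seed = 1L) {
  stop_if(missing(input) || !file.exists(input),
          "config: input file not found: ",
          if (missing(input)) "<missing>" else input)
  structure(list(input = input, output_dir = output_dir, policy = policy,
                 index_codes = index_codes, mining = mining,
                 periods = periods, network_policy = network_policy,
                 period_network_policy = period_network_policy,
                 top_k_patterns = as.integer(top_k_patterns),
                 min_categories = as.integer(min_categories),
                 stage_map = stage_map, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `input`, `output_dir`, `excluded_letters`,
#' `index_codes`, `min_support`, `min_confidence`, `min_lift`, `max_len`,
#' `periods` (labels), `top_k_patterns`, `min_categories`, `seed`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  y <- yaml::read_yaml(path)
  pipeline_config(
    input = y$input, output_dir = y$output_dir,
    policy = if (is.null(y$excluded_letters)) exclusion_policy()
             else exclusion_policy(y$excluded_letters),
    index_codes = y$index_codes %||% character(),
    mining = mining_config(y$min_support %||% 0.20,
                           y$min_confidence %||% 0.20,
                           y$min_lift %||% 1.0,
                           y$max_len %||% 4L),
    periods = if (is.null(y$periods)) period_defs()
              else period_defs(unlist(y$periods)),
    top_k_patterns = y$top_k_patterns %||% 20L,
    min_categories = y$min_categories %||% 2L,
    seed = y$seed %||% 1L)
}

#' Run the full comorbidity analysis pipeline
#'
#' Reads the diagnosis CSV, consolidates patients, mines the overall
#' multimorbidity cohort and each admission period, compares periods by
#' Jaccard similarity of top-k patterns, builds the overview
#' (node-budget) and per-period (top-20-edge) co-occurrence networks, and
#' writes the statistical tables. All outputs are deterministic given the
#' input file and configuration.
#'
#' Output bundle (in `config$output_dir`): `frequent_itemsets.csv`,
#' `rules.csv`, `rules_<period>.csv`, `jaccard.csv`,
#' `network_overall.gexf/.csv`, `network_<period>.gexf/.csv`,
#' `network_summaries.csv`, `comorbidity_distribution.csv`,
#' `subgroup_comparisons.csv`, `who_stage.csv`, `run_log.txt`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `records`,
#'   `transactions`, `frequent`, `rules`, `period_rules`, `jaccard`,
#'   `networks`, `summaries`, `distribution`, `subgroup_tests`.
#' @export
run_pipeline <- function(config) {
  stop_if(!inherits(config, "pipeline_config"),
          "config must be a pipeline_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("comorbnet pipeline | seed %d", config$seed),
                 sprintf("input: %s", config$input),
                 sprintf("thresholds: support %.2f confidence %.2f lift %.2f max_len %d",
                         config$mining$min_support, config$mining$min_confidence,
                         config$mining$min_lift, config$mining$max_len),
                 sprintf("excluded chapters: %s",
                         paste(config$policy$excluded_letters, collapse = "")),
                 "quartile convention: linear interpolation (type 7)")

  # --- ingest ---------------------------------------------------------
  diagnoses <- tryCatch(read_diagnoses(config$input),
                        error = function(e) stop("[ingest] ", conditionMessage(e),
                                                 call. = FALSE))
  records <- tryCatch(
    consolidate_patients(diagnoses, config$policy,
                         stage_map = config$stage_map,
                         index_codes = config$index_codes),
    error = function(e) stop("[coding] ", conditionMessage(e), call. = FALSE))
  fc <- records$filter_counts
  multi <- sum(records$patients$n_comorbidities >= config$min_categories)
  log_lines <- c(log_lines,
    sprintf("rows in: %d | patients in: %d | retained after exclusions: %d | multimorbidity cohort (>=%d categories): %d",
            fc[["diagnosis_rows_in"]], fc[["patients_in"]],
            fc[["patients_retained"]], config$min_categories, multi))

  # --- overall mining -------------------------------------------------
  tset <- tryCatch(
    build_transactions(records, "patient",
                       min_categories = config$min_categories),
    error = function(e) stop("[transactions] ", conditionMessage(e),
                             call. = FALSE))
  frequent <- mine_frequent(tset, config$mining)
  rules <- generate_rules(frequent, config$mining)
  write_frequent_csv(frequent[frequent$length >= 2L, ],
                     file.path(config$output_dir, "frequent_itemsets.csv"))
  write_rules_csv(rank_rules(rules, "lift"),
                  file.path(config$output_dir, "rules.csv"))
  write_transactions_csv(tset,
                         file.path(config$output_dir, "transactions.csv"))

  # --- per-period mining and comparison -------------------------------
  period_tsets <- split_transactions_by_period(records, config$periods,
                                               config$min_categories)
  period_tsets <- Filter(Negate(is.null), period_tsets)
  period_rules <- lapply(period_tsets, function(ts) {
    generate_rules(mine_frequent(ts, config$mining), config$mining)
  })
  for (p in names(period_rules)) {
    write_rules_csv(rank_rules(period_rules[[p]], "lift"),
                    file.path(config$output_dir,
                              sprintf("rules_%s.csv", gsub("[^0-9A-Za-z]+", "_", p))))
  }
  jac <- if (length(period_rules) >= 2L)
    jaccard_matrix(period_rules, config$top_k_patterns) else NULL
  if (!is.null(jac))
    write_csv_strict(jac, file.path(config$output_dir, "jaccard.csv"))

  # --- networks -------------------------------------------------------
  networks <- list()
  edges_all <- cooccurrence_edges(tset)
  networks[["overall"]] <- build_network(edges_all, config$network_policy)
  for (p in names(period_tsets)) {
    networks[[p]] <- build_network(cooccurrence_edges(period_tsets[[p]]),
                                   config$period_network_policy)
  }
  summaries <- do.call(rbind, lapply(names(networks), function(nm) {
    cbind(data.frame(network = nm, stringsAsFactors = FALSE),
          networks[[nm]]$summary)
  }))
  write_csv_strict(summaries,
                   file.path(config$output_dir, "network_summaries.csv"))
  for (nm in names(networks)) {
    safe <- gsub("[^0-9A-Za-z]+", "_", nm)
    export_network(networks[[nm]],
                   file.path(config$output_dir,
                             sprintf("network_%s.gexf", safe)), "gexf")
    export_network(networks[[nm]],
                   file.path(config$output_dir,
                             sprintf("network_%s.csv", safe)), "edge_csv")
  }

  # --- statistics -----------------------------------------------------
  cohort <- records$patients[records$patients$n_comorbidities >=
                               config$min_categories, ]
  dist <- summarize_distribution(cohort$n_comorbidities)
  write_csv_strict(data.frame(n = dist$n, median = dist$median,
                              p25 = dist$p25, p75 = dist$p75,
                              min = dist$min, max = dist$max),
                   file.path(config$output_dir,
                             "comorbidity_distribution.csv"))
  ks <- suppressWarnings(stats::ks.test(cohort$n_comorbidities, "pnorm",
                                        mean(cohort$n_comorbidities),
                                        stats::sd(cohort$n_comorbidities)))
  log_lines <- c(log_lines,
                 sprintf("normality check (Kolmogorov-Smirnov): D = %.4f, p = %.3g",
                         unname(ks$statistic), ks$p.value))

  period_of <- assign_period(records, config$periods, "first_admission")
  cohort$period <- period_of[cohort$patient_id]
  tests <- list(
    gender = mann_whitney_u(cohort$n_comorbidities[cohort$gender == "male"],
                            cohort$n_comorbidities[cohort$gender == "female"]),
    residence = mann_whitney_u(
      cohort$n_comorbidities[cohort$residence == "rural"],
      cohort$n_comorbidities[cohort$residence == "urban"]),
    period = kruskal_wallis_dunn(split(cohort$n_comorbidities,
                                       cohort$period)))
  subgroup <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(comparison = nm, test = t$test_name,
               statistic = t$statistic, p_value = t$p_value,
               effect_size = if (is.null(t$effect_size)) NA_real_
                             else t$effect_size,
               stringsAsFactors = FALSE)
  }))
  write_csv_strict(subgroup,
                   file.path(config$output_dir, "subgroup_comparisons.csv"))
  write_csv_strict(tests$period$pairwise,
                   file.path(config$output_dir, "period_dunn_posthoc.csv"))
  stage_tab <- as.data.frame(table(factor(cohort$who_stage, levels = 1:4)),
                             stringsAsFactors = FALSE)
  names(stage_tab) <- c("who_stage", "n_patients")
  stage_tab$percent <- 100 * stage_tab$n_patients / sum(stage_tab$n_patients)
  write_csv_strict(stage_tab, file.path(config$output_dir, "who_stage.csv"))

  log_lines <- c(log_lines,
                 sprintf("frequent itemsets (size>=2): %d | rules: %d",
                         sum(frequent$length >= 2L), nrow(rules$rules)),
                 sprintf("networks: %s",
                         paste(sprintf("%s(%d nodes)", names(networks),
                                       vapply(networks, function(x)
                                         x$summary$n_nodes, numeric(1))),
                               collapse = ", ")))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))

  invisible(list(records = records, transactions = tset,
                 frequent = frequent, rules = rules,
                 period_rules = period_rules, jaccard = jac,
                 networks = networks, summaries = summaries,
                 distribution = dist, subgroup_tests = tests))
}
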