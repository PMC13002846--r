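# comorbnet

Comorbidity-pattern mining and disease co-occurrence networks for
inpatient ICD-10 diagnosis data.

Hospitalised patients with a chronic index disease (the motivating case is
HIV under long-term antiretroviral therapy) typically carry many coexisting
conditions. Given one row per patient–admission–diagnosis, `comorbnet`
answers three questions a clinical epidemiologist asks of such records:

- **Which disease combinations are frequent, and how strong are their
  associations?** Raw codes are aggregated to 3-character ICD-10
  categories (`B20.7 → B20`), non-comorbidity chapters (mental disorders,
  injuries/external causes, congenital disease) are excluded, and a
  from-scratch Apriori miner extracts frequent 2–4 disease itemsets and
  association rules `X → Y` with the five standard metrics
  (support `s`, confidence `s(X∪Y)/s(X)`, lift `s(X∪Y)/(s(X)s(Y))`,
  leverage `s(X∪Y) − s(X)s(Y)`, conviction `(1−s(Y))/(1−conf)`), at the
  usual thresholds (support ≥ 0.20, confidence ≥ 0.20, lift ≥ 1, length ≤ 4).
- **How do the patterns evolve over admission periods?** Patients are
  stratified by first admission year, each period is mined separately, and
  periods are compared by the Jaccard similarity of their top-20
  support-ranked orientation-free patterns.
- **Which diseases are hubs?** Weighted co-occurrence networks (edge
  weight = number of patients carrying both diseases) are built under a
  top-k-edges policy or a 24–34-node budget, with degree, weighted degree,
  normalised betweenness centrality, density and clustering summaries,
  exported as Gephi-compatible GEXF/GraphML/CSV.

Descriptive statistics (median with P25/P75), Mann–Whitney U,
Kruskal–Wallis with ε² effect size and Dunn–Holm post-hoc comparisons, and
a WHO clinical-stage proxy for advanced HIV disease round out the pipeline.

Because hospital EHR data cannot be shipped, the package includes a
noisy-OR latent-block synthetic cohort generator with closed-form itemset
expectations (`study_cohort_spec()`, `generate_cohort()`,
`expected_support()`), so the whole pipeline is validated against known
ground truth. See `vignettes/comorbidity-mining.Rmd` for the model and the
design decisions.

## Worked example

```r
library(comorbnet)

cohort <- generate_cohort(study_cohort_spec(n_patients = 3000, seed = 20190101))
write_cohort_csv(cohort, "cohort.csv")

res <- run_pipeline(pipeline_config("cohort.csv", "out", seed = 1))
res$networks$overall
#> comorbidity_network: 24 nodes, 45 edges, density 0.163, avg weighted degree 2726.8, avg clustering 0.369

head(res$frequent[res$frequent$length == 2, c("key", "support")], 3)
#>        key   support
#> 11 B20+E87 0.5993986
#> 12 E46+E87 0.5766789
#> 13 B37+E87 0.5549616

rank_rules(res$rules, "lift", 2)[, c("antecedent_key", "consequent_key",
                                     "confidence", "lift")]
#>   antecedent_key consequent_key confidence   lift
#> 1        B20+B37            B99  0.4412568 1.3102
#> 2            B99        B20+B37  0.6408730 1.3102

res$jaccard
#>    period_a  period_b  k   jaccard n_shared
#> 1 2019-2020 2021-2022 20 0.6666667       16
#> 2 2019-2020 2023-2024 20 0.7391304       17
#> 3 2021-2022 2023-2024 20 0.9047619       19
```

Reading the output: electrolyte disorders (E87) pair with the HIV-related
infection and nutritional hubs (B20, E46, B37) in more than half of the
multimorbidity cohort; the strongest rule links the infection pair
B20 + B37 with bacterial infection B99 (lift ≈ 1.3, i.e. ~30% more often
than independence would predict); and the high cross-period Jaccard values
say the synthetic generator plants the same block structure in every
period — on real data these values quantify pattern turnover. The same
steps, with narrated output and tables written under `results/`, are the
numbered scripts in `analysis/` (run them in order:
`Rscript analysis/01_simulate_cohort.R` … `05_subgroup_stats.R`).

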