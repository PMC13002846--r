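Package: comorbnet
Title: Comorbidity Pattern Mining and Co-Occurrence Networks for Inpatient
    Diagnosis Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing comorbidity patterns in inpatient
    ICD-10 diagnosis records: aggregation of raw codes to 3-character
    categories with configurable exclusion rules, from-scratch Apriori
    frequent-itemset and association-rule mining with support, confidence,
    lift, leverage and conviction, period-stratified rule comparison via
    Jaccard similarity of canonical comorbidity patterns, weighted disease
    co-occurrence networks with centrality and network-level summaries, and
    nonparametric group comparisons (Mann-Whitney U, Kruskal-Wallis with
    Dunn-Holm post-hoc and epsilon-squared effect size). Includes a
    noisy-OR latent-block synthetic cohort generator with closed-form
    itemset expectations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
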