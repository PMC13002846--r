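---
title: "Mining comorbidity patterns and co-occurrence networks from inpatient diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining comorbidity patterns and co-occurrence networks from inpatient diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem

Inpatient populations with a chronic index disease — the motivating case is
HIV under long-term antiretroviral therapy — accumulate many coexisting
conditions. Their discharge diagnoses form a high-dimensional, sparse,
multi-disease record: one patient may carry ten or more aggregated ICD-10
categories, and the clinically interesting structure lies in which
conditions co-occur, how strongly, and how those combinations shift over
admission periods. `comorbnet` implements the full analysis chain for such
data:

1. **Coding**: raw ICD-10 codes are aggregated to their 3-character core
   (first letter plus two digits), and chapters that cannot be treated as
   comorbidities (mental disorders F, injuries/external causes S, T, V–Y,
   congenital Q) are excluded.
2. **Association rule mining**: Apriori over per-patient transactions with
   support, confidence, lift, leverage and conviction.
3. **Temporal comparison**: period-stratified mining plus Jaccard
   similarity of top-ranked orientation-free patterns.
4. **Networks**: weighted disease co-occurrence graphs with degree,
   weighted degree, betweenness and graph-level summaries.
5. **Statistics**: median/IQR burden summaries, Mann–Whitney U,
   Kruskal–Wallis with Dunn–Holm post-hoc and the ε² effect size.

Because real hospital EHR data cannot be redistributed, the package ships a
synthetic cohort generator whose statistical structure mirrors such a
cohort and whose ground truth is available in closed form; everything
downstream is validated against it.

## Transactions and the mining model

The analysis unit is the patient: one *transaction* per patient, the union
of aggregated categories over all admissions. This matches how comorbidity
burden is reported clinically (one count per patient) and keeps repeat
admissions from double-counting a stable diagnosis. Admission-level
transactions remain available via `build_transactions(..., "admission")`
for sensitivity analyses. Analyses of comorbidity *patterns* are restricted
to the multimorbidity cohort — patients with at least two retained
categories (`min_categories = 2`) — and supports are fractions of that
cohort's transaction count.

For an itemset $Z$ with support $s(Z)$ and a rule $X \to Y$:

$$\mathrm{conf} = \frac{s(X \cup Y)}{s(X)}, \quad
\mathrm{lift} = \frac{s(X \cup Y)}{s(X)\,s(Y)}, \quad
\mathrm{lev} = s(X \cup Y) - s(X)s(Y), \quad
\mathrm{conv} = \frac{1 - s(Y)}{1 - \mathrm{conf}}.$$

Conviction has a pole at confidence 1; it is reported as `Inf` and
serialised as `"inf"`. Both rule directions are emitted — published
comorbidity tables list $X \to Y$ and $Y \to X$ as separate rows because
confidence and conviction differ — and the orientation-free merge happens
only where patterns are compared across periods.

### Thresholds

The default `mining_config()` is support ≥ 0.20, confidence ≥ 0.20,
lift ≥ 1.0, itemset length ≤ 4. A 20% support floor keeps only
combinations common enough to generalise; the low confidence floor keeps
exploratory rules; lift ≥ 1 excludes negative associations (lift = 1 is
statistical independence); and the length cap keeps patterns clinically
interpretable while preventing rule explosion in ~600-category data. All
four are ordinary arguments.

### Correctness strategy

`mine_frequent()` is a from-scratch level-wise Apriori (prefix-join
candidate generation, downward-closure pruning, transaction-id-intersection
counting). Its independent check is `brute_force_frequent()`, a direct
subset-enumeration oracle (guarded to ≤ 20 items); the test suite asserts
exact equality of itemsets, counts and ordering on 100 random transaction
sets per run, plus the downward-closure invariant and the algebraic
identities linking the five metrics (to 1e-12, including
leverage > 0 ⟺ lift > 1 and the symmetry of support, lift and leverage
under direction reversal).

## Temporal comparison

Patients are stratified by *first* admission year into the configured
periods (default 2019–2020, 2021–2022, 2023–2024), so each patient
contributes to exactly one period and per-period transaction counts sum to
the cohort size. Within each period the same mining configuration runs on
that period's transactions only. For comparison, rules are ranked by
support, canonicalised (`X -> Y` and `Y -> X` collapse to one unordered
pattern; each side sorted; sides ordered lexicographically), deduplicated
in rank order, cut to the top *k* = 20 *patterns* (not raw rules — keeping
both directions would waste half the list on mirror images), and two
periods are compared by the Jaccard index of those pattern sets. A
comparison of two empty pattern sets is rejected rather than reported as 0,
since the ratio is undefined.

## Co-occurrence networks

Edges connect unordered category pairs with weight equal to the number of
transactions containing both — identical, by construction, to the pair
itemset count from the miner on the same transactions (the tests assert
this cross-module identity). Two edge-selection policies are implemented:

- `top_k_edges` (default k = 20): the per-period networks.
- `node_budget` (defaults 24–34 nodes): edges are added in descending
  weight order (ties broken by lexicographic pair, making the result
  deterministic) until the node count first reaches the minimum; any edge
  that would push the count past the maximum is skipped and the scan
  continues. This realises "add high-weight edges until the network holds
  roughly 24–34 disease nodes" as a reproducible rule.

Node metrics are degree, weighted degree (sum of incident weights) and
betweenness centrality. Betweenness is computed on the *unweighted*
topology of the retained graph and normalised by $(n-1)(n-2)/2$, so values
lie in $[0,1]$; no weighted-geodesic scheme is used because none is
standard for co-occurrence networks and published hub betweenness values
lie in the unit interval. Networks with fewer than 3 nodes get all-zero
betweenness (the normaliser degenerates). The shortest-path computation is
delegated to igraph's Brandes implementation behind
`betweenness_centrality()`; its independent check in the tests is an
exhaustive shortest-path *enumeration* oracle (BFS predecessor walks,
fractional credit per geodesic) on 50 random graphs per run. Graph-level
summaries are node/edge counts, density $2E/(N(N-1))$, mean weighted
degree, and the mean unweighted local clustering coefficient with
degree-< 2 nodes contributing 0. Export formats are GEXF (Gephi), GraphML
and edge CSV, with import round-trip tests.

## Statistics

Comorbidity counts are summarised as median (P25, P75) using linear
interpolation (R's quantile type 7); the convention is stated in the run
log because published tables rarely say which one they used. Group
comparisons are nonparametric: Mann–Whitney U for binary subgroups
(midranks, tie-corrected normal approximation with continuity correction,
smaller-U reporting; cross-checked against `stats::wilcox.test`), and
Kruskal–Wallis (via `stats::kruskal.test`, tie-corrected) for
multi-category subgroups with ε² = H/(N−1), Dunn's pairwise z using the
tie-corrected rank variance, and Holm step-down adjustment via
`stats::p.adjust`. A Kolmogorov–Smirnov normality check is reported in the
pipeline log only; it gates nothing downstream. One published table pairs a
4-stratum length-of-stay comparison with a statistic of ambiguous family;
this pipeline always reports Kruskal–Wallis for ≥ 3 groups.

## The synthetic cohort generator

`generate_cohort()` draws from a noisy-OR latent-block model. Patient $t$
joins block $b$ with probability $\pi_b$; given memberships $z$, category
$i$ is present with probability

$$P(i \mid z) = 1 - (1 - p_i) \prod_{b:\, z_b = 1} (1 - q_{b,i}),$$

with background prevalence $p_i$. This model was chosen because it plants
controllable positive pairwise *and* higher-order associations while
keeping 1- and 2-item expectations in closed form
(`expected_support()`, `planted_truth()`): absence indicators factorise
over blocks, so

$$P(i \wedge j) = 1 - E[A_i] - E[A_j] + (1-p_i)(1-p_j)
\prod_b \big(1 - \pi_b + \pi_b (1-q_{b,i})(1-q_{b,j})\big).$$

The tests exploit this: empirical supports at n = 10,000 must sit within
0.02 of the closed forms, every planted positive pair must show empirical
lift > 1, and a calibrated 3,000-patient cohort must deliver its planted
pairs through the whole mining pipeline within ±0.03 of expectation.

`study_cohort_spec()` is the calibrated default emulating the study
conditions: 3,000 patients; 25 hub categories whose marginals are solved
(via `calibrate_background()`) to match a published top-25 prevalence
profile (E87 ≈ 86%, B20 ≈ 70%, B37 ≈ 66%, E46 ≈ 63%, …); an
opportunistic-infection block, a metabolic–nutritional block and a
pneumonia–metabolic block planting the hub associations; a 14-category
hospitalization-burden block (π = 0.35, q = 0.45, every member's marginal
held below the 0.20 support floor) that widens and right-skews the
per-patient count distribution the way severe admissions bundle
mid-prevalence conditions; and a ~575-category geometric-decay tail of
rare codes. The resulting per-patient category count has median ≈ 9 and
IQR ≈ 6–12, right-skewed, with > 99.5% of patients multimorbid — the
shape such inpatient cohorts report. Admission periods mix at
0.366/0.378/0.255 matching published yearly admission proportions;
admission counts are shifted-geometric with mean ≈ 2.1; length of stay is
rounded lognormal (mean 10.9, SD 6.5 days); demographics (72.7% male,
78.7% rural, the published age-band mix) are independent of the disease
process, because the motivating cohort found no demographic effect on
comorbidity counts. Where the underlying publication gives only summary
statistics, block parameters are this package's calibration choices, fixed
once; they are not paper facts.

What the generator does **not** emulate: real ICD-10 ontology structure in
the tail codes, diagnosis-position semantics, treatment histories,
outcomes, or period-varying disease mixtures (block membership
probabilities are constant across periods, so the synthetic Jaccard
similarities are high by design). Passing tests therefore demonstrate that
the machinery recovers known structure faithfully — not that any specific
clinical finding generalises.

## Numerical and degenerate-input choices

- Table-facing rounding is half-away-from-zero to 2 decimals
  (`round_half_up()`), the convention of clinical tables; recomputing
  confidence and leverage from published 2-dp supports reproduces
  published 2-dp values only for rows where the authors' unrounded inputs
  survive rounding, and the packaged reference rows
  (`inst/extdata/rule_anchor_rows.csv`) are exactly those.
- `min_support = 0` is rejected (it would enumerate all subsets);
  the brute-force oracle refuses universes above 20 items.
- Empty transaction sets, empty groups, empty edge lists, years outside
  every period, malformed ICD codes, and stage maps outside {2,3,4} are
  rejected with messages naming the offending value; pipeline failures are
  labelled with the stage that raised them.
- WHO staging is a maximum over a configurable category→stage CSV map
  (default packaged, derived from WHO clinical staging guidance at the
  3-character level); patients with no stage-defining category are stage 1,
  which means "no documented stage 3/4 condition", not "early infection".
- All randomness flows from the single generator seed through an
  RNG-stream-preserving wrapper; the analysis path is seed-free, so
  pipeline runs are byte-identical given the same input and configuration.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
calibrated 3,000-patient cohort (~600 categories); module tests use
10,000-patient cohorts where closed-form convergence is asserted and
5–30-transaction sets for the oracle-equivalence sweeps; the betweenness
oracle runs on graphs of up to 8 nodes, where exhaustive path enumeration
is exact and fast. These sizes were chosen so every validation is
comfortably exact and the full suite stays quick on a laptop.

## Known limitations

- Rule mining reports descriptive co-occurrence structure; no
  significance testing or multiplicity control is applied to rules (only
  to the Dunn post-hoc family), matching standard practice in exploratory
  comorbidity mining.
- The node-budget stopping rule is one reproducible reading of
  "progressively add edges until ~24–34 nodes"; other readings (e.g.
  stopping before rather than after the threshold edge) yield slightly
  different networks.
- Betweenness ignores edge weights; hub rankings on weight-dominated
  networks should lean on weighted degree.
- The generator's closed forms cover itemsets of size ≤ 2; planted
  higher-order structure is validated empirically, not analytically.
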