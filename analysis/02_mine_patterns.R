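#!/usr/bin/env Rscript
# Step 2 — frequent comorbidity itemsets and association rules, overall.
#
# Consolidates the diagnosis rows (3-character aggregation, chapter
# exclusions), restricts to the multimorbidity cohort (>= 2 retained
# conditions), and mines it at the standard thresholds (support 0.20,
# confidence 0.20, lift 1.0, itemsets of 2-4 diseases).

library(comorbnet)

records <- consolidate_patients(read_diagnoses("results/cohort.csv"))
tset <- build_transactions(records, "patient", min_categories = 2L)
message(sprintf("multimorbidity cohort: %d of %d patients", tset$n,
                nrow(records$patients)))

cfg <- mining_config()
frequent <- mine_frequent(tset, cfg)
rules <- generate_rules(frequent, cfg)

write_frequent_csv(frequent[frequent$length >= 2, ],
                   "results/frequent_itemsets.csv")
write_rules_csv(rank_rules(rules, "lift"), "results/rules.csv")

pairs <- frequent[frequent$length == 2, ]
message(sprintf("frequent itemsets of size 2-4: %d | rules kept: %d",
                sum(frequent$length >= 2), nrow(rules$rules)))
message("top 3 disease pairs by support:")
for (r in utils::head(seq_len(nrow(pairs)), 3)) {
  message(sprintf("  %s  support %.2f", pairs$key[r],
                  round_half_up(pairs$support[r])))
}
top <- rank_rules(rules, "lift", 2)
message("top 2 rules by lift:")
for (r in seq_len(nrow(top))) {
  message(sprintf("  (%s) -> (%s)  conf %.2f lift %.2f", top$antecedent_key[r],
                  top$consequent_key[r], top$confidence[r], top$lift[r]))
}
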