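# Apriori mining, the brute-force oracle, rule metrics and ranking.

test_that("mine_frequent reproduces the hand-enumerated toy example", {
  ts <- transaction_set(list(c("A", "B", "C"), c("A", "B"),
                             c("A", "C"), c("B", "C")))
  f <- mine_frequent(ts, mining_config(0.5, max_len = 3))
  expect_equal(nrow(f), 6)
  expect_equal(f$key, c("A", "B", "C", "A+B", "A+C", "B+C"))
  expect_equal(f$support, c(0.75, 0.75, 0.75, 0.5, 0.5, 0.5))
  expect_false("A+B+C" %in% f$key)  # 0.25 < 0.5
  # min_support 1.0: no item in every transaction
  expect_equal(nrow(mine_frequent(ts, mining_config(1.0))), 0)
  expect_error(mining_config(0), "min_support")
})

test_that("brute force handles degenerate inputs and guards its universe", {
  expect_equal(brute_force_frequent(transaction_set(list("A")),
                                    mining_config(0.5))$support, 1)
  big <- transaction_set(list(paste0(LETTERS[1:21], "x")))
  expect_error(brute_force_frequent(big, mining_config(0.5)), "guard")
  expect_error(transaction_set(list()), "non-empty")
})

test_that("Apriori equals brute-force enumeration on random instances", {
  set.seed(2024)
  for (i in 1:100) {
    ts <- random_transaction_set(n_tx = sample(5:30, 1), max_items = 8)
    cfg <- mining_config(stats::runif(1, 0.1, 0.6),
                         max_len = sample(2:4, 1))
    a <- mine_frequent(ts, cfg)
    b <- brute_force_frequent(ts, cfg)
    expect_identical(a$key, b$key)
    expect_identical(a$count, b$count)
    expect_equal(a$support, b$support)
  }
})

test_that("downward closure holds for every mined itemset", {
  set.seed(7)
  for (i in 1:30) {
    ts <- random_transaction_set(n_tx = sample(10:30, 1))
    f <- mine_frequent(ts, mining_config(0.2))
    sup <- stats::setNames(f$support, f$key)
    for (r in which(f$length >= 2)) {
      z <- f$items[[r]]
      for (d in seq_along(z)) {
        sub_key <- paste(sort(z[-d]), collapse = "+")
        expect_true(sub_key %in% names(sup))
        expect_gte(sup[[sub_key]], f$support[r])
      }
    }
  }
})

test_that("rule metrics match definitions and the printed worked example", {
  m <- rule_metrics(0.22, 0.34, 0.40)
  expect_equal(round_half_up(m$confidence), 0.65)
  expect_equal(round_half_up(m$leverage), 0.08)
  # independence: lift 1, leverage 0
  m0 <- rule_metrics(0.12, 0.3, 0.4)
  expect_equal(m0$lift, 1)
  expect_equal(m0$leverage, 0)
  # degenerate perfect rule: conviction pole
  m1 <- rule_metrics(1, 1, 1)
  expect_equal(m1$confidence, 1)
  expect_identical(m1$conviction, Inf)
  expect_error(rule_metrics(0.5, 0.4, 0.6), "inconsistent")
})

test_that("generate_rules emits both directions and filters by lift", {
  ts <- transaction_set(list(c("A", "B", "C"), c("A", "B"),
                             c("A", "C"), c("B", "C")))
  f <- mine_frequent(ts, mining_config(0.5, max_len = 3))
  rs <- generate_rules(f, mining_config(0.5, min_confidence = 0.2,
                                        min_lift = 1.0, max_len = 3))
  expect_equal(nrow(rs$rules), 0)  # all pair lifts are 0.5/(0.75^2) < 1
  # perfect co-occurrence: both directions, confidence 1, lift 2
  ts2 <- transaction_set(list(c("A", "B"), c("A", "B"), "C", "C"))
  f2 <- mine_frequent(ts2, mining_config(0.4))
  rs2 <- generate_rules(f2, mining_config(0.4))
  expect_equal(nrow(rs2$rules), 2)
  expect_setequal(rs2$rules$antecedent_key, c("A", "B"))
  expect_equal(rs2$rules$confidence, c(1, 1))
  expect_equal(rs2$rules$lift, c(2, 2))
  expect_identical(rs2$rules$conviction, c(Inf, Inf))
})

test_that("a 3-itemset yields all 6 bipartition rules when thresholds allow", {
  ts <- transaction_set(rep(list(c("A", "B", "C")), 3))
  f <- mine_frequent(ts, mining_config(0.5, max_len = 3))
  rs <- generate_rules(f, mining_config(0.5, min_confidence = 0.01,
                                        min_lift = 0, max_len = 3))
  from_abc <- rs$rules[lengths(rs$rules$antecedent) +
                         lengths(rs$rules$consequent) == 3, ]
  expect_equal(nrow(from_abc), 6)  # 2^3 - 2 bipartitions
})

test_that("metric identities hold on every mined rule", {
  set.seed(99)
  for (i in 1:20) {
    ts <- random_transaction_set(n_tx = sample(10:30, 1))
    rs <- generate_rules(mine_frequent(ts, mining_config(0.15)),
                         mining_config(0.15, min_confidence = 0.01,
                                       min_lift = 0))
    r <- rs$rules
    if (nrow(r) == 0) next
    expect_equal(r$lift, r$confidence / r$support_consequent,
                 tolerance = 1e-12)
    expect_equal(r$leverage, r$support -
                   r$support_antecedent * r$support_consequent,
                 tolerance = 1e-12)
    fin <- is.finite(r$conviction)
    expect_equal(r$conviction[fin],
                 (1 - r$support_consequent[fin]) / (1 - r$confidence[fin]),
                 tolerance = 1e-12)
    expect_identical(r$leverage > 1e-15, r$lift > 1 + 1e-12)
    # symmetry of lift/leverage/support across rule directions
    key_f <- paste(r$antecedent_key, r$consequent_key, sep = ">")
    key_r <- paste(r$consequent_key, r$antecedent_key, sep = ">")
    mirrored <- match(key_r, key_f)
    ok <- !is.na(mirrored)
    expect_equal(r$lift[ok], r$lift[mirrored[ok]])
    expect_equal(r$leverage[ok], r$leverage[mirrored[ok]])
    expect_equal(r$support[ok], r$support[mirrored[ok]])
  }
})

test_that("rank_rules sorts with deterministic tie-breaks and caps at k", {
  ts <- transaction_set(list(c("A", "B"), c("A", "B"), c("C", "D"),
                             c("C", "D"), c("A", "B", "C", "D")))
  rs <- generate_rules(mine_frequent(ts, mining_config(0.3)),
                       mining_config(0.3, min_confidence = 0.01, min_lift = 0))
  top <- rank_rules(rs, "lift", 1)
  expect_equal(nrow(top), 1)
  expect_gte(top$lift, max(rs$rules$lift) - 1e-12)
  all_r <- rank_rules(rs, "support", 10000)
  expect_equal(nrow(all_r), nrow(rs$rules))  # no padding
  # ties broken lexicographically by antecedent then consequent
  sup <- rank_rules(rs, "support")
  tie <- sup[sup$support == sup$support[1] & sup$lift == sup$lift[1], ]
  if (nrow(tie) > 1) {
    expect_true(!is.unsorted(paste(tie$antecedent_key, tie$consequent_key)))
  }
  expect_error(rank_rules(rs, "bogus"), "arg")
})

test_that("frequent itemsets and rules round-trip through their CSVs", {
  ts <- transaction_set(list(c("A", "B"), c("A", "B"), c("B", "C")))
  f <- mine_frequent(ts, mining_config(0.3))
  rs <- generate_rules(f, mining_config(0.3, min_confidence = 0.01,
                                        min_lift = 0))
  fp <- tempfile(fileext = ".csv"); rp <- tempfile(fileext = ".csv")
  write_frequent_csv(f, fp); write_rules_csv(rs, rp)
  fread <- utils::read.csv(fp, stringsAsFactors = FALSE)
  expect_equal(fread$items, f$key)
  expect_equal(fread$support, f$support)
  rread <- utils::read.csv(rp, stringsAsFactors = FALSE)
  expect_equal(nrow(rread), nrow(rs$rules))
  expect_true(all(c("support_by_antecedent", "conviction") %in% names(rread)))
})
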