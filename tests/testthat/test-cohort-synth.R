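# Noisy-OR synthetic cohort generator: closed-form expectations,
# reproducibility, planted-truth recovery.

test_that("expected_support matches hand-derived closed forms", {
  # independent items: product of background prevalences
  s0 <- cohort_spec(10, c(X = 0.3, Y = 0.4), seed = 1)
  expect_equal(expected_support(s0, "X"), 0.3)
  expect_equal(expected_support(s0, c("X", "Y")), 0.12)
  # single block pi = 0.5, q = 1, zero background: P(X & Y) = pi
  s1 <- cohort_spec(10, c(X = 0, Y = 0),
                    blocks = list(comorbidity_block("b", 0.5, c(X = 1, Y = 1))),
                    seed = 1)
  expect_equal(expected_support(s1, "X"), 0.5)
  expect_equal(expected_support(s1, c("X", "Y")), 0.5)
  # general single-block formula: pi [1-(1-p)(1-q)]^2 + (1-pi) p^2
  s2 <- cohort_spec(10, c(X = 0.2, Y = 0.2),
                    blocks = list(comorbidity_block("b", 0.4,
                                                    c(X = 0.7, Y = 0.7))),
                    seed = 1)
  manual <- 0.4 * (1 - 0.8 * 0.3)^2 + 0.6 * 0.04
  expect_equal(expected_support(s2, c("X", "Y")), manual)
  expect_error(expected_support(s0, "Z"), "universe")
  expect_error(expected_support(s0, c("X", "Y", "X")), "1 or 2")
})

test_that("invalid probabilities are rejected naming the offending field", {
  expect_error(comorbidity_block("b", 1.5, c(X = 0.5)), "membership_prob")
  expect_error(comorbidity_block("b", 0.5, c(X = -0.1)), "item_probs")
  expect_error(cohort_spec(10, c(X = 1.2)), "background_prevalence")
  expect_error(cohort_spec(10, c(X = 0.5),
                           period_weights = c("2019" = 0.4, "2020" = 0.4)),
               "sum to 1")
  expect_error(
    cohort_spec(10, c(X = 0.5),
                blocks = list(comorbidity_block("b", 0.5, c(Z = 1)))),
    "outside the")
})

test_that("generation is reproducible and independence yields lift near 1", {
  spec <- cohort_spec(10000, c(X = 0.5, Y = 0.5), seed = 11)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$diagnoses, co2$diagnoses)
  expect_identical(co1$patients, co2$patients)
  expect_equal(nrow(co1$patients), 10000)
  px <- empirical_support(co1, "X"); py <- empirical_support(co1, "Y")
  pxy <- empirical_support(co1, c("X", "Y"))
  expect_lt(abs(pxy / (px * py) - 1), 0.1)
})

test_that("a deterministic block plants the expected pair and lift 2", {
  spec <- cohort_spec(10000, c(X = 0, Y = 0),
                      blocks = list(comorbidity_block("b", 0.5,
                                                      c(X = 1, Y = 1))),
                      seed = 5)
  co <- generate_cohort(spec)
  px <- empirical_support(co, "X")
  pxy <- empirical_support(co, c("X", "Y"))
  expect_lt(abs(px - 0.5), 0.02)
  expect_equal(px, pxy)  # q = 1: members appear together or not at all
  expect_lt(abs(pxy / px^2 - 2), 0.1)
})

test_that("empirical supports converge to closed-form expectations", {
  spec <- cohort_spec(
    10000, c(A01 = 0.3, B20 = 0.05, B37 = 0.1, E87 = 0.25),
    blocks = list(comorbidity_block("inf", 0.45, c(B20 = 0.9, B37 = 0.7)),
                  comorbidity_block("met", 0.3, c(E87 = 0.6, A01 = 0.4))),
    seed = 17)
  co <- generate_cohort(spec)
  truth <- planted_truth(spec)
  for (it in names(truth$marginal_supports)) {
    expect_lt(abs(empirical_support(co, it) - truth$marginal_supports[[it]]),
              0.02)
  }
  for (r in seq_len(nrow(truth$pair_supports))) {
    pr <- truth$pair_supports[r, ]
    expect_lt(abs(empirical_support(co, c(pr$item_a, pr$item_b)) -
                    pr$expected_support), 0.02)
  }
  # every planted positive pair shows empirical lift > 1
  for (r in seq_len(nrow(truth$positive_pairs))) {
    a <- truth$positive_pairs$item_a[r]; b <- truth$positive_pairs$item_b[r]
    lift <- empirical_support(co, c(a, b)) /
      (empirical_support(co, a) * empirical_support(co, b))
    expect_gt(lift, 1)
  }
})

test_that("planted_truth enumerates the universe and flags block pairs only", {
  s0 <- cohort_spec(10, c(X = 0.3, Y = 0.4), seed = 1)
  t0 <- planted_truth(s0)
  expect_equal(nrow(t0$positive_pairs), 0)
  expect_setequal(names(t0$marginal_supports), c("X", "Y"))
  s1 <- cohort_spec(10, c(X = 0, Y = 0),
                    blocks = list(comorbidity_block("b", 0.5, c(X = 1, Y = 1))),
                    seed = 1)
  t1 <- planted_truth(s1)
  expect_equal(nrow(t1$positive_pairs), 1)  # 0.5 > 0.25
  expect_setequal(c(t1$positive_pairs$item_a, t1$positive_pairs$item_b),
                  c("X", "Y"))
})

test_that("study-style cohort has a right-skewed multimorbidity profile", {
  spec <- study_cohort_spec(n_patients = 1500, seed = 303)
  co <- generate_cohort(spec)
  cnt <- lengths(co$categories)
  d <- summarize_distribution(cnt)
  expect_gte(d$median, 7); expect_lte(d$median, 11)
  expect_gt(mean((cnt - mean(cnt))^3) / stats::sd(cnt)^3, 0)  # right skew
  expect_gt(mean(cnt >= 2), 0.95)
  # calibrated marginals track their targets (hub example: E87 ~ 0.856)
  expect_lt(abs(empirical_support(co, "E87") - 0.8557), 0.03)
})

test_that("cohort round-trips through YAML spec and diagnosis CSV", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 50", "seed: 9",
    "background_prevalence: {A01: 0.4, B20: 0.3}",
    "period_weights: {'2019-2020': 0.5, '2021-2022': 0.5}",
    "blocks:",
    "  - block_id: b1", "    membership_prob: 0.5",
    "    item_probs: {A01: 0.8, B20: 0.8}"), yml)
  spec <- read_cohort_spec(yml)
  expect_equal(spec$n_patients, 50L)
  expect_equal(spec$blocks[[1]]$item_probs[["A01"]], 0.8)
  co <- generate_cohort(spec)
  csv <- tempfile(fileext = ".csv")
  write_cohort_csv(co, csv)
  dx <- read_diagnoses(csv)
  expect_true(all(c("patient_id", "icd10_code", "year") %in% names(dx)))
  expect_setequal(unique(dx$icd10_code), c("A01", "B20"))
})
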