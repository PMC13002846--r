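# Period assignment, canonical patterns and Jaccard comparison.

make_dx <- function(patient, admission, year, code) {
  data.frame(patient_id = patient, admission_id = admission, year = year,
             gender = "male", age = 40, residence = "rural", los_days = 5,
             icd10_code = code, stringsAsFactors = FALSE)
}

test_that("period definitions reject overlaps and unknown years", {
  expect_s3_class(period_defs(), "period_defs")
  expect_error(period_defs(c("2019-2021", "2021-2022")), "overlap")
  dx <- rbind(make_dx("p1", "a1", 2019, "B20"),
              make_dx("p1", "a2", 2021, "B37"))
  rec <- consolidate_patients(dx)
  expect_equal(unname(assign_period(rec, period_defs())["p1"]), "2019-2020")
  per_adm <- assign_period(rec, period_defs(), "per_admission")
  expect_setequal(per_adm[["p1"]], c("2019-2020", "2021-2022"))
  dx_bad <- make_dx("p9", "a9", 2018, "B20")
  rec_bad <- consolidate_patients(dx_bad)
  expect_error(assign_period(rec_bad, period_defs()), "2018")
})

test_that("period split partitions patients without leakage", {
  set.seed(10)
  co <- generate_cohort(toy_block_spec(n = 300))
  csv <- tempfile(fileext = ".csv"); write_cohort_csv(co, csv)
  rec <- consolidate_patients(read_diagnoses(csv))
  tsets <- split_transactions_by_period(rec, period_defs())
  tsets <- Filter(Negate(is.null), tsets)
  ids <- unlist(lapply(tsets, function(ts) names(ts$transactions)))
  expect_false(any(duplicated(ids)))
  expect_equal(sum(vapply(tsets, function(ts) ts$n, integer(1))),
               nrow(rec$patients))
})

test_that("canonical patterns merge rule directions and sort sides", {
  p1 <- canonical_pattern("B99", c("B20", "B37"))
  p2 <- canonical_pattern(c("B37", "B20"), "B99")
  expect_identical(p1, p2)
  expect_identical(canonical_pattern(c("C", "A"), "B"), "A+C|B")
  expect_false(identical(canonical_pattern("A", "B"),
                         canonical_pattern("A", "C")))
})

test_that("jaccard_topk covers identity, disjoint and partial overlap", {
  ts1 <- transaction_set(list(c("A", "B"), c("A", "B"), c("C", "D"),
                              c("C", "D")))
  cfg <- mining_config(0.3, min_confidence = 0.01, min_lift = 0)
  rs1 <- generate_rules(mine_frequent(ts1, cfg), cfg)
  expect_equal(jaccard_topk(rs1, rs1, 20)$jaccard, 1)
  ts2 <- transaction_set(list(c("E", "G"), c("E", "G")))
  rs2 <- generate_rules(mine_frequent(ts2, cfg), cfg)
  expect_equal(jaccard_topk(rs1, rs2, 20)$jaccard, 0)
  # {AB, CD} vs {CD, EG}: one shared of three distinct -> 1/3
  ts3 <- transaction_set(list(c("C", "D"), c("C", "D"), c("E", "G"),
                              c("E", "G")))
  rs3 <- generate_rules(mine_frequent(ts3, cfg), cfg)
  cmp <- jaccard_topk(rs1, rs3, 20)
  expect_equal(cmp$jaccard, 1 / 3)
  expect_equal(cmp$shared_patterns, "C|D")
})

test_that("top_patterns deduplicates directions before cutting to k", {
  ts <- transaction_set(list(c("A", "B"), c("A", "B"), c("C", "D"),
                             c("C", "D")))
  cfg <- mining_config(0.3, min_confidence = 0.01, min_lift = 0)
  rs <- generate_rules(mine_frequent(ts, cfg), cfg)
  pats <- top_patterns(rs, 20)
  expect_equal(sort(pats), c("A|B", "C|D"))  # 4 rules, 2 patterns
  expect_length(top_patterns(rs, 1), 1)
})

test_that("jaccard is symmetric and bounded on random rule sets", {
  set.seed(31)
  cfg <- mining_config(0.2, min_confidence = 0.01, min_lift = 0)
  for (i in 1:10) {
    rs_a <- generate_rules(mine_frequent(random_transaction_set(15), cfg), cfg)
    rs_b <- generate_rules(mine_frequent(random_transaction_set(15), cfg), cfg)
    if (nrow(rs_a$rules) == 0 && nrow(rs_b$rules) == 0) next
    j_ab <- jaccard_topk(rs_a, rs_b, 10)$jaccard
    j_ba <- jaccard_topk(rs_b, rs_a, 10)$jaccard
    expect_equal(j_ab, j_ba)
    expect_gte(j_ab, 0); expect_lte(j_ab, 1)
    expect_equal(jaccard_topk(rs_a, rs_a, 10)$jaccard, 1)
  }
})
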