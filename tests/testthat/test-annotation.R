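hits <- tibble::tibble(
  query = c("q1", "q1", "q2", "q3", "q3"),
  target = c("tA", "tB", "tC", "tD", "tE"),
  evalue = c(1e-10, 1e-7, 1e-4, 1e-9, 1e-9),
  bitscore = c(50, 60, 40, 100, 120),
  qcov = 0.5, tcov = 0.5)

test_that("the lowest-E-value hit wins, ties go to higher bitscore", {
  best <- best_hit_per_query(hits)
  expect_equal(best$target[best$query == "q1"], "tA")
  expect_false("q2" %in% best$query)  # above the 1e-5 cutoff
  expect_equal(best$target[best$query == "q3"], "tE")
})

test_that("a hit at exactly the cutoff survives", {
  h <- tibble::tibble(query = "q", target = "t", evalue = 1e-5,
                      bitscore = 10, qcov = 1, tcov = 1)
  expect_equal(nrow(best_hit_per_query(h)), 1)
})

test_that("annotation rates count each source and their union", {
  best <- tibble::tibble(query = c("s1", "s2"), target = c("tA", "tB"),
                         evalue = 1e-10, bitscore = 50)
  eggnog <- tibble::tibble(seq_id = "s3", ortholog = "OG1")
  ann <- merge_annotations(best, eggnog, c("s1", "s2", "s3", "s4"))
  rates <- ann$rates
  expect_equal(rates$pct[rates$source == "swissprot"], 50.0)
  expect_equal(rates$pct[rates$source == "eggnog"], 25.0)
  expect_equal(rates$pct[rates$source == "either"], 75.0)
  expect_equal(ann$table$annotated_by[ann$table$seq_id == "s3"], "eggnog")
  expect_equal(ann$table$annotated_by[ann$table$seq_id == "s4"], "")
})

test_that("the union rate is bounded by the per-source rates", {
  set.seed(9)
  for (i in 1:20) {
    ids <- sprintf("x%02d", 1:30)
    sw <- sample(ids, sample(0:30, 1))
    eg <- sample(ids, sample(0:30, 1))
    best <- tibble::tibble(query = sw, target = "t", evalue = 1e-10,
                           bitscore = 1)
    eggnog <- tibble::tibble(seq_id = eg, ortholog = "OG")
    r <- merge_annotations(best, eggnog, ids)$rates
    either <- r$pct[r$source == "either"]
    expect_gte(either, max(r$pct[r$source != "either"]))
    expect_lte(either, sum(r$pct[r$source != "either"]) + 0.1)
  }
})

test_that("merging is order-independent", {
  best <- tibble::tibble(query = c("s1", "s2"), target = c("tA", "tB"),
                         evalue = 1e-10, bitscore = 50)
  eggnog <- tibble::tibble(seq_id = c("s3", "s1"), ortholog = c("OG1", "OG2"))
  a <- merge_annotations(best, eggnog, c("s1", "s2", "s3"))
  b <- merge_annotations(best[2:1, ], eggnog[2:1, ], c("s1", "s2", "s3"))
  expect_equal(a$table[order(a$table$seq_id), ],
               b$table[order(b$table$seq_id), ])
})

test_that("an empty universe errors, unknown orthology rows warn", {
  best <- tibble::tibble(query = character(), target = character(),
                         evalue = numeric(), bitscore = numeric())
  expect_error(merge_annotations(best, tibble::tibble(seq_id = character()),
                                 character()), "empty")
  expect_warning(
    merge_annotations(best, tibble::tibble(seq_id = "ghost", ortholog = "o"),
                      c("s1")), "ghost")
})
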