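test_that("the reference-ortholog confusion matrix partitions correctly", {
  t2 <- reference_ortholog_table()
  expected <- t2[, c("component", "accession")]
  found <- t2[t2$found == "yes", c("component", "accession")]
  val <- validate_against_references(found, expected)
  g <- glance(val)
  expect_equal(g$false_negatives, 1)
  expect_equal(g$false_positives, 0)
  expect_equal(val$fn$accession, "O08785")
  expect_equal(g$true_positives + g$false_negatives, nrow(expected))
})

test_that("found == expected gives an empty FN and FP set", {
  e <- tibble::tibble(component = c("CLK", "PER"),
                      accession = c("A1", "A2"))
  val <- validate_against_references(e, e)
  expect_equal(nrow(val$fn), 0)
  expect_equal(nrow(val$fp), 0)
  expect_equal(nrow(val$tp), 2)
})

test_that("validation matches direct set arithmetic on random subsets", {
  set.seed(15)
  for (i in 1:30) {
    expected <- tibble::tibble(
      component = sample(clock_components(), 12, TRUE),
      accession = sprintf("ACC%02d", 1:12))
    found <- dplyr::bind_rows(
      expected[sample(12, sample(0:12, 1)), ],
      tibble::tibble(component = "CLK",
                     accession = sprintf("NOV%d", seq_len(sample(0:3, 1)))))
    val <- validate_against_references(found, expected)
    ek <- paste(expected$component, expected$accession)
    fk <- unique(paste(found$component, found$accession))
    expect_equal(nrow(val$tp), sum(ek %in% fk))
    expect_equal(nrow(val$fn), sum(!ek %in% fk))
    expect_equal(nrow(val$fp), sum(!fk %in% ek))
    expect_equal(nrow(val$tp) + nrow(val$fn), nrow(expected))
  }
})

test_that("run comparison reports percentages of the union", {
  mk <- function(n, prefix) tibble::tibble(
    species = "s", seq_id = paste0(prefix, seq_len(n)), component = "CLK")
  shared <- mk(177, "sh")
  a <- dplyr::bind_rows(shared, mk(24, "a"))
  b <- dplyr::bind_rows(shared, mk(34, "b"))
  cmp <- compare_candidate_sets(a, b)
  expect_equal(cmp$n, c(177, 24, 34))
  expect_equal(cmp$pct, c(75.3, 10.2, 14.5))
  expect_lt(abs(sum(cmp$pct) - 100), 0.11)
})

test_that("identical and disjoint candidate sets compare as expected", {
  a <- tibble::tibble(species = "s", seq_id = c("x"), component = "CLK")
  cmp <- compare_candidate_sets(a, a)
  expect_equal(cmp$pct, c(100, 0, 0))
  b <- tibble::tibble(species = "s", seq_id = c("y", "z", "w"),
                      component = "CLK")
  cmp2 <- compare_candidate_sets(a, b)
  expect_equal(cmp2$pct, c(0, 25, 75))
  expect_error(compare_candidate_sets(a[0, ], b[0, ]), "empty")
})

test_that("fallback selection applies the coverage floor and status codes", {
  hits <- tibble::tibble(
    species = c("sp1", "sp1", "sp1", "sp2"),
    component = c("PER", "PER", "PER", "CLK"),
    query = "bait", target = c("t1", "t2", "t3", "t4"),
    evalue = c(1e-30, 1e-50, 1e-80, 1e-10),
    bitscore = c(100, 200, 300, 50),
    qcov = c(0.5, 0.6, 0.15, 0.20),
    tcov = c(0.9, 0.9, 0.9, 0.20))
  already <- tibble::tibble(species = "sp1", component = "CLK")
  avail <- tibble::tibble(species = c("sp1", "sp2", "sp3"),
                          has_data = c(TRUE, TRUE, FALSE))
  res <- select_fallback_hits(hits, already, avail,
                              species = c("sp1", "sp2", "sp3"),
                              components = c("CLK", "PER"))
  # t3 has the best E-value but fails the qcov floor; t2 wins across the
  # two surviving hits for (sp1, PER)
  expect_equal(res$hits$target[res$hits$species == "sp1"], "t2")
  # coverage of exactly 0.20 is retained
  expect_true("t4" %in% res$hits$target)
  st <- setNames(res$status$status,
                 paste(res$status$species, res$status$component))
  expect_equal(unname(st["sp1 CLK"]), "-")
  expect_equal(unname(st["sp1 PER"]), "YES")
  expect_equal(unname(st["sp2 PER"]), "NH")
  expect_equal(unname(st["sp3 CLK"]), "ND")
  expect_equal(unname(st["sp3 PER"]), "ND")
})
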