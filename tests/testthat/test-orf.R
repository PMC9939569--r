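test_that("minimum-length filter keeps records of exactly the threshold", {
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         seq = c(random_dna(199), random_dna(200),
                                 random_dna(350)))
  kept <- filter_min_length(recs)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(nrow(filter_min_length(recs[0, ])), 0)
  expect_equal(filter_min_length(recs, 100), recs)
})

test_that("start present without stop is tagged 3'-partial", {
  o <- find_best_orf("t", "ATGAAAAAAAAA", min_aa = 1)
  expect_equal(o$protein, "MKKK")
  expect_equal(o$completeness, "3p")
  expect_equal(o$strand, "+")
})

test_that("a complete start-to-stop ORF is among the enumerated candidates", {
  cands <- clockfindr:::enumerate_orf_candidates("GGGATGAAATGACCC")
  mk <- cands[cands$protein == "MK", ]
  expect_equal(nrow(mk), 1)
  expect_equal(mk$completeness, "cmp")
  expect_equal(mk$strand, "+")
  expect_equal(c(mk$start, mk$end), c(3, 12))  # stop codon included
})

test_that("codons containing N terminate a span without counting as stop", {
  # ATG AAA NNA AAA: N codon splits the frame; first segment is M K (3p-like
  # but terminated by the N codon, so no stop)
  o <- find_best_orf("t", "ATGAAANNAAAACGTACGAAA", min_aa = 1)
  expect_false(is.null(o))
  expect_false(grepl("X", o$protein))
})

test_that("residues outside the nucleotide alphabet error", {
  expect_error(find_best_orf("t", "ACGTU"), "residues")
})

test_that("best ORF agrees with the exhaustive six-frame oracle", {
  set.seed(101)
  for (i in 1:50) {
    s <- random_dna(300)
    got <- find_best_orf("t", s, min_aa = 1)
    want <- oracle_best_orf(s, min_aa = 1)
    expect_equal(got$protein, want$protein, info = s)
    expect_equal(got$strand, want$strand, info = s)
    expect_equal(got$frame, want$frame, info = s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
    expect_equal(got$completeness, want$completeness, info = s)
  }
})

test_that("ORF coordinates are consistent with the protein length", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(400)
    o <- find_best_orf("t", s, min_aa = 1)
    span <- o$end - o$start
    expect_equal(span %% 3, 0)
    has_stop <- o$completeness %in% c("cmp", "5p")
    expect_equal(nchar(o$protein), span / 3 - as.integer(has_stop))
  }
})

test_that("min_aa suppresses short ORFs", {
  expect_null(find_best_orf("t", "GGGATGAAATGACCC", min_aa = 100))
})
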