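test_that("a fixed seed reproduces the universe and transcripts exactly", {
  cfg <- synth_config(n_species = 2, seed = 42)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1$proteomes, u2$proteomes)
  expect_identical(u1$pair_table, u2$pair_table)
  expect_identical(u1$domain_table, u2$domain_table)
  t1 <- generate_transcripts(u1$proteomes, cfg)
  t2 <- generate_transcripts(u2$proteomes, cfg)
  expect_identical(t1$transcripts, t2$transcripts)
  u3 <- generate_universe(synth_config(n_species = 2, seed = 43))
  expect_false(identical(u1$proteomes$seq, u3$proteomes$seq))
})

test_that("with noise off the pair table equals the planted truth exactly", {
  cfg <- synth_config(n_species = 3, seed = 8)
  uni <- generate_universe(cfg)
  truth <- uni$manifest$orthologs
  expect_setequal(
    paste(uni$pair_table$species_b, uni$pair_table$seq_b),
    paste(truth$species, truth$seq_id))
  expect_equal(nrow(uni$manifest$fn_dropped), 0)
  expect_equal(nrow(uni$manifest$fp_pairs), 0)
  # every pair row maps the tagged bait of the right component
  comp_of <- setNames(uni$registry$component, uni$registry$seq_id)
  expect_equal(unname(comp_of[uni$pair_table$seq_a]),
               truth$component[match(uni$pair_table$seq_b, truth$seq_id)])
})

test_that("a minimal configuration plants exactly the requested orthologs", {
  cfg <- synth_config(n_species = 2, components = "CLK", paralog_rate = 0,
                      fragment_rate = 0, decoy_count = 0,
                      near_duplicate_rate = 0, seed = 3)
  uni <- generate_universe(cfg)
  expect_equal(nrow(uni$manifest$orthologs), 2)
  expect_true(all(uni$manifest$orthologs$completeness == "cmp"))
  expect_equal(nrow(uni$proteomes), 2)
})

test_that("pair-table noise is recorded in the manifest", {
  cfg <- synth_config(n_species = 3, seed = 4, ortholog_fn_rate = 0.3,
                      ortholog_fp_rate = 0.5)
  uni <- generate_universe(cfg)
  truth_k <- paste(uni$manifest$orthologs$species,
                   uni$manifest$orthologs$seq_id)
  pair_k <- paste(uni$pair_table$species_b, uni$pair_table$seq_b)
  fp_k <- paste(uni$manifest$fp_pairs$species_b, uni$manifest$fp_pairs$seq_b)
  fn_k <- paste(uni$manifest$fn_dropped$species_b,
                uni$manifest$fn_dropped$seq_b)
  expect_gt(nrow(uni$manifest$fn_dropped), 0)
  expect_gt(nrow(uni$manifest$fp_pairs), 0)
  # every non-FP pair row is a manifest ortholog; dropped rows are absent
  expect_true(all(setdiff(pair_k, fp_k) %in% truth_k))
  expect_false(any(fn_k %in% pair_k))
  # all FP rows point at decoys
  expect_true(all(uni$manifest$fp_pairs$seq_b %in%
                    uni$manifest$decoys$seq_id))
})

test_that("decoys carry exactly one bait domain in an unrelated family", {
  cfg <- synth_config(n_species = 2, seed = 6)
  uni <- generate_universe(cfg)
  dec <- uni$manifest$decoys
  expect_gt(nrow(dec), 0)
  bait_accs <- unique(uni$domain_table$accession[
    uni$domain_table$seq_id %in% uni$registry$seq_id])
  for (i in seq_len(nrow(dec))) {
    drows <- uni$domain_table[uni$domain_table$seq_id == dec$seq_id[i], ]
    expect_equal(nrow(drows), 1)
    expect_true(drows$accession %in% bait_accs)
    frow <- uni$family_table[uni$family_table$seq_id == dec$seq_id[i], ]
    expect_false(frow$family_acc %in% uni$family_table$family_acc[
      uni$family_table$seq_id %in% uni$registry$seq_id])
  }
})

test_that("back-translation is the fixed-codon expansion", {
  expect_equal(back_translate("MK", "GGG", "CCC"), "GGGATGAAATGACCC")
  expect_equal(back_translate("MK", include_stop = FALSE), "ATGAAA")
  expect_error(back_translate("MZ"), "Z")
})

test_that("near-duplicate transcripts have >= 98% planted identity", {
  cfg <- synth_config(n_species = 2, near_duplicate_rate = 1, seed = 19)
  uni <- generate_universe(cfg)
  tr <- generate_transcripts(uni$proteomes, cfg)
  nd <- tr$near_duplicates
  expect_gt(nrow(nd), 0)
  for (i in seq_len(min(nrow(nd), 10))) {
    a <- tr$transcripts$seq[tr$transcripts$id == nd$original_id[i] &
                              tr$transcripts$species == nd$species[i]]
    b <- tr$transcripts$seq[tr$transcripts$id == nd$duplicate_id[i] &
                              tr$transcripts$species == nd$species[i]]
    st <- pairwise_identity(a, b)
    expect_gte(st$identity, 0.98)
    expect_gte(st$coverage_shorter, 0.98)
    # cross-check with the independent alignment oracle
    ora <- oracle_align(a, b)
    expect_gte(ora$identity, 0.98)
  }
})

test_that("planted completeness tags are re-derived by the ORF classifier", {
  cfg <- synth_config(n_species = 2, fragment_rate = 0.6, seed = 13,
                      isoform_probs = 1, near_duplicate_rate = 0)
  uni <- generate_universe(cfg)
  tr <- generate_transcripts(uni$proteomes, cfg)
  truth <- uni$manifest$orthologs
  for (i in seq_len(nrow(truth))) {
    tseq <- tr$transcripts$seq[
      tr$transcripts$id == truth$transcript_id[i] &
        tr$transcripts$species == truth$species[i]]
    o <- find_best_orf(truth$transcript_id[i], tseq)
    expect_equal(o$completeness, truth$completeness[i],
                 info = paste(truth$species[i], truth$seq_id[i]))
    # and the ORF recovers the planted protein
    planted <- uni$proteomes$seq[uni$proteomes$id == truth$seq_id[i] &
                                   uni$proteomes$species == truth$species[i]]
    expect_equal(o$protein, planted)
  }
})

test_that("read simulation respects the requested defect rates", {
  tr <- tibble::tibble(id = "t", seq = random_dna(800))
  expect_equal(nrow(generate_read_pairs(tr, 0)), 0)
  clean <- generate_read_pairs(tr, 200, seed = 2)
  expect_equal(nrow(filter_read_pairs(clean)$kept), 200)
  noisy <- generate_read_pairs(tr, 1000, frac_n = 0.1, seed = 2)
  kept <- nrow(filter_read_pairs(noisy)$kept)
  # binomial expectation: 900 +- 4 sd (sd ~ 9.5)
  expect_gt(kept, 900 - 38)
  expect_lt(kept, 900 + 38)
})
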