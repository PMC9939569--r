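# A small hand-built universe for the bait/vetting unit tests.
mini_registry_setup <- function() {
  proteome <- tibble::tibble(
    id = c("sp|O61735|CLK_DROME", "sp|A0A212FAM3|CRY2_DANPL",
           "sp|Q00001|OTHER_DROME"),
    desc = "", seq = c(strrep("M", 50), strrep("K", 50), strrep("L", 50)))
  baits <- tibble::tibble(component = c("CLK", "CRY2"),
                          accession = c("O61735", "A0A212FAM3"))
  tag_baits(proteome, baits)
}

test_that("bait tagging appends the marker and builds the registry", {
  tg <- mini_registry_setup()
  expect_true("sp|O61735|CLK_DROME_SOIREF" %in% tg$proteome$id)
  expect_true("sp|Q00001|OTHER_DROME" %in% tg$proteome$id)
  expect_equal(tg$registry$seq_id[tg$registry$component == "CLK"],
               "sp|O61735|CLK_DROME_SOIREF")
})

test_that("missing or ambiguous bait accessions and marker clashes error", {
  proteome <- tibble::tibble(id = c("sp|A|X", "sp|A|Y"), desc = "",
                             seq = c("MM", "KK"))
  expect_error(tag_baits(proteome,
                         tibble::tibble(component = "CLK", accession = "B")),
               "B")
  expect_error(tag_baits(proteome,
                         tibble::tibble(component = "CLK", accession = "A")),
               "multiple")
  p2 <- tibble::tibble(id = "seq_SOIREF_like", desc = "", seq = "MM")
  expect_error(tag_baits(p2, tibble::tibble(component = "CLK",
                                            accession = "seq")),
               "Marker")
})

test_that("pairwise-ortholog extraction handles one-to-many and duplicates", {
  tg <- mini_registry_setup()
  pt <- tibble::tibble(
    species_a = c("reference", "reference", "reference", "spB", "reference"),
    seq_a = c("sp|O61735|CLK_DROME_SOIREF", "sp|A0A212FAM3|CRY2_DANPL_SOIREF",
              "sp|A0A212FAM3|CRY2_DANPL_SOIREF", "s1",
              "sp|O61735|CLK_DROME_SOIREF"),
    species_b = c("spA", "spB", "spB", "reference", "spA"),
    seq_b = c("seq1", "s1", "s2", "sp|A0A212FAM3|CRY2_DANPL_SOIREF", "seq1"))
  raw <- extract_bait_orthologs(pt, tg$registry)
  expect_equal(nrow(raw), 3)  # duplicate (spA, seq1, CLK) collapsed
  expect_setequal(raw$seq_id[raw$component == "CRY2"], c("s1", "s2"))
  # the mirrored row (bait in column b) was recognized too
  expect_equal(sum(raw$component == "CRY2" & raw$species == "spB"), 2)
})

test_that("an empty or bait-free pair table yields no candidates", {
  tg <- mini_registry_setup()
  pt <- tibble::tibble(species_a = "x", seq_a = "a",
                       species_b = "y", seq_b = "b")
  expect_equal(nrow(extract_bait_orthologs(pt, tg$registry)), 0)
})

# Vetting fixtures: bait CLK has domains PF1+PF2, family FAMA subfamily SF1.
vet_fixture <- function() {
  registry <- tibble::tibble(component = "CLK", accession = "O61735",
                             seq_id = "bait_SOIREF")
  domain <- tibble::tibble(
    seq_id = c("bait_SOIREF", "bait_SOIREF", "c_pass", "c_nofam",
               "c_nodomshared", "c_wrongfam", "c_nosubfam"),
    db = "Pfam",
    accession = c("PF1", "PF2", "PF1", "PF1", "PF9", "PF1", "PF2"),
    name = "dom", start = 1L, end = 10L, evalue = 1e-10)
  family <- tibble::tibble(
    seq_id = c("bait_SOIREF", "c_pass", "c_nodomshared", "c_wrongfam",
               "c_nosubfam", "c_nopfam"),
    family_acc = c("FAMA", "FAMA", "FAMA", "FAMB", "FAMA", "FAMA"),
    subfamily_acc = c("FAMA:SF1", "FAMA:SF1", "FAMA:SF1", NA, NA, NA))
  raw <- tibble::tibble(
    species = "spA",
    seq_id = c("c_pass", "c_nofam", "c_nopfam", "c_nodomshared",
               "c_wrongfam", "c_nosubfam"),
    component = "CLK")
  list(registry = registry, domain = domain, family = family, raw = raw)
}

test_that("the vetting cascade drops candidates at the documented stages", {
  fx <- vet_fixture()
  v <- vet_candidates(fx$raw, fx$domain, fx$family, fx$registry)
  cand <- v$candidates
  stage <- setNames(cand$failed_stage, cand$seq_id)
  expect_true(is.na(stage["c_pass"]))
  expect_equal(unname(stage["c_nofam"]), "S1")   # Pfam but no PANTHER
  expect_equal(unname(stage["c_nopfam"]), "S1")  # PANTHER but no Pfam
  expect_equal(unname(stage["c_nodomshared"]), "S2")
  expect_equal(unname(stage["c_wrongfam"]), "S3")
  # c_nosubfam shares a domain and the family, but a same-family sibling
  # (c_pass) matches the bait subfamily, so only that sibling is retained
  expect_equal(unname(stage["c_nosubfam"]), "S4")
  expect_equal(cand$seq_id[cand$retained], "c_pass")
})

test_that("without a subfamily-matching sibling all family members survive", {
  fx <- vet_fixture()
  fx$family$subfamily_acc[fx$family$seq_id == "c_pass"] <- NA
  v <- vet_candidates(fx$raw, fx$domain, fx$family, fx$registry)
  cand <- v$candidates
  expect_setequal(cand$seq_id[cand$retained], c("c_pass", "c_nosubfam"))
})

test_that("a bait without annotations is a configuration error", {
  fx <- vet_fixture()
  expect_error(vet_candidates(fx$raw, fx$domain[-(1:2), ], fx$family,
                              fx$registry), "cascade undefined")
})

test_that("cascade failures are monotone and stage rules re-verify", {
  # randomized annotation tables; every verdict is re-checked against an
  # independent evaluation of the four stage predicates
  for (seed in 1:25) {
    set.seed(seed)
    n <- 40
    comps <- sample(c("CLK", "CRY2"), n, TRUE)
    registry <- tibble::tibble(
      component = c("CLK", "CRY2"), accession = c("a1", "a2"),
      seq_id = c("baitCLK_SOIREF", "baitCRY2_SOIREF"))
    bait_dom <- tibble::tibble(
      seq_id = rep(registry$seq_id, each = 2), db = "Pfam",
      accession = c("PF1", "PF2", "PF3", "PF4"),
      name = "d", start = 1L, end = 5L, evalue = 1e-9)
    bait_fam <- tibble::tibble(
      seq_id = registry$seq_id, family_acc = c("FAMC", "FAMD"),
      subfamily_acc = c("FAMC:SF1", NA))
    ids <- sprintf("cand%02d", 1:n)
    has_dom <- runif(n) < 0.8
    dom <- tibble::tibble(
      seq_id = ids[has_dom], db = "Pfam",
      accession = sample(paste0("PF", 1:5), sum(has_dom), TRUE),
      name = "d", start = 1L, end = 5L, evalue = 1e-9)
    has_fam <- runif(n) < 0.8
    fam <- tibble::tibble(
      seq_id = ids[has_fam],
      family_acc = sample(c("FAMC", "FAMD", "FAMX"), sum(has_fam), TRUE),
      subfamily_acc = ifelse(runif(sum(has_fam)) < 0.5, "FAMC:SF1",
                             NA_character_))
    raw <- tibble::tibble(species = sample(c("s1", "s2"), n, TRUE),
                          seq_id = ids, component = comps)
    v <- vet_candidates(raw, dplyr::bind_rows(bait_dom, dom),
                        dplyr::bind_rows(bait_fam, fam), registry)
    cand <- v$candidates
    # monotone survivor sets across stages
    surv <- function(k) {
      sum(is.na(cand$failed_stage) |
            match(cand$failed_stage, paste0("S", 1:4)) > k)
    }
    counts <- vapply(0:4, surv, numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[1], n)
    # independent re-check of each retained candidate
    pfams <- split(dom$accession, dom$seq_id)
    bait_pf <- split(bait_dom$accession, bait_dom$seq_id)
    famv <- setNames(fam$family_acc, fam$seq_id)
    subv <- setNames(fam$subfamily_acc, fam$seq_id)
    bfam <- setNames(bait_fam$family_acc, registry$component)
    bsub <- setNames(bait_fam$subfamily_acc, registry$component)
    for (i in which(cand$retained)) {
      sid <- cand$seq_id[i]; cp <- cand$component[i]
      expect_true(sid %in% names(pfams) && sid %in% names(famv))
      expect_gt(length(intersect(
        pfams[[sid]],
        bait_pf[[registry$seq_id[registry$component == cp]]])), 0)
      expect_equal(unname(famv[sid]), unname(bfam[cp]))
      # S4: if retained without the bait subfamily, no retained-or-dropped
      # same-group candidate may have matched it
      if (!is.na(bsub[cp]) &&
          (is.na(subv[sid]) || subv[sid] != bsub[cp])) {
        grp <- cand[cand$species == cand$species[i] &
                      cand$component == cp, ]
        grp_alive <- grp[is.na(grp$failed_stage) |
                           grp$failed_stage == "S4", ]
        expect_false(any(!is.na(subv[grp_alive$seq_id]) &
                           subv[grp_alive$seq_id] == bsub[cp],
                         na.rm = FALSE))
      }
    }
  }
})

test_that("Swiss-Prot confirmation flags but never removes candidates", {
  fx <- vet_fixture()
  v <- vet_candidates(fx$raw, fx$domain, fx$family, fx$registry)
  best <- tibble::tibble(query = "c_pass", target = "sp|O61735|CLK_DROME",
                         evalue = 1e-30, bitscore = 200)
  v2 <- confirm_swissprot(v, best, whitelist = "O61735")
  cand <- v2$candidates
  expect_true(cand$swissprot_confirmed[cand$seq_id == "c_pass"])
  expect_false(any(cand$swissprot_confirmed[cand$seq_id != "c_pass"]))
  expect_equal(cand$retained, v$candidates$retained)
  # empty whitelist: all unconfirmed, all retained rows unchanged
  v3 <- confirm_swissprot(v, best, whitelist = character())
  expect_false(any(v3$candidates$swissprot_confirmed))
})

test_that("the candidate matrix counts retained candidates with NA absences", {
  cand <- tibble::tibble(
    species = "Acartia tonsa",
    seq_id = sprintf("s%d", 1:4),
    component = c("CLK", "PDP1e", "PDP1e", "PDP1e"),
    retained = TRUE)
  m <- candidate_matrix(cand)
  expect_equal(m$CLK, 1L)
  expect_equal(m$PDP1e, 3L)
  expect_true(all(is.na(m$TIM)))
  expect_equal(names(m), c("species", clock_components()))
  m0 <- candidate_matrix(cand[0, ])
  expect_equal(nrow(m0), 0)
})
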