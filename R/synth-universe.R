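# Fixed back-translation codon table: one codon per amino acid, chosen once.
# Leucine (TTA) and serine (TCA) reverse-complement into stop codons, which
# seeds the reverse strand of every back-translated CDS with stops and keeps
# the planted ORF the best one. The stop codon is TGA.
codon_table <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "TTA", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCA", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

aa_alphabet <- names(codon_table)

#' Back-translate a protein with a fixed codon table
#'
#' Deterministic: one codon per amino acid. A stop codon (`TGA`) is appended
#' when `include_stop` is TRUE.
#'
#' @param protein Amino-acid string.
#' @param utr5,utr3 Flanking untranslated sequence (default empty).
#' @param include_stop Append the stop codon (default TRUE).
#' @return Nucleotide string `utr5 + CDS (+ stop) + utr3`.
#' @export
back_translate <- function(protein, utr5 = "", utr3 = "",
                           include_stop = TRUE) {
  aas <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(aas), aa_alphabet)
  if (length(bad)) stop_with_ids("Amino acid(s) without codon", bad)
  paste0(utr5, paste(codon_table[aas], collapse = ""),
         if (include_stop) "TGA" else "", utr3)
}

random_protein <- function(n) {
  paste(sample(aa_alphabet, n, replace = TRUE), collapse = "")
}

# Substitution-only mutation at a per-residue rate. Position 1 (the
# initiator methionine) is never touched when keep_first is TRUE.
mutate_protein <- function(seq, rate, keep_first = TRUE) {
  if (rate == 0) return(seq)
  aas <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(aas)) < rate)
  if (keep_first) hit <- setdiff(hit, 1L)
  for (i in hit) {
    aas[i] <- sample(setdiff(aa_alphabet, aas[i]), 1)
  }
  paste(aas, collapse = "")
}

mutate_dna <- function(seq, n_subs) {
  if (n_subs == 0) return(seq)
  nts <- strsplit(seq, "")[[1]]
  pos <- sample(length(nts), n_subs)
  for (i in pos) nts[i] <- sample(setdiff(c("A", "C", "G", "T"), nts[i]), 1)
  paste(nts, collapse = "")
}

# Build a bait protein from its domain architecture: leader, then domains
# separated by linkers, then a tail padded so the protein reaches the
# configured minimum length. Returns the sequence and 1-based inclusive
# domain coordinates.
make_architecture_protein <- function(arch, cfg) {
  lead <- cfg$leader_len; link <- cfg$linker_len; tail <- cfg$tail_len
  total <- lead + sum(arch$len) + link * (nrow(arch) - 1) + tail
  pad <- max(0L, cfg$min_protein_len - total)
  segs <- character(0)
  coords <- integer(0)
  pos <- 1L
  segs <- c(segs, paste0("M", random_protein(lead - 1)))
  pos <- pos + lead
  starts <- ends <- integer(nrow(arch))
  for (i in seq_len(nrow(arch))) {
    starts[i] <- pos
    segs <- c(segs, random_protein(arch$len[i]))
    pos <- pos + arch$len[i]
    ends[i] <- pos - 1L
    if (i < nrow(arch)) {
      segs <- c(segs, random_protein(link))
      pos <- pos + link
    }
  }
  segs <- c(segs, random_protein(tail + pad))
  list(seq = paste(segs, collapse = ""),
       domains = tibble(accession = arch$accession, name = arch$name,
                        start = starts, end = ends))
}

# Cut an ortholog into an ORF fragment, keeping at least one full domain.
# Cuts fall in linkers (multi-domain architectures) or in the leader/tail
# (single-domain). Domain coordinates are shifted; domains crossing a cut
# are dropped. The first residue of a start-less fragment is forced away
# from methionine so the ORF classifier cannot see a spurious start codon.
cut_fragment <- function(seq, domains, type, cfg) {
  L <- nchar(seq)
  k <- nrow(domains)
  half <- cfg$linker_len %/% 2
  from <- 1L
  to <- L
  if (type %in% c("5p", "int")) {
    from <- if (k >= 2) domains$start[2] - half else cfg$leader_len %/% 2
  }
  if (type == "3p") {
    to <- if (k >= 2) domains$end[k - 1] + half else L - cfg$tail_len %/% 2
  }
  if (type == "int") to <- L - cfg$tail_len %/% 2
  frag <- substr(seq, from, to)
  if (type %in% c("5p", "int") && substr(frag, 1, 1) == "M") {
    frag <- paste0("V", substr(frag, 2, nchar(frag)))
  }
  keep <- domains$start >= from & domains$end <= to
  dom <- domains[keep, , drop = FALSE]
  dom$start <- dom$start - from + 1L
  dom$end <- dom$end - from + 1L
  if (nrow(dom) == 0 || nchar(frag) < 100) {
    stop("Architecture too small to fragment (config error).")
  }
  list(seq = frag, domains = dom)
}

#' Generate a ground-truthed synthetic ortholog universe
#'
#' Plants, per species, one ortholog of each clock bait (mutated at the
#' configured divergence, with domains re-annotated at the planted
#' coordinates), optional more-diverged paralogs, ORF fragments with known
#' completeness tags, and single-domain decoy proteins in an unrelated
#' PANTHER family. Emits the reference proteome (baits marker-tagged), the
#' species proteomes, domain/family tables covering baits and all planted
#' sequences, a pairwise-ortholog table derived from the truth (with
#' configurable false-negative/positive noise), a Swiss-Prot-style best-hit
#' table, and a truth manifest for validation.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `ref_proteome`, `registry`, `proteomes`
#'   (tibble with `species`, `id`, `desc`, `seq`, `completeness`),
#'   `domain_table`, `family_table`, `pair_table`, `hit_table`, `manifest`
#'   (list: `orthologs`, `decoys`, `fn_dropped`, `fp_pairs`), and `config`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)

  # --- reference proteome and baits ------------------------------------
  bait_prot <- vector("list", length(cfg$components))
  names(bait_prot) <- cfg$components
  ref_rows <- list()
  dom_rows <- list()
  fam_rows <- list()
  for (cp in cfg$components) {
    bp <- make_architecture_protein(cfg$architectures[[cp]], cfg)
    bait_prot[[cp]] <- bp
    acc <- cfg$baits$accession[cfg$baits$component == cp]
    id <- paste0("sp|", acc, "|", gsub("-", "", cp), "_REFSP")
    ref_rows[[cp]] <- tibble(id = id, desc = "", seq = bp$seq)
    dom_rows[[paste0("bait_", cp)]] <- dplyr::mutate(
      bp$domains, seq_id = id, db = "Pfam", evalue = 1e-20, .before = 1)
  }
  ref_proteome <- dplyr::bind_rows(ref_rows)
  # a few non-bait reference proteins so the reference set is not all baits
  for (i in 1:3) {
    ref_proteome <- dplyr::bind_rows(
      ref_proteome,
      tibble(id = sprintf("sp|X%05d|OTHER%d_REFSP", i, i), desc = "",
             seq = paste0("M", random_protein(199))))
  }
  tagged <- tag_baits(ref_proteome, cfg$baits)
  ref_proteome <- tagged$proteome
  registry <- tagged$registry
  # bait ids changed by tagging; re-key their domain rows
  id_map <- setNames(registry$seq_id, registry$component)
  for (cp in cfg$components) {
    dom_rows[[paste0("bait_", cp)]]$seq_id <- unname(id_map[cp])
    famr <- cfg$families[cfg$families$component == cp, ]
    fam_rows[[paste0("bait_", cp)]] <- tibble(
      seq_id = unname(id_map[cp]), family_acc = famr$family_acc,
      subfamily_acc = famr$subfamily_acc)
  }

  # --- species proteomes ------------------------------------------------
  prot_rows <- list()
  ortho_rows <- list()
  decoy_rows <- list()
  hit_rows <- list()
  frag_types <- c("5p", "3p", "int")
  for (sp in cfg$species) {
    # gene numbers are blocked per species so sequence ids are unique
    # across the whole universe (annotation tables are keyed by seq_id)
    gene <- 10000L * match(sp, cfg$species)
    emit <- function(component, seq, domains, completeness, is_paralog) {
      gene <<- gene + 1L
      tid <- sprintf("TRINITY_DN%d_c0_g1_i1", gene)
      pid <- paste0(tid, ".p1")
      prot_rows[[paste(sp, gene)]] <<- tibble(
        species = sp, id = pid, desc = paste0("type:", completeness),
        seq = seq, completeness = completeness)
      dom_rows[[paste(sp, gene)]] <<- dplyr::mutate(
        domains, seq_id = pid, db = "Pfam", evalue = 1e-15, .before = 1)
      list(pid = pid, tid = tid)
    }
    for (cp in cfg$components) {
      n_copies <- 1L + (runif(1) < cfg$paralog_rate)
      for (copy in seq_len(n_copies)) {
        is_par <- copy > 1L
        rate <- if (is_par) cfg$paralog_divergence else
          cfg$divergence_per_species
        seq <- mutate_protein(bait_prot[[cp]]$seq, rate)
        domains <- bait_prot[[cp]]$domains
        completeness <- "cmp"
        if (runif(1) < cfg$fragment_rate) {
          completeness <- sample(frag_types, 1)
          fr <- cut_fragment(seq, domains, completeness, cfg)
          seq <- fr$seq
          domains <- fr$domains
        }
        ids <- emit(cp, seq, domains, completeness, is_par)
        famr <- cfg$families[cfg$families$component == cp, ]
        fam_rows[[paste(sp, ids$pid)]] <- tibble(
          seq_id = ids$pid, family_acc = famr$family_acc,
          subfamily_acc = if (runif(1) < cfg$subfamily_frac)
            famr$subfamily_acc else NA_character_)
        ortho_rows[[paste(sp, ids$pid)]] <- tibble(
          species = sp, component = cp, seq_id = ids$pid,
          transcript_id = ids$tid,
          gene_key = parse_trinity_id(ids$tid)$gene_key,
          completeness = completeness, is_paralog = is_par)
        acc <- cfg$baits$accession[cfg$baits$component == cp]
        hit_rows[[paste(sp, ids$pid)]] <- tibble(
          query = ids$pid, species = sp,
          target = paste0("sp|", acc, "|", gsub("-", "", cp), "_REFSP"),
          evalue = 1e-40, bitscore = 300, qcov = 0.9, tcov = 0.9)
      }
    }
    # decoys: exactly one bait domain inside an unrelated family
    for (d in seq_len(cfg$decoy_count)) {
      cp <- sample(cfg$components, 1)
      src <- bait_prot[[cp]]
      dom1 <- src$domains[1, , drop = FALSE]
      dom_seq <- mutate_protein(
        substr(src$seq, dom1$start, dom1$end), 0.05, keep_first = FALSE)
      lead <- cfg$leader_len
      seq <- paste0("M", random_protein(lead - 1), dom_seq,
                    random_protein(cfg$tail_len + 60))
      domains <- tibble(accession = dom1$accession, name = dom1$name,
                        start = lead + 1L, end = lead + nchar(dom_seq))
      ids <- emit(cp, seq, domains, "cmp", FALSE)
      fam_rows[[paste(sp, ids$pid)]] <- tibble(
        seq_id = ids$pid, family_acc = "PTHR88888",
        subfamily_acc = "PTHR88888:SF1")
      decoy_rows[[paste(sp, ids$pid)]] <- tibble(
        species = sp, seq_id = ids$pid, transcript_id = ids$tid,
        shared_domain = dom1$accession)
      hit_rows[[paste(sp, ids$pid)]] <- tibble(
        query = ids$pid, species = sp, target = "sp|Q99999|DECOY_REFSP",
        evalue = 1e-10, bitscore = 80, qcov = 0.8, tcov = 0.4)
    }
  }
  proteomes <- dplyr::bind_rows(prot_rows)
  orthologs <- dplyr::bind_rows(ortho_rows)
  decoys <- dplyr::bind_rows(decoy_rows)

  # --- pair table from truth, with injectable noise ---------------------
  true_pairs <- tibble(
    species_a = "reference",
    seq_a = unname(id_map[orthologs$component]),
    species_b = orthologs$species,
    seq_b = orthologs$seq_id)
  drop <- runif(nrow(true_pairs)) < cfg$ortholog_fn_rate
  fn_dropped <- true_pairs[drop, , drop = FALSE]
  pair_table <- true_pairs[!drop, , drop = FALSE]
  fp_rows <- list()
  if (cfg$ortholog_fp_rate > 0 && nrow(decoys) > 0) {
    for (i in seq_len(nrow(decoys))) {
      if (runif(1) < cfg$ortholog_fp_rate) {
        cp <- sample(cfg$components, 1)
        fp_rows[[i]] <- tibble(
          species_a = "reference", seq_a = unname(id_map[cp]),
          species_b = decoys$species[i], seq_b = decoys$seq_id[i])
      }
    }
  }
  fp_pairs <- dplyr::bind_rows(fp_rows)
  if (nrow(fp_pairs)) pair_table <- dplyr::bind_rows(pair_table, fp_pairs)

  # orthology-mapper style annotations: every planted sequence gets a row
  # (orthologs point at the component's orthogroup, decoys elsewhere)
  eggnog_table <- dplyr::bind_rows(
    tibble(seq_id = orthologs$seq_id,
           ortholog = paste0("OG_", orthologs$component),
           gos = "GO:0007623",
           pfams = NA_character_),
    if (nrow(decoys)) tibble(seq_id = decoys$seq_id,
                             ortholog = "OG_DECOY",
                             gos = "GO:0003674",
                             pfams = NA_character_)
  )

  list(
    ref_proteome = ref_proteome,
    registry = registry,
    proteomes = proteomes,
    eggnog_table = eggnog_table,
    domain_table = dplyr::bind_rows(dom_rows)[
      , c("seq_id", "db", "accession", "name", "start", "end", "evalue")],
    family_table = dplyr::bind_rows(fam_rows),
    pair_table = pair_table,
    hit_table = dplyr::bind_rows(hit_rows),
    manifest = list(orthologs = orthologs, decoys = decoys,
                    fn_dropped = fn_dropped, fp_pairs = fp_pairs),
    config = cfg
  )
}
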