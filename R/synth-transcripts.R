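# UTRs are built from "TTAA" repeats: stop codons in every frame on both
# strands and no ATG, so untranslated flanks never extend or seed an ORF.
# The 5' UTR ends with an in-frame TAA immediately upstream of the start
# codon, which pins the planted ORF's 5' boundary.
make_utr5 <- function(len) {
  if (len < 3) len <- 3
  body <- strrep("TTAA", ceiling(len / 4))
  paste0(substr(body, 1, len - 3), "TAA")
}

make_utr3 <- function(len) {
  if (len <= 0) return("")
  substr(strrep("TTAA", ceiling(len / 4)), 1, len)
}

#' Generate Trinity-style transcripts for a synthetic proteome
#'
#' Each protein becomes a gene emitting 1..k transcript isoforms sharing a
#' gene key. Isoform `i1` back-translates the full protein; the transcript
#' structure encodes the planted completeness (`cmp`: UTRs, start and stop;
#' `5p`: no 5' UTR, first codon not ATG; `3p`: no stop or 3' UTR; `int`:
#' bare codons). Additional isoforms are 3'-truncations, so the longest
#' protein per gene is always the `i1` translation. Genes can additionally
#' emit a near-duplicate transcript (a lightly truncated copy with < 2%
#' substitutions) under a fresh gene id, which the clustering step is
#' expected to remove.
#'
#' @param proteins Tibble with `id` (Trinity protein ids `..._i1.p1`),
#'   `seq`, optional `completeness` (default `cmp`) and optional `species`.
#' @param config A [synth_config()] object.
#' @param seed Seed for isoform-count and duplicate draws (default
#'   `config$seed + 1000`).
#' @return A list: `transcripts` (tibble `species?`, `id`, `seq`), `map`
#'   (tibble `protein_id`, `transcript_id`, `isoform_index`, `role`), and
#'   `near_duplicates` (tibble `original_id`, `duplicate_id`, with planted
#'   pairwise identity >= 98%).
#' @export
generate_transcripts <- function(proteins, config, seed = config$seed + 1000L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  cfg <- config
  if (!"completeness" %in% names(proteins)) proteins$completeness <- "cmp"
  has_species <- "species" %in% names(proteins)
  groups <- if (has_species) split(proteins, proteins$species) else
    list(all = proteins)

  tr_rows <- list()
  map_rows <- list()
  dup_rows <- list()
  for (gname in names(groups)) {
    grp <- groups[[gname]]
    parsed <- parse_trinity_id(grp$id)
    gene_counter <- max(as.integer(sub("^DN([0-9]+)_.*$", "\\1",
                                       parsed$gene_key)))
    for (r in seq_len(nrow(grp))) {
      cmp <- grp$completeness[r]
      tid1 <- strip_orf_suffix(grp$id[r])
      cds <- back_translate(grp$seq[r], include_stop = cmp %in% c("cmp", "5p"))
      utr5 <- if (cmp %in% c("cmp", "3p")) make_utr5(cfg$utr5_len) else ""
      utr3 <- if (cmp %in% c("cmp", "5p")) make_utr3(cfg$utr3_len) else ""
      t1 <- paste0(utr5, cds, utr3)
      tr_rows[[paste(gname, tid1)]] <- tibble(
        species = if (has_species) gname else NA_character_,
        id = tid1, seq = t1)
      map_rows[[paste(gname, tid1)]] <- tibble(
        protein_id = grp$id[r], transcript_id = tid1,
        isoform_index = 1L, role = "primary")
      # extra, 3'-truncated isoforms under the same gene key
      n_iso <- sample(seq_along(cfg$isoform_probs), 1,
                      prob = cfg$isoform_probs)
      L <- nchar(t1)
      for (j in seq_len(n_iso - 1)) {
        tl <- L - 120L * j
        if (tl < 200L) break
        tidj <- sub("_i1$", paste0("_i", j + 1L), tid1)
        tr_rows[[paste(gname, tidj)]] <- tibble(
          species = if (has_species) gname else NA_character_,
          id = tidj, seq = substr(t1, 1, tl))
        map_rows[[paste(gname, tidj)]] <- tibble(
          protein_id = grp$id[r], transcript_id = tidj,
          isoform_index = j + 1L, role = "truncated_isoform")
      }
      # near-duplicate under a fresh gene id
      if (runif(1) < cfg$near_duplicate_rate && L >= 250) {
        gene_counter <- gene_counter + 1L
        dup_id <- sprintf("TRINITY_DN%d_c0_g1_i1", gene_counter)
        t_cut <- max(1L, as.integer(floor(0.004 * L)))
        n_sub <- max(1L, as.integer(floor(0.004 * L)))
        dup_seq <- mutate_dna(substr(t1, 1, L - t_cut), n_sub)
        tr_rows[[paste(gname, dup_id)]] <- tibble(
          species = if (has_species) gname else NA_character_,
          id = dup_id, seq = dup_seq)
        map_rows[[paste(gname, dup_id)]] <- tibble(
          protein_id = grp$id[r], transcript_id = dup_id,
          isoform_index = 1L, role = "near_duplicate")
        dup_rows[[paste(gname, dup_id)]] <- tibble(
          species = if (has_species) gname else NA_character_,
          original_id = tid1, duplicate_id = dup_id)
      }
    }
  }
  transcripts <- dplyr::bind_rows(tr_rows)
  if (!has_species) transcripts$species <- NULL
  dups <- dplyr::bind_rows(dup_rows)
  if (nrow(dups) && !has_species) dups$species <- NULL
  list(transcripts = transcripts,
       map = dplyr::bind_rows(map_rows),
       near_duplicates = if (nrow(dups)) dups else
         tibble(original_id = character(), duplicate_id = character()))
}

#' Simulate paired-end reads from transcripts
#'
#' Uniform sampling of fixed-length windows from transcripts long enough to
#' host a pair; a configurable fraction of pairs receives an `N` base call
#' (forward mate) or a low mean quality (reverse mate) to exercise the read
#' filter. Clean reads carry Q40 throughout; low-quality reads Q10.
#'
#' @param transcripts Sequence tibble (`id`, `seq`).
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 100).
#' @param frac_n Fraction of pairs given an `N` (default 0).
#' @param frac_lowq Fraction of pairs given a low-quality mate (default 0).
#' @param seed Integer seed.
#' @return Tibble of pairs (columns of [read_fastq_pairs()]) plus a
#'   `defect` column (`none`, `n`, `lowq`) recording the planted truth.
#' @export
generate_read_pairs <- function(transcripts, n_pairs, read_len = 100L,
                                frac_n = 0, frac_lowq = 0, seed = 1L) {
  set.seed(seed)
  if (n_pairs == 0) {
    return(tibble(pair_id = character(), fwd_seq = character(),
                  fwd_qual = character(), rev_seq = character(),
                  rev_qual = character(), defect = character()))
  }
  span <- read_len + 50L
  ok <- nchar(transcripts$seq) >= span
  if (!any(ok)) stop("No transcript long enough to sample read pairs from.")
  pool <- transcripts$seq[ok]
  idx <- sample(length(pool), n_pairs, replace = TRUE)
  pos <- vapply(idx, function(i) {
    sample(nchar(pool[i]) - span + 1L, 1)
  }, integer(1))
  fwd <- substr(pool[idx], pos, pos + read_len - 1L)
  rev_tpl <- substr(pool[idx], pos + 50L, pos + span - 1L)
  rev <- vapply(rev_tpl, revcomp, character(1), USE.NAMES = FALSE)
  q_hi <- strrep("I", read_len)  # Q40
  q_lo <- strrep("+", read_len)  # Q10
  u <- runif(n_pairs)
  defect <- ifelse(u < frac_n, "n",
                   ifelse(u < frac_n + frac_lowq, "lowq", "none"))
  fwd_q <- rep(q_hi, n_pairs)
  rev_q <- ifelse(defect == "lowq", q_lo, q_hi)
  n_pos <- sample(read_len, n_pairs, replace = TRUE)
  fwd <- ifelse(defect == "n",
                paste0(substr(fwd, 1, n_pos - 1), "N",
                       substr(fwd, n_pos + 1, read_len)),
                fwd)
  tibble(pair_id = sprintf("read_%06d", seq_len(n_pairs)),
         fwd_seq = fwd, fwd_qual = fwd_q,
         rev_seq = rev, rev_qual = rev_q,
         defect = defect)
}
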