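# Independent oracles used across the suite. They deliberately take a
# different route than the package code: alignments go through
# Biostrings::pairwiseAlignment, ORF enumeration works on translated
# frame strings, N50 via an explicit search over candidate lengths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Global alignment with the same unit-cost scoring as the package's
# Needleman-Wunsch, via Biostrings.
oracle_align <- function(a, b) {
  letters_ab <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
  m <- matrix(-1, length(letters_ab), length(letters_ab),
              dimnames = list(letters_ab, letters_ab))
  diag(m) <- 1
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 1)
  list(identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
       coverage_shorter = (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa)) /
         min(nchar(a), nchar(b)),
       score = Biostrings::score(pa))
}

# Greedy clustering with the same join rule, all alignments through the
# Biostrings oracle, no prefilter.
oracle_cluster <- function(records, min_identity = 0.98,
                           min_target_cov = 0.98) {
  ord <- order(-nchar(records$seq), records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  reps <- integer(0)
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    joined <- 0L
    for (r in reps) {
      st <- oracle_align(seqs[r], seqs[i])
      if (st$identity >= min_identity &&
          st$coverage_shorter >= min_target_cov) {
        joined <- r
        break
      }
    }
    if (joined == 0L) {
      reps <- c(reps, i)
      joined <- i
    }
    assign[i] <- joined
  }
  tibble::tibble(representative_id = ids[assign], member_id = ids)
}

# Exhaustive six-frame ORF enumeration on translated frame strings.
# Stops become '*', codons containing N become 'X'; chunks between
# terminators give at most two candidates (first-M-anchored; edge-anchored
# for the frame's first chunk). Returns all candidates as a tibble.
oracle_orf_candidates <- function(seq) {
  L <- nchar(seq)
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < 1) next
      pos <- frame + 1 + 3 * (0:(n_codons - 1))
      codons <- substring(s, pos, pos + 2)
      aa <- ifelse(grepl("N", codons), "X", unname(gc[codons]))
      aa_str <- paste(aa, collapse = "")
      # chunk boundaries on the translated string
      term <- gregexpr("[*X]", aa_str)[[1]]
      term <- term[term > 0]
      bounds <- c(0, term, nchar(aa_str) + 1)
      for (bi in seq_len(length(bounds) - 1)) {
        a0 <- bounds[bi] + 1
        b0 <- bounds[bi + 1] - 1
        if (a0 > b0) next
        chunk <- substr(aa_str, a0, b0)
        stop_here <- bounds[bi + 1] <= nchar(aa_str) &&
          substr(aa_str, bounds[bi + 1], bounds[bi + 1]) == "*"
        starts <- integer(0)
        if (a0 == 1) starts <- a0
        m1 <- regexpr("M", chunk, fixed = TRUE)
        if (m1 > 0) starts <- union(starts, a0 + m1 - 1)
        for (cs in starts) {
          prot <- substr(aa_str, cs, b0)
          has_start <- substr(prot, 1, 1) == "M" &&
            codons[cs] == "ATG"
          span0 <- frame + 3 * (cs - 1)
          span1 <- frame + 3 * b0 + if (stop_here) 3 else 0
          fwd <- if (strand == "+") c(span0, span1) else
            c(L - span1, L - span0)
          cmp <- if (has_start && stop_here) "cmp"
                 else if (stop_here) "5p"
                 else if (has_start) "3p" else "int"
          out[[length(out) + 1]] <- tibble::tibble(
            strand = strand, frame = frame, start = fwd[1], end = fwd[2],
            protein = prot, completeness = cmp)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

oracle_best_orf <- function(seq, min_aa = 100L) {
  cands <- oracle_orf_candidates(seq)
  if (nrow(cands) == 0) return(NULL)
  cands <- cands[order(-nchar(cands$protein), cands$strand != "+",
                       cands$frame, cands$start), ]
  best <- cands[1, , drop = FALSE]
  if (nchar(best$protein) < min_aa) return(NULL)
  best
}

# N50 by explicit search: the largest length L in the list such that
# contigs of length >= L hold at least half of all bases.
oracle_n50 <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  }
  min(lengths)
}

# Write a pair tibble to two temp FASTQ files and return the paths.
write_temp_fastq <- function(pairs) {
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq_pairs(pairs, f1, f2)
  c(f1, f2)
}
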