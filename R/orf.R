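#' Drop transcripts shorter than a minimum length
#'
#' @param records Sequence tibble (`id`, `seq`, ...), nucleotide alphabet.
#' @param min_len Minimum length in nucleotides (default 200); records of
#'   exactly `min_len` are kept.
#' @return The records with `nchar(seq) >= min_len`, order preserved.
#' @export
filter_min_length <- function(records, min_len = 200L) {
  records[nchar(records$seq) >= min_len, , drop = FALSE]
}

stop_codons <- c("TAA", "TAG", "TGA")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Predict the single best ORF of a transcript
#'
#' Scans all six frames (both strands). Candidate ORFs are maximal in-frame
#' spans running from an ATG -- or from the in-frame transcript edge when no
#' upstream stop exists (partial) -- to a stop codon or the edge (partial).
#' Codons containing `N` are untranslatable and terminate a span without
#' counting as a stop. The best ORF is the one with the longest protein;
#' ties are broken deterministically: `+` strand first, then lowest frame,
#' then smallest forward-strand start.
#'
#' Completeness tags: `cmp` (ATG and stop), `5p` (no ATG, stop present),
#' `3p` (ATG, no stop), `int` (neither).
#'
#' @param transcript_id Id recorded in the result.
#' @param seq Nucleotide sequence (A, C, G, T, N only).
#' @param min_aa Minimum protein length to report an ORF (default 100).
#' @return A one-row tibble (`transcript_id`, `strand`, `frame`, `start`,
#'   `end`, `protein`, `completeness`) or `NULL` when no ORF reaches
#'   `min_aa`. Coordinates are 0-based half-open on the forward strand of
#'   the transcript and include the stop codon when present.
#' @export
find_best_orf <- function(transcript_id, seq, min_aa = 100L) {
  if (grepl("[^ACGTN]", seq)) {
    stop("Transcript '", transcript_id,
         "' contains residues outside {A,C,G,T,N}.")
  }
  cands <- enumerate_orf_candidates(seq)
  if (is.null(cands) || nrow(cands) == 0) return(NULL)
  cands <- cands[order(-nchar(cands$protein),
                       cands$strand != "+", cands$frame, cands$start), ]
  best <- cands[1, , drop = FALSE]
  if (nchar(best$protein) < min_aa) return(NULL)
  tibble(transcript_id = transcript_id, best)
}

# All candidate ORFs of one transcript, as a tibble. Shared by the best-ORF
# picker; the completeness logic lives here.
enumerate_orf_candidates <- function(seq) {
  L <- nchar(seq)
  out <- vector("list", 6)
  k <- 0
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < 1) next
      starts <- frame + 1 + 3 * (0:(n_codons - 1))
      codons <- substring(s, starts, starts + 2)
      is_stop <- codons %in% stop_codons
      is_nn <- grepl("N", codons, fixed = TRUE)
      term <- which(is_stop | is_nn)
      seg_start <- c(1L, term + 1L)
      seg_end <- c(term - 1L, n_codons)
      rows <- list()
      for (i in seq_along(seg_start)) {
        a <- seg_start[i]; b <- seg_end[i]
        if (a > b) next
        stop_here <- i <= length(term) && is_stop[term[i]]
        cand_starts <- integer(0)
        if (a == 1L) cand_starts <- a  # touches the transcript edge
        atg <- which(codons[a:b] == "ATG")
        if (length(atg)) cand_starts <- union(cand_starts, a + atg[1] - 1L)
        for (cs in cand_starts) {
          has_start <- codons[cs] == "ATG"
          prot <- paste(translate_codons(codons[cs:b]), collapse = "")
          span0 <- frame + 3 * (cs - 1L)
          span1 <- frame + 3 * b + if (stop_here) 3L else 0L
          fwd <- if (strand == "+") c(span0, span1) else c(L - span1, L - span0)
          cmp <- if (has_start && stop_here) "cmp"
                 else if (!has_start && stop_here) "5p"
                 else if (has_start) "3p" else "int"
          rows[[length(rows) + 1]] <- tibble(
            strand = strand, frame = frame,
            start = fwd[1], end = fwd[2],
            protein = prot, completeness = cmp)
        }
      }
      if (length(rows)) { k <- k + 1; out[[k]] <- dplyr::bind_rows(rows) }
    }
  }
  if (k == 0) return(NULL)
  dplyr::bind_rows(out[seq_len(k)])
}

#' Predict best ORFs for a set of transcripts
#'
#' @param records Sequence tibble (`id`, `seq`).
#' @param min_aa Minimum protein length (default 100).
#' @return A tibble of best ORFs, one row per transcript that yields one.
#' @export
find_best_orfs <- function(records, min_aa = 100L) {
  res <- purrr::map2(records$id, records$seq, find_best_orf, min_aa = min_aa)
  dplyr::bind_rows(res)
}

#' Convert predicted ORFs to a protein sequence tibble
#'
#' Ids follow the `<transcript_id>.p1` convention (single best ORF per
#' transcript) with the completeness tag in the description.
#'
#' @param orfs Tibble from [find_best_orfs()].
#' @return Sequence tibble (`id`, `desc`, `seq`) plus a `completeness`
#'   column.
#' @export
orfs_to_proteins <- function(orfs) {
  tibble(id = paste0(orfs$transcript_id, ".p1"),
         desc = paste0("type:", orfs$completeness),
         seq = orfs$protein,
         completeness = orfs$completeness)
}
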