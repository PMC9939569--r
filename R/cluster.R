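#' Pairwise global-alignment identity and coverage
#'
#' Global (Needleman-Wunsch) alignment with unit costs (match +1,
#' mismatch -1, gap -1). Identity is identical aligned residues divided by
#' alignment length (gap columns included); coverage is the fraction of the
#' shorter sequence's residues aligned against residues (not gaps) of the
#' other.
#'
#' @param a,b Sequences (character scalars).
#' @return A list with `identity`, `coverage_shorter`, `matches`, `width`,
#'   `pairs`, `score`.
#' @export
pairwise_identity <- function(a, b) {
  st <- nw_align_stats(a, b)
  st$identity <- st$matches / st$width
  st$coverage_shorter <- st$pairs / min(nchar(a), nchar(b))
  st
}

#' Greedy near-duplicate clustering at identity/coverage thresholds
#'
#' Eliminates nearly identical sequences: sequences are processed in
#' descending length (ties broken by lexicographic id); each joins the first
#' existing representative whose global-alignment identity is at least
#' `min_identity` and whose aligned coverage of the shorter sequence is at
#' least `min_target_cov`, otherwise it founds a new cluster. The founding
#' (longest) member is the representative, so representatives always have
#' maximal length in their cluster and clusters partition the input.
#'
#' A length-ratio prefilter skips alignments that provably cannot reach the
#' identity bound (identity <= shorter/longer for any global alignment);
#' it never changes the result.
#'
#' @param records Sequence tibble (`id`, `seq`) of one alphabet.
#' @param min_identity Minimum identity fraction (default 0.98).
#' @param min_target_cov Minimum coverage of the shorter sequence
#'   (default 0.98).
#' @return A tibble with one row per input sequence: `representative_id`,
#'   `member_id`.
#' @export
cluster_sequences <- function(records, min_identity = 0.98,
                              min_target_cov = 0.98) {
  if (nrow(records) == 0) {
    return(tibble(representative_id = character(), member_id = character()))
  }
  seq_alphabet(records$seq)  # errors on mixed alphabets
  ord <- order(-nchar(records$seq), records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  lens <- nchar(seqs)
  rep_idx <- integer(0)          # indices (into ord) of representatives
  assign <- integer(length(ids)) # representative index per member
  for (i in seq_along(ids)) {
    joined <- 0L
    for (r in rep_idx) {
      # reps are at least as long as seqs[i] by processing order
      if (lens[i] < min_identity * lens[r]) next
      st <- pairwise_identity(seqs[r], seqs[i])
      if (st$identity >= min_identity &&
          st$coverage_shorter >= min_target_cov) {
        joined <- r
        break
      }
    }
    if (joined == 0L) {
      rep_idx <- c(rep_idx, i)
      joined <- i
    }
    assign[i] <- joined
  }
  tibble(representative_id = ids[assign], member_id = ids)
}
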