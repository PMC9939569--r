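#' Pair-synchronized read quality filtering
#'
#' A read fails if it contains any ambiguous base call (`N`, when `drop_n`)
#' or its arithmetic-mean PHRED score is strictly below `min_mean_q`. A pair
#' is kept only when both mates pass: both reads are discarded even when
#' only one is affected, since unpaired reads are useless for assembly.
#' Order is preserved.
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()].
#' @param min_mean_q Minimum mean PHRED score (default 20; a mean of
#'   exactly 20 passes).
#' @param drop_n Drop pairs where either mate contains an `N` (default TRUE).
#' @param species Optional species label recorded in the stats row.
#' @return A list with `kept` (the surviving pairs, same columns) and
#'   `stats` (one-row tibble: `species`, `raw_pairs`, `kept_pairs`,
#'   `retained_pct`, `lost_pct`; `lost_pct` is computed as
#'   `100 - retained_pct` so the two always sum to 100.0 after rounding).
#' @export
filter_read_pairs <- function(pairs, min_mean_q = 20, drop_n = TRUE,
                              species = NA_character_) {
  stopifnot(all(c("pair_id", "fwd_seq", "fwd_qual", "rev_seq", "rev_qual")
                %in% names(pairs)))
  pass <- function(seqs, quals) {
    ok_n <- if (drop_n) !grepl("N", seqs, fixed = TRUE) else TRUE
    ok_q <- if (nrow(pairs)) mean_phred(quals) >= min_mean_q else logical(0)
    ok_n & ok_q
  }
  keep <- if (nrow(pairs) == 0) logical(0) else
    pass(pairs$fwd_seq, pairs$fwd_qual) & pass(pairs$rev_seq, pairs$rev_qual)
  kept <- pairs[keep, , drop = FALSE]
  raw <- nrow(pairs)
  retained <- if (raw > 0) retention_percentage(raw, nrow(kept)) else NA_real_
  stats <- tibble(
    species = species,
    raw_pairs = raw,
    kept_pairs = nrow(kept),
    retained_pct = retained,
    lost_pct = if (raw > 0) 100 - retained else NA_real_
  )
  list(kept = kept, stats = stats)
}
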