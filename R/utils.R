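#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here follow the
#' conventional half-away-from-zero rule so that printed table values are
#' reproduced exactly.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage retained after a filtering step
#'
#' @param raw Count before filtering (must be positive).
#' @param kept Count after filtering, `0 <= kept <= raw`.
#' @param digits Decimal places (default 1, as reported).
#' @return `100 * kept / raw`, rounded half away from zero.
#' @export
retention_percentage <- function(raw, kept, digits = 1) {
  if (any(raw <= 0)) {
    stop("retention_percentage(): 'raw' must be positive (undefined ratio).")
  }
  if (any(kept < 0) || any(kept > raw)) {
    stop("retention_percentage(): 'kept' must satisfy 0 <= kept <= raw.")
  }
  round_half_up(100 * kept / raw, digits)
}

# Classify the alphabet of a set of sequences: "nucleotide" if every residue
# is in {A,C,G,T,N}, otherwise "protein". Errors on a mixture.
seq_alphabet <- function(seqs) {
  nuc <- !grepl("[^ACGTN]", seqs)
  if (all(nuc)) return("nucleotide")
  if (all(!nuc)) return("protein")
  stop("Mixed nucleotide and protein sequences in one input.")
}

# Internal: stop with a message listing offending ids.
stop_with_ids <- function(msg, ids) {
  stop(msg, ": ", paste(ids, collapse = ", "), call. = FALSE)
}
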