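#' Tag bait sequences in reference proteomes
#'
#' Appends a uniquely identifiable marker string to the FASTA ids of the
#' designated bait proteins so that their pairwise orthologs can be pulled
#' out of an ortholog table by simple id matching. Every bait accession must
#' occur in exactly one reference sequence id, and no untagged id may
#' already contain the marker.
#'
#' @param proteome Sequence tibble of the combined reference proteomes.
#' @param baits Tibble with columns `component` (one of
#'   [clock_components()]) and `accession` (UniProt accession embedded in
#'   the sequence id).
#' @param marker Marker string appended to bait ids (default `"SOIREF"`).
#' @return A list: `proteome` (ids of baits now carry the marker) and
#'   `registry` (tibble `component`, `accession`, `seq_id` of the tagged
#'   bait).
#' @export
tag_baits <- function(proteome, baits, marker = "SOIREF") {
  if (anyDuplicated(baits$component)) {
    stop("tag_baits(): one bait per component required.")
  }
  if (any(grepl(marker, proteome$id, fixed = TRUE))) {
    bad <- proteome$id[grepl(marker, proteome$id, fixed = TRUE)]
    stop_with_ids("Marker already present in untagged id(s)", bad)
  }
  hit_rows <- lapply(baits$accession, function(acc) {
    which(grepl(acc, proteome$id, fixed = TRUE))
  })
  n_hits <- lengths(hit_rows)
  if (any(n_hits == 0)) {
    stop_with_ids("Bait accession(s) not found in the reference proteome",
                  baits$accession[n_hits == 0])
  }
  if (any(n_hits > 1)) {
    stop_with_ids("Bait accession(s) matching multiple sequences",
                  baits$accession[n_hits > 1])
  }
  rows <- unlist(hit_rows)
  proteome$id[rows] <- paste0(proteome$id[rows], "_", marker)
  registry <- tibble(component = baits$component,
                     accession = baits$accession,
                     seq_id = proteome$id[rows])
  list(proteome = proteome, registry = registry)
}

#' Extract raw bait-ortholog candidates from a pairwise-ortholog table
#'
#' Every pair row with exactly one marker-tagged member yields a raw
#' candidate for the untagged member's species; one-to-many orthology yields
#' multiple candidates. Duplicate (species, seq, component) triples are
#' collapsed. Rows pairing two tagged baits are skipped with a warning.
#'
#' @param pair_table Tibble (`species_a`, `seq_a`, `species_b`, `seq_b`).
#' @param registry Bait registry from [tag_baits()].
#' @return Tibble of raw candidates: `species`, `seq_id`, `component`.
#' @export
extract_bait_orthologs <- function(pair_table, registry) {
  a_bait <- pair_table$seq_a %in% registry$seq_id
  b_bait <- pair_table$seq_b %in% registry$seq_id
  both <- a_bait & b_bait
  if (any(both)) {
    warning(sum(both), " pair row(s) join two tagged baits; skipped.")
  }
  one <- xor(a_bait, b_bait)
  pt <- pair_table[one, , drop = FALSE]
  is_a <- a_bait[one]
  comp <- setNames(registry$component, registry$seq_id)
  tibble(
    species = ifelse(is_a, pt$species_b, pt$species_a),
    seq_id = ifelse(is_a, pt$seq_b, pt$seq_a),
    component = unname(comp[ifelse(is_a, pt$seq_a, pt$seq_b)])
  ) |>
    dplyr::distinct()
}
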