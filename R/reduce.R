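#' Reduce a transcriptome assembly to a representative gene catalog
#'
#' The assembly-optimization workflow, applied to one species' assembly:
#'
#' 1. drop transcripts shorter than `min_len` nucleotides;
#' 2. predict the single best ORF per transcript ([find_best_orf()]) and
#'    tag its completeness;
#' 3. cluster the (length-filtered) transcripts at `min_identity` /
#'    `min_target_cov` ([cluster_sequences()]) and keep only cluster
#'    representatives, removing nearly identical sequences;
#' 4. keep the longest protein isoform per Trinity gene
#'    ([select_longest_isoform()]);
#' 5. extract the final transcripts corresponding to the kept proteins.
#'
#' @param transcripts Sequence tibble of the initial assembly (`id`, `seq`),
#'   Trinity-style ids.
#' @param min_len Minimum transcript length (default 200 nt).
#' @param min_aa Minimum ORF protein length (default 100).
#' @param min_identity,min_target_cov Clustering thresholds (default 0.98).
#' @return An object of class `assembly_reduction`: a list with `proteins`
#'   (final proteome tibble incl. `completeness`), `final_transcripts`,
#'   `orfs`, `clusters`, `selection_map`, and `counts` (per-step survivor
#'   counts).
#' @export
reduce_assembly <- function(transcripts, min_len = 200L, min_aa = 100L,
                            min_identity = 0.98, min_target_cov = 0.98) {
  filtered <- filter_min_length(transcripts, min_len)
  orfs <- find_best_orfs(filtered, min_aa)
  proteins <- orfs_to_proteins(orfs)
  clusters <- cluster_sequences(filtered[, c("id", "seq")],
                                min_identity, min_target_cov)
  reps <- unique(clusters$representative_id)
  with_orf <- proteins[strip_orf_suffix(proteins$id) %in% reps, ,
                       drop = FALSE]
  sel <- select_longest_isoform(with_orf)
  final_tr <- extract_final_transcripts(filtered, sel$kept$id)
  structure(list(
    proteins = sel$kept,
    final_transcripts = final_tr,
    orfs = orfs,
    clusters = clusters,
    selection_map = sel$selection_map,
    counts = tibble(
      step = c("input", "min_length", "orf", "cluster_rep", "isoform"),
      n = c(nrow(transcripts), nrow(filtered), nrow(proteins),
            nrow(with_orf), nrow(sel$kept)))
  ), class = "assembly_reduction")
}

#' @export
print.assembly_reduction <- function(x, ...) {
  cat("Assembly reduction:\n")
  print(x$counts)
  invisible(x)
}

#' @rdname reduce_assembly
#' @param x An `assembly_reduction` object.
#' @param ... Unused.
#' @method tidy assembly_reduction
#' @export
tidy.assembly_reduction <- function(x, ...) {
  tibble(id = x$proteins$id, completeness = x$proteins$completeness,
         transcript_id = strip_orf_suffix(x$proteins$id))
}

#' @rdname reduce_assembly
#' @method glance assembly_reduction
#' @export
glance.assembly_reduction <- function(x, ...) {
  tibble(
    n_input = x$counts$n[x$counts$step == "input"],
    n_final = nrow(x$proteins),
    pct_of_initial = retention_percentage(
      x$counts$n[x$counts$step == "input"], nrow(x$proteins)),
    n50_final = compute_n50(nchar(x$final_transcripts$seq)),
    pct_complete_orfs = pct_complete_orfs(x$proteins)
  )
}
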