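#' Select the longest protein isoform per Trinity gene
#'
#' Trinity groups isoforms of one hypothetical gene under a shared gene key
#' (`DN<d>_c<d>_g<d>`). Per gene, the longest protein is retained as the
#' representative; ties are broken by smallest isoform index, then
#' lexicographic id.
#'
#' @param proteins Sequence tibble (`id`, `seq`, ...) whose ids are Trinity
#'   protein ids (`TRINITY_..._i<d>.p<d>`).
#' @return A list with `kept` (one protein per gene key, input order
#'   preserved) and `selection_map` (tibble `gene_key`, `kept_id`,
#'   `discarded_id`; one row per discarded isoform).
#' @export
select_longest_isoform <- function(proteins) {
  parsed <- parse_trinity_id(proteins$id)  # errors listing unparseable ids
  df <- dplyr::mutate(proteins,
                      gene_key = parsed$gene_key,
                      isoform_index = parsed$isoform_index,
                      .len = nchar(.data$seq),
                      .row = dplyr::row_number())
  winners <- df |>
    dplyr::arrange(dplyr::desc(.data$.len), .data$isoform_index, .data$id) |>
    dplyr::distinct(.data$gene_key, .keep_all = TRUE)
  kept_ids <- winners$id
  kept <- df[df$id %in% kept_ids, names(proteins), drop = FALSE]
  map <- df |>
    dplyr::left_join(winners[, c("gene_key", "id")],
                     by = "gene_key", suffix = c("", "_kept")) |>
    dplyr::filter(.data$id != .data$id_kept) |>
    dplyr::transmute(gene_key = .data$gene_key, kept_id = .data$id_kept,
                     discarded_id = .data$id)
  list(kept = kept, selection_map = as_tibble(map))
}

#' Extract final transcripts for selected proteins
#'
#' Maps each kept protein id back to its source transcript (by dropping the
#' `.p` suffix) and pulls exactly those transcripts from the initial
#' assembly, in assembly order.
#'
#' @param initial_transcriptome Sequence tibble of the initial assembly.
#' @param kept_protein_ids Character vector of protein ids.
#' @return Sequence tibble with one transcript per kept protein.
#' @export
extract_final_transcripts <- function(initial_transcriptome, kept_protein_ids) {
  wanted <- strip_orf_suffix(kept_protein_ids)
  missing <- setdiff(wanted, initial_transcriptome$id)
  if (length(missing)) {
    stop_with_ids("Transcript(s) missing from the initial assembly", missing)
  }
  initial_transcriptome[initial_transcriptome$id %in% wanted, , drop = FALSE]
}
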