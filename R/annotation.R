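#' Best homology hit per query at an E-value cutoff
#'
#' Hits above `max_evalue` are discarded; per query the minimum-E-value hit
#' is the definitive homolog, with ties broken by higher bitscore, then
#' lexicographic target id. Queries with no surviving hit are simply absent.
#'
#' @param hits Hit tibble (`query`, `target`, `evalue`, `bitscore`, ...).
#' @param max_evalue E-value cutoff (default 1e-5; hits at exactly the
#'   cutoff survive).
#' @return One-row-per-query tibble of best hits.
#' @export
best_hit_per_query <- function(hits, max_evalue = 1e-5) {
  hits |>
    dplyr::filter(.data$evalue <= max_evalue) |>
    dplyr::arrange(.data$query, .data$evalue,
                   dplyr::desc(.data$bitscore), .data$target) |>
    dplyr::distinct(.data$query, .keep_all = TRUE)
}

#' Merge homology and orthology annotations
#'
#' One record per sequence in the universe, flagging which source(s)
#' annotated it. Any non-empty orthology-mapper row counts as an annotation
#' from that source. No coverage cutoff is applied, so short sequences can
#' still receive annotations.
#'
#' @param best_hits Best Swiss-Prot-style hits from [best_hit_per_query()].
#' @param eggnog_table Tibble with `seq_id` and optional `ortholog`,
#'   `gos`, `pfams` columns (orthology-mapper style output).
#' @param all_seq_ids Character vector: the annotation universe.
#' @return A list of class `clock_annotations`: `table` (one row per
#'   sequence: `seq_id`, `swissprot_target`, `swissprot_evalue`,
#'   `swissprot_bitscore`, `eggnog_ortholog`, `annotated_by`) and `rates`
#'   (tibble `source`, `n`, `pct`, percentages to 1 decimal).
#' @export
merge_annotations <- function(best_hits, eggnog_table, all_seq_ids) {
  n_univ <- length(all_seq_ids)
  if (n_univ == 0) stop("merge_annotations(): empty sequence universe.")
  unknown <- setdiff(eggnog_table$seq_id, all_seq_ids)
  if (length(unknown)) {
    warning("Orthology rows for sequence(s) outside the universe: ",
            paste(head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
  }
  sp <- best_hits |>
    dplyr::transmute(seq_id = .data$query,
                     swissprot_target = .data$target,
                     swissprot_evalue = .data$evalue,
                     swissprot_bitscore = .data$bitscore)
  eg <- eggnog_table |>
    dplyr::distinct(.data$seq_id, .keep_all = TRUE) |>
    dplyr::transmute(seq_id = .data$seq_id,
                     eggnog_ortholog = if ("ortholog" %in% names(eggnog_table))
                       .data$ortholog else NA_character_,
                     .eggnog = TRUE)
  table <- tibble(seq_id = all_seq_ids) |>
    dplyr::left_join(sp, by = "seq_id") |>
    dplyr::left_join(eg, by = "seq_id") |>
    dplyr::mutate(
      .swiss = !is.na(.data$swissprot_target),
      .eggnog = !is.na(.data$.eggnog),
      annotated_by = dplyr::case_when(
        .data$.swiss & .data$.eggnog ~ "swissprot,eggnog",
        .data$.swiss ~ "swissprot",
        .data$.eggnog ~ "eggnog",
        TRUE ~ ""
      )
    )
  rates <- tibble(
    source = c("swissprot", "eggnog", "either"),
    n = c(sum(table$.swiss), sum(table$.eggnog),
          sum(table$.swiss | table$.eggnog))
  )
  rates$pct <- round_half_up(100 * rates$n / n_univ, 1)
  table <- dplyr::select(table, -".swiss", -".eggnog")
  structure(list(table = as_tibble(table), rates = rates, n = n_univ),
            class = "clock_annotations")
}

#' @export
print.clock_annotations <- function(x, ...) {
  cat("Merged annotations for", x$n, "sequences\n")
  print(x$rates)
  invisible(x)
}

#' @rdname merge_annotations
#' @param x A `clock_annotations` object.
#' @param ... Unused.
#' @method tidy clock_annotations
#' @export
tidy.clock_annotations <- function(x, ...) x$table

#' @rdname merge_annotations
#' @method glance clock_annotations
#' @export
glance.clock_annotations <- function(x, ...) {
  tibble(n_sequences = x$n,
         pct_swissprot = x$rates$pct[x$rates$source == "swissprot"],
         pct_eggnog = x$rates$pct[x$rates$source == "eggnog"],
         pct_either = x$rates$pct[x$rates$source == "either"])
}
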