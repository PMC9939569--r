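#' Compute the N50 of a set of contig lengths
#'
#' Contigs of length greater than or equal to the N50 contain at least half
#' of all assembled bases: lengths are sorted in descending order and the
#' N50 is the length at which the cumulative sum first reaches half the
#' total. When the half-total falls exactly on a boundary, the larger
#' (earlier) length is returned.
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The N50 (same units as `lengths`).
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("compute_n50(): empty length list.")
  if (any(lengths <= 0)) stop("compute_n50(): lengths must be positive.")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Percentage of complete ORFs
#'
#' @param orfs Tibble with a `completeness` column (tags `cmp`, `5p`, `3p`,
#'   `int`).
#' @return Percent of ORFs tagged `cmp`, rounded half away from zero to
#'   1 decimal.
#' @export
pct_complete_orfs <- function(orfs) {
  if (nrow(orfs) == 0) stop("pct_complete_orfs(): empty ORF list.")
  round_half_up(100 * mean(orfs$completeness == "cmp"), 1)
}

#' Summarize per-species assembly statistics across phases
#'
#' Arithmetic means per phase of the transcript count, N50 and (for the
#' final phase) the percentage of initial transcripts retained. N50 and
#' transcript-count means are rounded to the nearest integer, percentage
#' means to 2 decimals.
#'
#' @param stats Tibble with columns `species`, `phase` (`initial`/`final`),
#'   `n_transcripts`, `n50`, and optionally `pct_of_initial` and
#'   `pct_complete_orfs`.
#' @return A tibble with one row per phase: `phase`, `n_species`,
#'   `mean_n_transcripts`, `mean_n50`, `mean_pct_of_initial`,
#'   `mean_pct_complete_orfs` (NA where the column is absent/NA).
#' @export
summarize_assemblies <- function(stats) {
  missing_phase <- setdiff(c("initial", "final"), unique(stats$phase))
  if (length(missing_phase)) {
    stop("summarize_assemblies(): no rows for phase(s): ",
         paste(missing_phase, collapse = ", "))
  }
  if (!"pct_of_initial" %in% names(stats)) stats$pct_of_initial <- NA_real_
  if (!"pct_complete_orfs" %in% names(stats)) {
    stats$pct_complete_orfs <- NA_real_
  }
  stats |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      mean_n_transcripts = round_half_up(mean(.data$n_transcripts), 0),
      mean_n50 = round_half_up(mean(.data$n50), 0),
      mean_pct_of_initial = round_half_up(mean(.data$pct_of_initial), 2),
      mean_pct_complete_orfs = round_half_up(mean(.data$pct_complete_orfs), 2),
      .groups = "drop"
    )
}

#' Per-assembly statistics row
#'
#' Convenience constructor for one phase of one species.
#'
#' @param species Species label.
#' @param phase `"initial"` or `"final"`.
#' @param transcripts Sequence tibble of the assembly.
#' @param n_initial Transcript count of the initial assembly (for
#'   `pct_of_initial` in the final phase; optional).
#' @param orfs Optional ORF tibble for the complete-ORF percentage.
#' @return One-row tibble matching [summarize_assemblies()] input.
#' @export
assembly_stats_row <- function(species, phase, transcripts,
                               n_initial = NA_integer_, orfs = NULL) {
  tibble(
    species = species,
    phase = phase,
    n_transcripts = nrow(transcripts),
    n50 = compute_n50(nchar(transcripts$seq)),
    pct_of_initial = if (!is.na(n_initial)) {
      retention_percentage(n_initial, nrow(transcripts))
    } else NA_real_,
    pct_complete_orfs = if (!is.null(orfs) && nrow(orfs) > 0) {
      pct_complete_orfs(orfs)
    } else NA_real_
  )
}
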