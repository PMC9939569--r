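# TSV dialect readers. All tables are tab-delimited UTF-8 with a header row;
# lines starting with '#' are comments (OrthoFinder/InterProScan convention).
# Unknown columns are preserved; required columns are checked by name and
# numeric fields are validated row by row so errors carry a line number.

read_tsv_dialect <- function(path, required, numeric_cols = character()) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("Non-numeric value in column '", col, "' of ", path,
           " at data row ", bad[1], ": '", df[[col]][bad[1]], "'")
    }
    df[[col]] <- parsed
  }
  as_tibble(df)
}

#' Read a pairwise-ortholog table
#'
#' One row per inferred ortholog pair between two sequence sets, in the
#' style of OrthoFinder's pairwise-orthologs output. Columns: `species_a`,
#' `seq_a`, `species_b`, `seq_b`. Bait sequences are recognizable by the
#' marker string embedded in their ids.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_pair_table <- function(path) {
  read_tsv_dialect(path, c("species_a", "seq_a", "species_b", "seq_b"))
}

#' Read a domain annotation table
#'
#' InterProScan-style rows: `seq_id`, `db` (one of Pfam, SMART, CDD),
#' `accession`, `name`, `start`, `end` (1-based inclusive amino-acid
#' coordinates), `evalue`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with numeric `start`, `end`, `evalue`.
#' @export
read_domain_table <- function(path) {
  df <- read_tsv_dialect(path,
                         c("seq_id", "db", "accession", "name", "start", "end", "evalue"),
                         numeric_cols = c("start", "end", "evalue"))
  bad <- setdiff(unique(df$db), c("Pfam", "SMART", "CDD"))
  if (length(bad)) {
    stop("Unknown domain database(s): ", paste(bad, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Read a protein family table
#'
#' PANTHER-style assignments: `seq_id`, `family_acc` (`PTHR#####`) and an
#' optional `subfamily_acc` (`PTHR#####:SF#`, may be empty).
#'
#' @param path Path to a TSV file.
#' @return A tibble; empty subfamily strings become `NA`.
#' @export
read_family_table <- function(path) {
  df <- read_tsv_dialect(path, c("seq_id", "family_acc"))
  if (!"subfamily_acc" %in% names(df)) df$subfamily_acc <- NA_character_
  df$subfamily_acc[!is.na(df$subfamily_acc) & df$subfamily_acc == ""] <- NA_character_
  df
}

#' Read a homology-search hit table
#'
#' Columns: `query`, `target`, `evalue`, `bitscore`, `qcov`, `tcov`
#' (coverages as fractions in [0, 1]).
#'
#' @param path Path to a TSV file.
#' @return A tibble with numeric score/coverage columns.
#' @export
read_hit_table <- function(path) {
  df <- read_tsv_dialect(path,
                         c("query", "target", "evalue", "bitscore", "qcov", "tcov"),
                         numeric_cols = c("evalue", "bitscore", "qcov", "tcov"))
  if (any(df$qcov < 0 | df$qcov > 1 | df$tcov < 0 | df$tcov > 1, na.rm = TRUE)) {
    stop("Coverage values must be fractions in [0, 1] in ", path)
  }
  df
}

#' Read a BUSCO summary table
#'
#' Parsed, never computed: `lineage`, `complete_single`, `complete_dup`,
#' `fragmented`, `missing`, `total`. Completeness is reported as
#' single-copy + duplicated over total.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a derived `pct_complete` column (percent).
#' @export
read_busco_summary <- function(path) {
  df <- read_tsv_dialect(path,
                         c("lineage", "complete_single", "complete_dup",
                           "fragmented", "missing", "total"),
                         numeric_cols = c("complete_single", "complete_dup",
                                          "fragmented", "missing", "total"))
  df$pct_complete <- round_half_up(
    100 * (df$complete_single + df$complete_dup) / df$total, 1)
  df
}
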