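#' Parse Trinity-style sequence identifiers
#'
#' Trinity groups assembled transcripts into gene clusters: an id of the form
#' `TRINITY_DN<d>_c<d>_g<d>_i<d>` identifies gene cluster `DN<d>_c<d>_g<d>`
#' and isoform `i<d>`; a trailing `.p<d>` marks a predicted protein (ORF)
#' on that transcript.
#'
#' @param raw Character vector of ids.
#' @return A tibble with one row per id: `raw`, `gene_key`, `isoform_index`,
#'   `orf_index` (`NA` when no `.p` suffix is present).
#' @examples
#' parse_trinity_id("TRINITY_DN15555_c0_g1_i1.p1")
#' @export
parse_trinity_id <- function(raw) {
  pat <- "^TRINITY_(DN[0-9]+_c[0-9]+_g[0-9]+)_i([0-9]+)(\\.p([0-9]+))?$"
  ok <- grepl(pat, raw)
  if (!all(ok)) {
    stop_with_ids("Malformed Trinity id(s)", raw[!ok])
  }
  tibble(
    raw = raw,
    gene_key = sub(pat, "\\1", raw),
    isoform_index = as.integer(sub(pat, "\\2", raw)),
    orf_index = ifelse(grepl("\\.p[0-9]+$", raw),
                       as.integer(sub(pat, "\\4", raw)), NA_integer_)
  )
}

#' Format parsed Trinity ids back into raw strings
#'
#' Inverse of [parse_trinity_id()]: formatting a parsed id reproduces the
#' raw string exactly.
#'
#' @param parsed A tibble as returned by [parse_trinity_id()].
#' @return Character vector of ids.
#' @export
format_trinity_id <- function(parsed) {
  paste0("TRINITY_", parsed$gene_key, "_i", parsed$isoform_index,
         ifelse(is.na(parsed$orf_index), "",
                paste0(".p", parsed$orf_index)))
}

# transcript id of a protein id (drop the .p suffix); used when mapping
# selected proteins back to their source transcripts.
strip_orf_suffix <- function(ids) {
  sub("\\.p[0-9]+$", "", ids)
}
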