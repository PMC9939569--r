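#' Read a FASTA file into a tibble
#'
#' The id is the first whitespace-delimited token of the header; the rest is
#' kept as the description. Duplicate ids are an error (downstream joins are
#' keyed by id).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  seqs <- as.character(x)
  if (any(nchar(seqs) == 0)) {
    stop_with_ids("Empty FASTA record(s)", ids[nchar(seqs) == 0])
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop_with_ids("Duplicate FASTA id(s)", dup)
  tibble(id = ids, desc = desc, seq = unname(seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param line_width Residues per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  x <- Biostrings::BStringSet(records$seq)
  desc <- if ("desc" %in% names(records)) records$desc else
    rep("", nrow(records))
  names(x) <- ifelse(is.na(desc) | desc == "", records$id,
                     paste(records$id, desc))
  Biostrings::writeXStringSet(x, path, width = line_width)
  invisible(path)
}

#' Read synchronized paired FASTQ files
#'
#' Qualities are PHRED+33; other encodings are not supported. The two files
#' must list mates in the same order; the pair id is the read id with any
#' trailing `/1` or `/2` stripped, and must agree between mates.
#'
#' @param fwd_path,rev_path Paths to the forward and reverse FASTQ files.
#' @return A tibble with columns `pair_id`, `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`.
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  fwd <- read_fastq_one(fwd_path)
  rev <- read_fastq_one(rev_path)
  if (nrow(fwd) != nrow(rev)) {
    stop("Paired FASTQ files differ in read count: ",
         nrow(fwd), " vs ", nrow(rev), ".")
  }
  fid <- sub("/[12]$", "", fwd$id)
  rid <- sub("/[12]$", "", rev$id)
  bad <- which(fid != rid)
  if (length(bad)) {
    stop("Desynchronized read pair at record ", bad[1], ": '",
         fwd$id[bad[1]], "' vs '", rev$id[bad[1]], "'.")
  }
  tibble(pair_id = fid,
         fwd_seq = fwd$seq, fwd_qual = fwd$qual,
         rev_seq = rev$seq, rev_qual = rev$qual)
}

read_fastq_one <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- as.character(x)
  if (any(nchar(qual) != nchar(seqs))) {
    stop("FASTQ record with quality/sequence length mismatch in ", path)
  }
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(seqs),
         qual = unname(qual))
}

#' Write paired reads to two FASTQ files
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()].
#' @param fwd_path,rev_path Output paths.
#' @return `c(fwd_path, rev_path)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, fwd_path, rev_path) {
  write_fastq_one(pairs$pair_id, pairs$fwd_seq, pairs$fwd_qual, fwd_path, "/1")
  write_fastq_one(pairs$pair_id, pairs$rev_seq, pairs$rev_qual, rev_path, "/2")
  invisible(c(fwd_path, rev_path))
}

write_fastq_one <- function(ids, seqs, quals, path, mate_suffix) {
  lines <- character(4L * length(ids))
  if (length(ids)) {
    idx <- seq_along(ids)
    lines[4 * idx - 3] <- paste0("@", ids, mate_suffix)
    lines[4 * idx - 2] <- seqs
    lines[4 * idx - 1] <- "+"
    lines[4 * idx] <- quals
  }
  writeLines(lines, path)
  invisible(path)
}

# Mean PHRED score (arithmetic mean of per-base integers, +33 encoding).
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}
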