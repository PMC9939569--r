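#' Display label for a candidate or bait track
#'
#' Candidates are labelled `"<Species> <seq_id> (<tag>) (<phylum>)"` with the
#' ORF completeness tag (`cmp`, `5p`, `3p`, `int`) and a phylum abbreviation
#' (e.g. Ar for Arthropoda). Baits are reference proteins, not predicted
#' ORFs, so their label carries no tag parentheses.
#'
#' @param species Species display name.
#' @param seq_id Sequence id.
#' @param completeness Completeness tag; ignored for baits.
#' @param phylum_code Phylum abbreviation; ignored for baits.
#' @param is_bait Bait track (default FALSE).
#' @return Character label.
#' @export
label_candidate <- function(species, seq_id, completeness = NULL,
                            phylum_code = NULL, is_bait = FALSE) {
  if (is_bait) return(paste(species, seq_id))
  if (is.null(completeness) ||
      !all(completeness %in% c("cmp", "5p", "3p", "int"))) {
    stop("Unknown completeness tag: ",
         paste(setdiff(completeness, c("cmp", "5p", "3p", "int")),
               collapse = ", "))
  }
  paste0(species, " ", seq_id, " (", completeness, ") (", phylum_code, ")")
}

#' Domain-architecture track set
#'
#' Container for one component's domain-structure diagram: one horizontal
#' track per sequence, the bait topmost, domains drawn as labelled boxes at
#' a common per-residue scale.
#'
#' @param tracks Tibble with `label`, `length` (aa), `is_bait`.
#' @param domains Tibble with `label` (matching a track), `accession`,
#'   `name`, `start`, `end` (1-based inclusive aa coordinates), `db`
#'   (Pfam/SMART/CDD).
#' @return An object of class `domain_tracks`.
#' @export
domain_tracks <- function(tracks, domains) {
  stopifnot(nrow(tracks) >= 1)
  bad <- setdiff(domains$label, tracks$label)
  if (length(bad)) stop_with_ids("Domain row(s) for unknown track(s)", bad)
  tl <- setNames(tracks$length, tracks$label)
  over <- domains$end > unname(tl[domains$label]) | domains$start < 1 |
    domains$start > domains$end
  if (any(over)) {
    stop("Domain coordinates outside track length for: ",
         paste(unique(domains$label[over]), collapse = ", "))
  }
  # bait tracks first, then input order
  ord <- order(!tracks$is_bait)
  structure(list(tracks = tracks[ord, , drop = FALSE],
                 domains = domains), class = "domain_tracks")
}

# Stable colour per accession: a pure function of the sorted accession set.
domain_palette <- function(accessions) {
  accs <- sort(unique(accessions))
  setNames(grDevices::hcl.colors(max(length(accs), 2), "Dark 3")[
    seq_along(accs)], accs)
}

#' Render a domain-structure diagram to SVG
#'
#' Deterministic vector output: identical input yields byte-identical files.
#' One horizontal track per sequence at a common per-residue scale, bait
#' topmost; domains are boxes coloured by accession (colour assignment is a
#' pure function of the sorted accession set); annotations from different
#' databases are stacked as thin sub-bars within the track rather than
#' merged.
#'
#' @param x A [domain_tracks()] object.
#' @param out_path Output file path (`.svg`).
#' @return `out_path`, invisibly.
#' @export
render_domain_diagram <- function(x, out_path) {
  stopifnot(inherits(x, "domain_tracks"))
  tracks <- x$tracks
  domains <- x$domains
  pal <- domain_palette(domains$accession)
  label_w <- 360; plot_w <- 620; margin <- 10
  track_h <- 16; gap <- 22
  scale <- plot_w / max(tracks$length)
  width <- label_w + plot_w + 2 * margin
  height <- margin * 2 + nrow(tracks) * (track_h + gap)
  db_levels <- c("Pfam", "SMART", "CDD")

  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif" font-size="11">',
    width, as.integer(height)))
  for (i in seq_len(nrow(tracks))) {
    y0 <- margin + (i - 1) * (track_h + gap)
    x0 <- label_w + margin
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s">%s</text>',
      fmt(margin), fmt(y0 + track_h - 4), esc(tracks$label[i])))
    lines <- c(lines, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="#d9d9d9"/>',
      fmt(x0), fmt(y0 + track_h / 2 - 2),
      fmt(tracks$length[i] * scale), fmt(4)))
    dom <- domains[domains$label == tracks$label[i], , drop = FALSE]
    if (nrow(dom) == 0) next
    dom <- dom[order(dom$db, dom$accession, dom$start), , drop = FALSE]
    n_db <- length(db_levels)
    for (j in seq_len(nrow(dom))) {
      lev <- match(dom$db[j], db_levels)
      if (is.na(lev)) lev <- 1L
      sub_h <- track_h / n_db
      lines <- c(lines, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s</title></rect>',
        fmt(x0 + (dom$start[j] - 1) * scale),
        fmt(y0 + (lev - 1) * sub_h),
        fmt((dom$end[j] - dom$start[j] + 1) * scale),
        fmt(sub_h),
        pal[dom$accession[j]],
        esc(paste0(dom$accession[j], " ", dom$name[j], " ",
                   dom$start[j], "-", dom$end[j], " [", dom$db[j], "]"))))
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" font-size="8">%s</text>',
        fmt(x0 + (dom$start[j] - 1) * scale),
        fmt(y0 + track_h + 8),
        esc(dom$name[j])))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out_path)
  invisible(out_path)
}

#' Domain-architecture diagram as a ggplot
#'
#' @param object A [domain_tracks()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domain_tracks
#' @export
autoplot.domain_tracks <- function(object, ...) {
  tracks <- object$tracks
  domains <- object$domains
  tracks$y <- rev(seq_len(nrow(tracks)))
  domains <- dplyr::left_join(domains, tracks[, c("label", "y")],
                              by = "label")
  pal <- domain_palette(domains$accession)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tracks,
      ggplot2::aes(x = 1, xend = .data$length, y = .data$y, yend = .data$y),
      linewidth = 1, colour = "grey70") +
    ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                   fill = .data$accession)) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_continuous(breaks = tracks$y, labels = tracks$label) +
    ggplot2::labs(x = "position (aa)", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}
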