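#' Vet raw ortholog candidates with the Pfam/PANTHER cascade
#'
#' Four ordered filters applied to the raw pairwise-ortholog candidates:
#'
#' * **S1 dual annotation** -- drop candidates lacking either a Pfam domain
#'   annotation or a PANTHER family assignment;
#' * **S2 shared domain** -- drop candidates sharing no Pfam accession with
#'   their bait;
#' * **S3 same family** -- drop candidates whose PANTHER family differs from
#'   the bait's;
#' * **S4 subfamily preference** -- per (species, component): if at least
#'   one survivor shares the bait's subfamily, keep only those; otherwise
#'   keep all survivors.
#'
#' Stage failures are monotone: a candidate failing stage k is never
#' evaluated at later stages. Bait annotations (domains, family, subfamily)
#' are taken from the same domain/family tables; a bait without a family or
#' Pfam annotation is a configuration error because the cascade is undefined
#' for it.
#'
#' @param raw_candidates Tibble from [extract_bait_orthologs()] (columns
#'   `species`, `seq_id`, `component`; an optional `completeness` column is
#'   carried through).
#' @param domain_table Domain tibble ([read_domain_table()] dialect)
#'   covering candidates and baits.
#' @param family_table Family tibble ([read_family_table()] dialect).
#' @param registry Bait registry from [tag_baits()].
#' @return An object of class `clock_candidates`: a list with `candidates`
#'   (the audit tibble: per candidate `retained`, `failed_stage`, `reason`,
#'   `family_acc`, `subfamily_acc`, `swissprot_confirmed` placeholder) and
#'   `registry` (with bait annotation columns attached).
#' @export
vet_candidates <- function(raw_candidates, domain_table, family_table,
                           registry) {
  pfam <- domain_table[domain_table$db == "Pfam", , drop = FALSE]
  pfam_sets <- split(pfam$accession, pfam$seq_id)
  fam <- family_table |> dplyr::distinct(.data$seq_id, .keep_all = TRUE)
  fam_acc <- setNames(fam$family_acc, fam$seq_id)
  fam_sub <- setNames(fam$subfamily_acc, fam$seq_id)

  bait_pfam <- lapply(registry$seq_id, function(id) unique(pfam_sets[[id]]))
  bait_family <- unname(fam_acc[registry$seq_id])
  bait_subfam <- unname(fam_sub[registry$seq_id])
  bad <- lengths(bait_pfam) == 0 | is.na(bait_family)
  if (any(bad)) {
    stop_with_ids(
      "Bait(s) without Pfam domain or PANTHER family annotation (cascade undefined)",
      registry$seq_id[bad])
  }
  names(bait_pfam) <- registry$component
  bait_fam_by_comp <- setNames(bait_family, registry$component)
  bait_sub_by_comp <- setNames(bait_subfam, registry$component)

  cand <- raw_candidates
  if (!"completeness" %in% names(cand)) cand$completeness <- NA_character_
  cand$family_acc <- unname(fam_acc[cand$seq_id])
  cand$subfamily_acc <- unname(fam_sub[cand$seq_id])
  has_pfam <- cand$seq_id %in% names(pfam_sets)
  has_family <- !is.na(cand$family_acc)

  n <- nrow(cand)
  failed_stage <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  # S1: dual annotation presence
  s1_fail <- !(has_pfam & has_family)
  failed_stage[s1_fail] <- "S1"
  reason[s1_fail] <- ifelse(!has_pfam[s1_fail] & !has_family[s1_fail],
                            "no Pfam and no PANTHER annotation",
                            ifelse(!has_pfam[s1_fail], "no Pfam annotation",
                                   "no PANTHER annotation"))

  # S2: at least one Pfam accession shared with the bait
  alive <- is.na(failed_stage)
  shares <- vapply(seq_len(n), function(i) {
    if (!alive[i]) return(FALSE)
    length(intersect(pfam_sets[[cand$seq_id[i]]],
                     bait_pfam[[cand$component[i]]])) > 0
  }, logical(1))
  s2_fail <- alive & !shares
  failed_stage[s2_fail] <- "S2"
  reason[s2_fail] <- "no Pfam domain shared with bait"

  # S3: same PANTHER family as the bait
  alive <- is.na(failed_stage)
  same_fam <- cand$family_acc == unname(bait_fam_by_comp[cand$component])
  s3_fail <- alive & !same_fam
  failed_stage[s3_fail] <- "S3"
  reason[s3_fail] <- "PANTHER family differs from bait"

  # S4: subfamily preference within each (species, component)
  alive <- is.na(failed_stage)
  bait_sub <- unname(bait_sub_by_comp[cand$component])
  sub_match <- alive & !is.na(bait_sub) & !is.na(cand$subfamily_acc) &
    cand$subfamily_acc == bait_sub
  grp <- paste(cand$species, cand$component, sep = "\r")
  grp_has_match <- tapply(sub_match, grp, any)
  s4_fail <- alive & unname(grp_has_match[grp]) & !sub_match
  failed_stage[s4_fail] <- "S4"
  reason[s4_fail] <- "same-family sibling matches the bait subfamily"

  cand$failed_stage <- failed_stage
  cand$reason <- reason
  cand$retained <- is.na(failed_stage)
  cand$swissprot_confirmed <- NA

  registry$pfam_accessions <- unname(lapply(
    registry$component, function(cp) bait_pfam[[cp]]))
  registry$family_acc <- bait_family
  registry$subfamily_acc <- bait_subfam
  structure(list(candidates = cand, registry = registry),
            class = "clock_candidates")
}

#' Flag candidates whose best Swiss-Prot homolog is a known clock protein
#'
#' A report-only confirmation: the flag is set when the candidate's best
#' Swiss-Prot hit is on the supplied whitelist of clock (or closely related)
#' accessions. Candidates are never removed at this step -- all sequences
#' cleared by the cascade remain potential candidates; the flag is logged
#' for manual review.
#'
#' @param vetted A `clock_candidates` object from [vet_candidates()].
#' @param best_hits Best-hit tibble from [best_hit_per_query()] keyed by
#'   candidate `seq_id` in `query`.
#' @param whitelist Character vector of accepted Swiss-Prot accessions
#'   (matched against the hit target by substring, so `sp|...|...` style
#'   target ids work).
#' @return The `clock_candidates` object with `swissprot_confirmed` filled.
#' @export
confirm_swissprot <- function(vetted, best_hits, whitelist) {
  stopifnot(inherits(vetted, "clock_candidates"))
  cand <- vetted$candidates
  tgt <- setNames(best_hits$target, best_hits$query)
  hit <- unname(tgt[cand$seq_id])
  confirmed <- !is.na(hit) & vapply(hit, function(t) {
    if (is.na(t) || length(whitelist) == 0) return(FALSE)
    any(vapply(whitelist, grepl, logical(1), x = t, fixed = TRUE))
  }, logical(1))
  cand$swissprot_confirmed <- unname(confirmed)
  vetted$candidates <- cand
  vetted
}

#' Species-by-component matrix of retained candidate counts
#'
#' @param vetted A `clock_candidates` object, or a plain candidate tibble
#'   with a `retained` column (or none, in which case all rows count).
#' @param components Column order (default [clock_components()]).
#' @return A tibble with `species` plus one integer column per component;
#'   `NA` marks species/component cells with no retained candidate.
#' @export
candidate_matrix <- function(vetted, components = clock_components()) {
  cand <- if (inherits(vetted, "clock_candidates")) {
    vetted$candidates
  } else {
    vetted
  }
  if ("retained" %in% names(cand)) cand <- cand[cand$retained, , drop = FALSE]
  counts <- cand |>
    dplyr::count(.data$species, .data$component)
  wide <- tidyr::pivot_wider(counts, names_from = "component",
                             values_from = "n")
  for (cp in setdiff(components, names(wide))) wide[[cp]] <- NA_integer_
  wide <- wide[, c("species", components), drop = FALSE]
  dplyr::arrange(wide, .data$species)
}

#' @export
print.clock_candidates <- function(x, ...) {
  cand <- x$candidates
  cat("Clock protein candidates:", nrow(cand), "raw,",
      sum(cand$retained), "retained after vetting\n")
  stages <- table(factor(cand$failed_stage, levels = paste0("S", 1:4)))
  cat("Dropped per stage:",
      paste(names(stages), stages, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname vet_candidates
#' @param x A `clock_candidates` object.
#' @param ... Unused.
#' @method tidy clock_candidates
#' @export
tidy.clock_candidates <- function(x, ...) as_tibble(x$candidates)

#' @rdname vet_candidates
#' @method glance clock_candidates
#' @export
glance.clock_candidates <- function(x, ...) {
  cand <- x$candidates
  tibble(
    n_raw = nrow(cand),
    n_retained = sum(cand$retained),
    n_s1 = sum(cand$failed_stage == "S1", na.rm = TRUE),
    n_s2 = sum(cand$failed_stage == "S2", na.rm = TRUE),
    n_s3 = sum(cand$failed_stage == "S3", na.rm = TRUE),
    n_s4 = sum(cand$failed_stage == "S4", na.rm = TRUE),
    n_species = dplyr::n_distinct(cand$species[cand$retained]),
    n_components = dplyr::n_distinct(cand$component[cand$retained])
  )
}

#' Candidate-count heatmap
#'
#' @param object A `clock_candidates` object.
#' @param ... Unused.
#' @return A ggplot: species by component, tile fill = retained count.
#' @method autoplot clock_candidates
#' @export
autoplot.clock_candidates <- function(object, ...) {
  cand <- object$candidates[object$candidates$retained, , drop = FALSE]
  counts <- dplyr::count(cand, .data$species, .data$component)
  counts$component <- factor(counts$component, levels = clock_components())
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$component, y = .data$species,
                                       fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "candidates") +
    ggplot2::theme_minimal()
}
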