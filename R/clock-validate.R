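#' Confusion matrix for expected versus found ortholog pairs
#'
#' Compares the (component, accession) pairs the workflow found against the
#' pairs it was expected to find (the known orthologs of each bait present
#' in the input proteomes). True positives are expected pairs that were
#' found, false negatives expected pairs that were missed, false positives
#' found pairs that were not expected.
#'
#' @param found_pairs,expected_pairs Tibbles with columns `component`,
#'   `accession`.
#' @return An object of class `clock_validation` with tibbles `tp`, `fn`,
#'   `fp`.
#' @export
validate_against_references <- function(found_pairs, expected_pairs) {
  key <- function(df) paste(df$component, df$accession, sep = "\r")
  fk <- key(found_pairs)
  ek <- key(expected_pairs)
  structure(list(
    tp = expected_pairs[ek %in% fk, , drop = FALSE],
    fn = expected_pairs[!ek %in% fk, , drop = FALSE],
    fp = found_pairs[!fk %in% ek, , drop = FALSE]
  ), class = "clock_validation")
}

#' @export
print.clock_validation <- function(x, ...) {
  cat("Ortholog-identification validation: ",
      nrow(x$tp), " TP, ", nrow(x$fn), " FN, ", nrow(x$fp), " FP\n", sep = "")
  invisible(x)
}

#' @rdname validate_against_references
#' @param x A `clock_validation` object.
#' @param ... Unused.
#' @method tidy clock_validation
#' @export
tidy.clock_validation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$tp, outcome = "true_positive"),
    dplyr::mutate(x$fn, outcome = "false_negative"),
    dplyr::mutate(x$fp, outcome = "false_positive")
  )
}

#' @rdname validate_against_references
#' @method glance clock_validation
#' @export
glance.clock_validation <- function(x, ...) {
  tibble(true_positives = nrow(x$tp),
         false_negatives = nrow(x$fn),
         false_positives = nrow(x$fp),
         n_expected = nrow(x$tp) + nrow(x$fn))
}

#' Compare candidate sets between two workflow runs
#'
#' Candidates are keyed by (species, seq_id, component); the comparison
#' reports the shared and run-exclusive counts and their percentages of the
#' union (rounded half away from zero to 1 decimal).
#'
#' @param run_a,run_b Candidate tibbles.
#' @param key Key columns (default `species`, `seq_id`, `component`).
#' @return Tibble with rows `shared`, `only_a`, `only_b`: columns `set`,
#'   `n`, `pct`.
#' @export
compare_candidate_sets <- function(run_a, run_b,
                                   key = c("species", "seq_id", "component")) {
  ka <- unique(do.call(paste, c(run_a[key], sep = "\r")))
  kb <- unique(do.call(paste, c(run_b[key], sep = "\r")))
  union_n <- length(union(ka, kb))
  if (union_n == 0) {
    stop("compare_candidate_sets(): both candidate sets are empty.")
  }
  n <- c(shared = length(intersect(ka, kb)),
         only_a = length(setdiff(ka, kb)),
         only_b = length(setdiff(kb, ka)))
  tibble(set = names(n), n = unname(n),
         pct = round_half_up(100 * unname(n) / union_n, 1))
}

#' Select fallback candidates from homology searches against public data
#'
#' For clock components the orthology workflow missed, public assemblies are
#' searched with the baits as queries. Hits with query or target coverage
#' below `min_cov` are excluded (exactly `min_cov` is retained); per
#' (species, component) the minimum-E-value survivor across all of that
#' species' assemblies is kept, with ties broken by higher bitscore, then
#' lexicographic target. Status codes per (species, component): `YES`
#' (fallback candidate found), `NH` (no homolog in available data), `ND`
#' (no public data for the species), `-` (already found by the orthology
#' workflow).
#'
#' @param hit_table Hit tibble with additional `species` and `component`
#'   columns (`query` is the bait).
#' @param already_found Tibble (`species`, `component`) of cells already
#'   filled by the orthology workflow.
#' @param data_available Tibble (`species`, `has_data` logical); species
#'   absent from the table count as having data when they have hits.
#' @param species Character vector fixing the full species set of the
#'   status table.
#' @param components Component set (default [clock_components()]).
#' @param min_cov Minimum query and target coverage (default 0.20).
#' @return A list: `hits` (at most one chosen hit per species/component)
#'   and `status` (tibble `species`, `component`, `status`).
#' @export
select_fallback_hits <- function(hit_table, already_found, data_available,
                                 species, components = clock_components(),
                                 min_cov = 0.20) {
  surv <- hit_table |>
    dplyr::filter(.data$qcov >= min_cov, .data$tcov >= min_cov) |>
    dplyr::arrange(.data$species, .data$component, .data$evalue,
                   dplyr::desc(.data$bitscore), .data$target) |>
    dplyr::distinct(.data$species, .data$component, .keep_all = TRUE)

  no_data <- data_available$species[!data_available$has_data]
  grid <- tidyr::expand_grid(species = species, component = components)
  found_key <- paste(already_found$species, already_found$component)
  surv_key <- paste(surv$species, surv$component)
  grid$status <- dplyr::case_when(
    paste(grid$species, grid$component) %in% found_key ~ "-",
    grid$species %in% no_data ~ "ND",
    paste(grid$species, grid$component) %in% surv_key ~ "YES",
    TRUE ~ "NH"
  )
  keep <- paste(surv$species, surv$component) %in%
    paste(grid$species, grid$component)[grid$status == "YES"]
  list(hits = surv[keep, , drop = FALSE], status = grid)
}
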