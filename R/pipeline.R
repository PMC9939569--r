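#' Pipeline run configuration
#'
#' Aggregates every threshold the workflow uses, the synthetic-data
#' configuration, and the output directory. Thresholds default to the
#' workflow's standard values: 200 nt minimum transcript length, mean PHRED
#' 20 read filter, 98% clustering identity/coverage, E-value cutoff 1e-5,
#' 20% fallback coverage, 100 aa minimum ORF.
#'
#' @param out_dir Directory for stage artifacts.
#' @param synth A [synth_config()] describing the simulated inputs.
#' @param min_len,min_mean_q,min_identity,min_target_cov,max_evalue
#'   Stage thresholds.
#' @param fallback_min_cov Coverage floor for fallback hit selection.
#' @param min_aa Minimum ORF protein length.
#' @param n_read_pairs Read pairs simulated per species.
#' @param read_frac_n,read_frac_lowq Planted read-defect fractions.
#' @param seed Master seed (defaults to the synthetic config's).
#' @return A list of class `clock_run_config`.
#' @export
clock_run_config <- function(out_dir,
                             synth = synth_config(),
                             min_len = 200L,
                             min_mean_q = 20,
                             min_identity = 0.98,
                             min_target_cov = 0.98,
                             max_evalue = 1e-5,
                             fallback_min_cov = 0.20,
                             min_aa = 100L,
                             n_read_pairs = 500L,
                             read_frac_n = 0.05,
                             read_frac_lowq = 0.05,
                             seed = synth$seed) {
  stopifnot(inherits(synth, "synth_config"))
  if (min_identity < 0 || min_identity > 1 || min_target_cov < 0 ||
      min_target_cov > 1 || max_evalue <= 0 || fallback_min_cov < 0 ||
      fallback_min_cov > 1 || min_len < 0 || min_aa < 1) {
    stop("clock_run_config(): threshold out of range (config error).")
  }
  structure(list(
    out_dir = out_dir, synth = synth, min_len = as.integer(min_len),
    min_mean_q = min_mean_q, min_identity = min_identity,
    min_target_cov = min_target_cov, max_evalue = max_evalue,
    fallback_min_cov = fallback_min_cov, min_aa = as.integer(min_aa),
    n_read_pairs = as.integer(n_read_pairs),
    read_frac_n = read_frac_n, read_frac_lowq = read_frac_lowq,
    seed = as.integer(seed)
  ), class = "clock_run_config")
}

stage_order <- c("simulate", "filter_reads", "reduce", "stats",
                 "annotate_merge", "find_clock", "validate",
                 "compare_runs", "draw_domains")

stage_deps <- list(
  simulate = character(),
  filter_reads = "simulate",
  reduce = "simulate",
  stats = "reduce",
  annotate_merge = c("simulate", "reduce"),
  find_clock = c("simulate", "reduce", "annotate_merge"),
  validate = "find_clock",
  compare_runs = "find_clock",
  draw_domains = "find_clock"
)

# Marker artifact per stage; its existence means the stage has run.
stage_marker <- function(cfg, stage) {
  file.path(cfg$out_dir, paste0(".", stage, ".done"))
}

pipe_path <- function(cfg, ...) file.path(cfg$out_dir, paste(..., sep = ""))

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
                   collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest_entry <- function(cfg, stage, artifacts) {
  entry <- list(stage = stage, config = config_hash(cfg),
                artifacts = as.list(unname(tools::md5sum(artifacts))))
  names(entry$artifacts) <- basename(artifacts)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n", sep = "",
      file = file.path(cfg$out_dir, "manifest.jsonl"), append = TRUE)
  writeLines(config_hash(cfg), stage_marker(cfg, stage))
}

stage_up_to_date <- function(cfg, stage) {
  mk <- stage_marker(cfg, stage)
  file.exists(mk) && identical(readLines(mk)[1], unname(config_hash(cfg)))
}

#' Run one pipeline stage
#'
#' Stages form a DAG: `simulate` -> `filter_reads`/`reduce` -> `stats` ->
#' `annotate_merge` -> `find_clock` -> `validate`/`compare_runs`/
#' `draw_domains`. A stage whose dependencies have not run errors naming the
#' stage to run first; a stage whose marker matches the current
#' configuration is skipped as up to date unless `force` is given.
#'
#' @param name Stage name (see Details).
#' @param config A [clock_run_config()].
#' @param force Re-run even when up to date.
#' @return A list: `stage`, `status` (`"done"` or `"up_to_date"`) and
#'   stage-specific results.
#' @export
run_stage <- function(name, config, force = FALSE) {
  cfg <- config
  stopifnot(inherits(cfg, "clock_run_config"))
  name <- match.arg(name, stage_order)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (dep in stage_deps[[name]]) {
    if (!file.exists(stage_marker(cfg, dep))) {
      stop("Stage '", name, "' needs stage '", dep, "' to run first.")
    }
  }
  if (!force && stage_up_to_date(cfg, name)) {
    return(list(stage = name, status = "up_to_date"))
  }
  res <- switch(name,
    simulate = stage_simulate(cfg),
    filter_reads = stage_filter_reads(cfg),
    reduce = stage_reduce(cfg),
    stats = stage_stats(cfg),
    annotate_merge = stage_annotate_merge(cfg),
    find_clock = stage_find_clock(cfg),
    validate = stage_validate(cfg),
    compare_runs = stage_compare_runs(cfg),
    draw_domains = stage_draw_domains(cfg)
  )
  write_manifest_entry(cfg, name, res$artifacts)
  c(list(stage = name, status = "done"), res)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order on the configured synthetic
#' universe and returns the per-stage results.
#'
#' @param config A [clock_run_config()].
#' @param force Re-run stages that are up to date.
#' @return Named list of stage results.
#' @export
run_pipeline <- function(config, force = FALSE) {
  setNames(lapply(stage_order, run_stage, config = config, force = force),
           stage_order)
}

# --- stage implementations ---------------------------------------------

stage_simulate <- function(cfg) {
  uni <- generate_universe(cfg$synth)
  tr <- generate_transcripts(uni$proteomes, cfg$synth)
  arts <- character(0)
  p <- function(...) {
    f <- pipe_path(cfg, ...)
    arts <<- c(arts, f)
    f
  }
  write_fasta(uni$ref_proteome, p("ref_proteome.fasta"))
  readr::write_tsv(uni$registry, p("bait_registry.tsv"))
  readr::write_tsv(uni$domain_table, p("domain_table.tsv"))
  readr::write_tsv(uni$family_table, p("family_table.tsv"))
  readr::write_tsv(uni$pair_table, p("pair_table.tsv"))
  readr::write_tsv(uni$hit_table, p("hit_table.tsv"))
  readr::write_tsv(uni$eggnog_table, p("eggnog_table.tsv"))
  readr::write_tsv(uni$proteomes[, c("species", "id", "desc", "seq",
                                     "completeness")],
                   p("planted_proteome.tsv"))
  for (sp in cfg$synth$species) {
    write_fasta(tr$transcripts[tr$transcripts$species == sp,
                               c("id", "seq")],
                p("transcripts_", sp, ".fasta"))
    reads <- generate_read_pairs(
      tr$transcripts[tr$transcripts$species == sp, ],
      cfg$n_read_pairs, frac_n = cfg$read_frac_n,
      frac_lowq = cfg$read_frac_lowq,
      seed = cfg$seed + match(sp, cfg$synth$species))
    write_fastq_pairs(reads, p("reads_", sp, "_1.fastq"),
                      p("reads_", sp, "_2.fastq"))
  }
  readr::write_tsv(tr$map, p("transcript_map.tsv"))
  readr::write_tsv(uni$manifest$orthologs, p("truth_orthologs.tsv"))
  readr::write_tsv(uni$manifest$decoys, p("truth_decoys.tsv"))
  readr::write_tsv(tr$near_duplicates, p("truth_near_duplicates.tsv"))
  list(artifacts = arts, universe = uni, transcripts = tr)
}

stage_filter_reads <- function(cfg) {
  arts <- character(0)
  stats <- list()
  for (sp in cfg$synth$species) {
    pairs <- read_fastq_pairs(pipe_path(cfg, "reads_", sp, "_1.fastq"),
                              pipe_path(cfg, "reads_", sp, "_2.fastq"))
    flt <- filter_read_pairs(pairs, min_mean_q = cfg$min_mean_q,
                             species = sp)
    f1 <- pipe_path(cfg, "filtered_", sp, "_1.fastq")
    f2 <- pipe_path(cfg, "filtered_", sp, "_2.fastq")
    write_fastq_pairs(flt$kept, f1, f2)
    arts <- c(arts, f1, f2)
    stats[[sp]] <- flt$stats
  }
  st <- dplyr::bind_rows(stats)
  f <- pipe_path(cfg, "read_stats.tsv")
  readr::write_tsv(st, f)
  list(artifacts = c(arts, f), stats = st)
}

stage_reduce <- function(cfg) {
  arts <- character(0)
  reductions <- list()
  for (sp in cfg$synth$species) {
    tr <- read_fasta(pipe_path(cfg, "transcripts_", sp, ".fasta"))
    red <- reduce_assembly(tr, min_len = cfg$min_len, min_aa = cfg$min_aa,
                           min_identity = cfg$min_identity,
                           min_target_cov = cfg$min_target_cov)
    fp <- pipe_path(cfg, "proteome_", sp, ".fasta")
    ft <- pipe_path(cfg, "final_transcripts_", sp, ".fasta")
    write_fasta(red$proteins[, c("id", "desc", "seq")], fp)
    write_fasta(red$final_transcripts, ft)
    fc <- pipe_path(cfg, "clusters_", sp, ".tsv")
    readr::write_tsv(red$clusters, fc)
    fo <- pipe_path(cfg, "orfs_", sp, ".tsv")
    readr::write_tsv(
      red$proteins[, c("id", "completeness")], fo)
    arts <- c(arts, fp, ft, fc, fo)
    reductions[[sp]] <- red
  }
  list(artifacts = arts, reductions = reductions)
}

stage_stats <- function(cfg) {
  rows <- list()
  for (sp in cfg$synth$species) {
    initial <- read_fasta(pipe_path(cfg, "transcripts_", sp, ".fasta"))
    final <- read_fasta(pipe_path(cfg, "final_transcripts_", sp, ".fasta"))
    orfs <- readr::read_tsv(pipe_path(cfg, "orfs_", sp, ".tsv"),
                            show_col_types = FALSE)
    rows[[paste(sp, "i")]] <- assembly_stats_row(sp, "initial", initial)
    rows[[paste(sp, "f")]] <- assembly_stats_row(
      sp, "final", final, n_initial = nrow(initial), orfs = orfs)
  }
  st <- dplyr::bind_rows(rows)
  f1 <- pipe_path(cfg, "assembly_stats.tsv")
  f2 <- pipe_path(cfg, "assembly_summary.tsv")
  readr::write_tsv(st, f1)
  summary <- summarize_assemblies(st)
  readr::write_tsv(summary, f2)
  list(artifacts = c(f1, f2), stats = st, summary = summary)
}

stage_annotate_merge <- function(cfg) {
  hits <- read_hit_table(pipe_path(cfg, "hit_table.tsv"))
  eggnog <- readr::read_tsv(pipe_path(cfg, "eggnog_table.tsv"),
                            show_col_types = FALSE)
  ids <- unlist(lapply(cfg$synth$species, function(sp) {
    read_fasta(pipe_path(cfg, "proteome_", sp, ".fasta"))$id
  }), use.names = FALSE)
  best <- best_hit_per_query(hits, max_evalue = cfg$max_evalue)
  ann <- merge_annotations(best, eggnog[eggnog$seq_id %in% ids, ], ids)
  f1 <- pipe_path(cfg, "annotations.tsv")
  f2 <- pipe_path(cfg, "annotation_rates.tsv")
  readr::write_tsv(ann$table, f1)
  readr::write_tsv(ann$rates, f2)
  list(artifacts = c(f1, f2), annotations = ann)
}

stage_find_clock <- function(cfg, pair_table = NULL, suffix = "") {
  registry <- readr::read_tsv(pipe_path(cfg, "bait_registry.tsv"),
                              show_col_types = FALSE)
  if (is.null(pair_table)) {
    pair_table <- read_pair_table(pipe_path(cfg, "pair_table.tsv"))
  }
  domain_table <- read_domain_table(pipe_path(cfg, "domain_table.tsv"))
  family_table <- read_family_table(pipe_path(cfg, "family_table.tsv"))
  proteomes <- dplyr::bind_rows(lapply(cfg$synth$species, function(sp) {
    dplyr::mutate(read_fasta(pipe_path(cfg, "proteome_", sp, ".fasta")),
                  species = sp)
  }))
  orf_tags <- dplyr::bind_rows(lapply(cfg$synth$species, function(sp) {
    readr::read_tsv(pipe_path(cfg, "orfs_", sp, ".tsv"),
                    show_col_types = FALSE)
  }))
  raw <- extract_bait_orthologs(pair_table, registry)
  # orthology only sees sequences that survived the reduction
  raw <- raw[paste(raw$species, raw$seq_id) %in%
               paste(proteomes$species, proteomes$id), , drop = FALSE]
  raw <- dplyr::left_join(raw, orf_tags, by = c(seq_id = "id"))
  vetted <- vet_candidates(raw, domain_table, family_table, registry)
  best <- best_hit_per_query(read_hit_table(pipe_path(cfg, "hit_table.tsv")),
                             max_evalue = cfg$max_evalue)
  vetted <- confirm_swissprot(vetted, best, registry$accession)
  cand <- vetted$candidates
  f1 <- pipe_path(cfg, "candidates", suffix, ".tsv")
  f2 <- pipe_path(cfg, "candidate_matrix", suffix, ".tsv")
  f3 <- pipe_path(cfg, "candidate_audit", suffix, ".jsonl")
  f4 <- pipe_path(cfg, "candidates", suffix, ".fasta")
  readr::write_tsv(cand, f1)
  mat <- candidate_matrix(vetted, components = cfg$synth$components)
  readr::write_tsv(mat, f2, na = "NA")
  writeLines(vapply(seq_len(nrow(cand)), function(i) {
    jsonlite::toJSON(as.list(cand[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1)), f3)
  retained <- cand[cand$retained, , drop = FALSE]
  seqs <- dplyr::inner_join(retained[, c("species", "seq_id")], proteomes,
                            by = c("species", seq_id = "id"))
  write_fasta(tibble(id = paste0(seqs$species, "|", seqs$seq_id),
                     desc = seqs$desc, seq = seqs$seq), f4)
  list(artifacts = c(f1, f2, f3, f4), vetted = vetted, matrix = mat)
}

stage_validate <- function(cfg) {
  cand <- readr::read_tsv(pipe_path(cfg, "candidates.tsv"),
                          show_col_types = FALSE)
  truth <- readr::read_tsv(pipe_path(cfg, "truth_orthologs.tsv"),
                           show_col_types = FALSE)
  found <- tibble(component = cand$component[cand$retained],
                  accession = paste(cand$species[cand$retained],
                                    cand$seq_id[cand$retained]))
  expected <- tibble(component = truth$component,
                     accession = paste(truth$species, truth$seq_id))
  val <- validate_against_references(found, expected)
  g <- glance(val)
  g$precision <- ifelse(nrow(found) > 0,
                        nrow(val$tp) / (nrow(val$tp) + nrow(val$fp)), NA)
  g$recall <- nrow(val$tp) / (nrow(val$tp) + nrow(val$fn))
  f1 <- pipe_path(cfg, "confusion_matrix.tsv")
  f2 <- pipe_path(cfg, "validation_summary.tsv")
  readr::write_tsv(tidy(val), f1)
  readr::write_tsv(g, f2)
  list(artifacts = c(f1, f2), validation = val, summary = g)
}

stage_compare_runs <- function(cfg) {
  cand_a <- readr::read_tsv(pipe_path(cfg, "candidates.tsv"),
                            show_col_types = FALSE)
  # second run on the same inputs; identical tables give full overlap
  res_b <- stage_find_clock(cfg, suffix = "_runb")
  cand_b <- res_b$vetted$candidates
  cmp <- compare_candidate_sets(cand_a[cand_a$retained, ],
                                cand_b[cand_b$retained, ])
  f <- pipe_path(cfg, "run_comparison.tsv")
  readr::write_tsv(cmp, f)
  list(artifacts = c(f, res_b$artifacts), comparison = cmp)
}

stage_draw_domains <- function(cfg) {
  cand <- readr::read_tsv(pipe_path(cfg, "candidates.tsv"),
                          show_col_types = FALSE)
  registry <- readr::read_tsv(pipe_path(cfg, "bait_registry.tsv"),
                              show_col_types = FALSE)
  domain_table <- read_domain_table(pipe_path(cfg, "domain_table.tsv"))
  proteomes <- dplyr::bind_rows(lapply(cfg$synth$species, function(sp) {
    dplyr::mutate(read_fasta(pipe_path(cfg, "proteome_", sp, ".fasta")),
                  species = sp)
  }))
  ref <- read_fasta(pipe_path(cfg, "ref_proteome.fasta"))
  retained <- cand[cand$retained, , drop = FALSE]
  arts <- character(0)
  index <- list()
  for (cp in unique(retained$component)) {
    bait_id <- registry$seq_id[registry$component == cp]
    rc <- retained[retained$component == cp, , drop = FALSE]
    seqs <- dplyr::inner_join(rc, proteomes,
                              by = c("species", seq_id = "id"))
    labels <- label_candidate(seqs$species, seqs$seq_id, seqs$completeness,
                              "Syn")
    tracks <- dplyr::bind_rows(
      tibble(label = label_candidate("reference", bait_id, is_bait = TRUE),
             length = nchar(ref$seq[ref$id == bait_id]), is_bait = TRUE),
      tibble(label = labels, length = nchar(seqs$seq), is_bait = FALSE))
    ids <- c(bait_id, seqs$seq_id)
    lbl <- setNames(tracks$label, ids)
    dom <- domain_table[domain_table$seq_id %in% ids, , drop = FALSE]
    dom <- tibble(label = unname(lbl[dom$seq_id]), accession = dom$accession,
                  name = dom$name, start = dom$start, end = dom$end,
                  db = dom$db)
    f <- pipe_path(cfg, "domains_", gsub("[^A-Za-z0-9]", "_", cp), ".svg")
    render_domain_diagram(domain_tracks(tracks, dom), f)
    arts <- c(arts, f)
    index[[cp]] <- tibble(component = cp, species = seqs$species,
                          seq_id = seqs$seq_id, figure = basename(f))
  }
  fi <- pipe_path(cfg, "figure_index.tsv")
  readr::write_tsv(dplyr::bind_rows(index), fi)
  list(artifacts = c(arts, fi))
}
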