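---
title: "Reducing de novo transcriptomes and identifying circadian clock orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing de novo transcriptomes and identifying circadian clock orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockfindr)
```

## The problem

De novo assembled transcriptomes are highly redundant: one gene is
typically represented by many transcript isoforms, near-identical
assembly variants, and fragments. Before such an assembly can serve as a
gene catalog — for example, to ask which circadian clock components a
non-model animal expresses — it has to be reduced to one representative
sequence per gene, and candidate genes have to be identified and vetted
against well-characterized references.

clockfindr implements this workflow as composable, tested functions:

1. **Read QC** — pair-synchronized filtering of paired-end reads
   (`filter_read_pairs()`): a read fails on any ambiguous base call or a
   mean PHRED score below 20, and the whole pair is discarded when either
   mate fails, since unpaired reads do not help assembly.
2. **Assembly reduction** (`reduce_assembly()`) — minimum transcript
   length 200 nt; single best ORF per transcript with a completeness tag;
   greedy clustering at 98% identity and coverage to remove
   near-identical sequences (longest member is the representative);
   longest protein isoform per Trinity gene; extraction of the matching
   final transcripts.
3. **Assembly statistics** — N50, transcript retention, complete-ORF
   fraction (`compute_n50()`, `summarize_assemblies()`).
4. **Annotation merge** — best homology hit per query at an E-value
   cutoff of 1e-5 (lowest E-value wins; ties by bitscore, then target
   id), merged with orthology-mapper annotations; no coverage cutoff is
   applied so short fragments can still be annotated
   (`best_hit_per_query()`, `merge_annotations()`).
5. **Clock ortholog identification** — ten reference clock proteins
   (CLK, CYC, TIM, PER, CRY1, CRY2, PDP1e, VRI, REV-ERBa, RORa) are
   marker-tagged in their proteomes (`tag_baits()`); their pairwise
   orthologs are pulled from an ortholog table
   (`extract_bait_orthologs()`) and vetted by a four-stage cascade
   (`vet_candidates()`); retained candidates are summarized as a
   species-by-component count matrix (`candidate_matrix()`).
6. **Validation** — a confusion matrix of expected versus found
   reference orthologs (`validate_against_references()`), candidate-set
   overlap between runs (`compare_candidate_sets()`), and fallback
   selection from homology searches against public data
   (`select_fallback_hits()`).
7. **Visualization** — deterministic domain-architecture diagrams per
   component (`domain_tracks()`, `render_domain_diagram()`,
   `autoplot()`).

## The vetting cascade

Raw pairwise-ortholog candidates are filtered by four ordered stages:

* **S1** both a Pfam domain annotation and a PANTHER family assignment
  must be present;
* **S2** at least one Pfam accession must be shared with the bait;
* **S3** the PANTHER family must equal the bait's family;
* **S4** within each (species, component), if any surviving candidate
  shares the bait's PANTHER subfamily, only those are retained —
  otherwise all survive.

Failures are monotone: a candidate dropped at stage *k* is never
evaluated later, and the audit table records the stage and reason for
every drop. The subsequent Swiss-Prot confirmation
(`confirm_swissprot()`) is deliberately a report-only flag: candidates
that cleared the cascade are all retained, because no reliable in-silico
criterion distinguishes competing survivors, and removing candidates on
the basis of a best-hit lookup would silently contradict the cascade's
audit trail. The flag marks candidates whose best Swiss-Prot homolog is
on a user-supplied whitelist of clock-related accessions, for manual
review.

Candidates orthologous to two different baits (possible under
one-to-many orthology) are kept under both assignments; the audit table
makes the duplication visible.

## Key parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `min_mean_q` | 20 | `filter_read_pairs()` | mean-PHRED floor; exactly 20 passes |
| `min_len` | 200 nt | `filter_min_length()` | minimum transcript length; exactly 200 kept |
| `min_aa` | 100 | `find_best_orf()` | minimum protein length to report an ORF |
| `min_identity` | 0.98 | `cluster_sequences()` | global-alignment identity to join a cluster |
| `min_target_cov` | 0.98 | `cluster_sequences()` | aligned coverage of the shorter sequence |
| `max_evalue` | 1e-5 | `best_hit_per_query()` | homology-hit cutoff; exactly 1e-5 survives |
| `min_cov` | 0.20 | `select_fallback_hits()` | query/target coverage floor; exactly 0.20 retained |

All boundary conventions are inclusive as listed and covered by tests.

## Numerical and algorithmic choices

**ORF enumeration.** All six frames are scanned. Candidate ORFs run from
an ATG — or from the in-frame transcript edge when no upstream stop
exists (partial) — to a stop codon or the edge (partial). Codons
containing `N` terminate a span without counting as a stop. The best ORF
is the longest protein; ties break to the `+` strand, then the lowest
frame, then the smallest forward-strand start. Scoring by length rather
than a coding-potential model keeps the operation fully checkable
against an exhaustive enumerator; on real data a model-based ORF caller
may occasionally pick a different frame. One consequence of admitting
edge-anchored partial ORFs is that on very short sequences a strand with
no stop codons can host an "internal" candidate longer than a genuine
start-to-stop ORF; the completeness tag records exactly this. ORF
coordinates are 0-based half-open on the transcript's forward strand and
include the stop codon when present.

**Clustering identity.** The clustering threshold needs an explicit
identity definition. We use global (Needleman-Wunsch) alignment with
unit costs (match +1, mismatch -1, gap -1; implemented in C++ via Rcpp);
identity = identical aligned residues / alignment length including gap
columns, and "target coverage" is read as coverage of the shorter
sequence — the permissive reading consistent with removing nearly
identical sequences. Greedy incremental clustering processes sequences
in descending length (ties by id), so representatives are always maximal
and clusters partition the input. A length-ratio prefilter skips
alignments that provably cannot reach the identity bound and cannot
change the result; the test suite compares the whole procedure against
an all-pairs alignment oracle built on `Biostrings::pairwiseAlignment`
with the same scoring.

**Rounding.** All reported percentages round half away from zero
(`round_half_up()`), and a loss percentage is always computed as
100 − retained so the pair sums to 100.0 after rounding.

**N50.** Lengths are sorted descending and the N50 is the first length
at which the cumulative sum reaches half the total; when the half-total
falls exactly on a boundary the larger length is returned.

**Deterministic figures.** Domain diagrams are written as plain SVG text
with a colour assignment that is a pure function of the sorted accession
set, so identical inputs give byte-identical files; overlapping
annotations from different databases are stacked as thin sub-bars rather
than merged. `autoplot()` methods provide ggplot2 versions for
interactive work.

## What the synthetic generator emulates

`generate_universe()` plants a ground-truthed universe: per species, one
ortholog of each clock bait mutated at a configurable substitution rate
(default 0.10 per residue — comfortably inside the detectable range for
orthology while clearly diverged), optional within-species paralogs
(rate 0.2, divergence 0.25), ORF fragments (rate 0.2, equiprobable
5'-partial/3'-partial/internal, cut in inter-domain linkers so at least
one full domain survives), and per species three decoy proteins that
carry exactly one bait domain inside an unrelated PANTHER family — the
construction is designed so that injected false-positive ortholog pairs
are removed at the shared-domain or same-family stage.
`generate_transcripts()` expands each protein into 1–3 Trinity-style
isoforms (the first is always the full-length back-translation; the
others are 3' truncations) plus, at rate 0.2, a near-duplicate
transcript at ≥ 98% identity under a fresh gene id, which the clustering
stage must remove. UTRs are built from stop-codon-rich repeats so they
can neither extend nor seed an ORF, and the fixed back-translation codon
table uses leucine/serine codons whose reverse complements are stop
codons, which keeps the planted ORF the best one. All true orthologs are
annotated with the bait's subfamily (decoys with a foreign family), so
on noise-free inputs the subfamily-preference stage is lossless and
planted recovery is exact.

Deliberately not emulated: indels (substitution-only mutation keeps
identity and coverage arithmetic exact for oracle checks), realistic
codon usage, expression levels, and quality-score error models beyond
N-injection and a low-quality mate. Passing the end-to-end recovery test
therefore demonstrates the correctness of the extraction/vetting logic
and the reduction plumbing, not robustness to assembly artefacts or
alignment noise in real data.

**Problem sizes.** The shipped tests and the acceptance script run the
end-to-end recovery at 5 species × 10 components (a few hundred
transcripts), the clustering oracle at up to ~16 sequences × 100 seeds,
the ORF oracle at 50 random 300-nt sequences, and the N50 oracle at
1000 random length lists — sizes at which the independent oracles stay
exact and the whole suite completes in a few minutes on one CPU.

## Staged pipeline

`run_stage()`/`run_pipeline()` orchestrate the stages as a DAG
(simulate → filter_reads/reduce → stats → annotate_merge → find_clock →
validate/compare_runs/draw_domains) over a directory of plain-text
artifacts. Every completed stage writes a manifest entry (configuration
hash and artifact checksums); re-running an up-to-date stage is a no-op
unless forced, and running a stage before its dependencies errors naming
the stage to run first. With a fixed seed the entire artifact tree is
reproducible byte for byte.

```{r, eval = FALSE}
cfg <- clock_run_config(out_dir = "run1",
                        synth = synth_config(n_species = 5, seed = 1))
res <- run_pipeline(cfg)
res$validate$summary
autoplot(res$find_clock$vetted)
```

## Known limitations

* The ortholog table is consumed, never computed: orthology inference
  (orthogroups, gene trees, species-tree rooting) is an external
  concern, and the workflow's sensitivity is bounded by it.
* Best-ORF selection by protein length can disagree with
  coding-potential models on real data (see above).
* BUSCO summaries and read-support rates are parsed from external
  summaries, not computed.
* The Swiss-Prot whitelist for the confirmation flag is a user-supplied
  configuration; no curated list ships with the package.
* Fragment candidates that retain only a promiscuous domain (e.g. a
  single PAS) pass the cascade by construction; the completeness tag and
  audit trail are the intended guard, mirroring the caution one should
  apply to such candidates in practice.
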