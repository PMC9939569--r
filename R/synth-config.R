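# Domain architectures used for the ten bait proteins. Lengths are in amino
# acids; accessions are the Pfam families characteristic of each component
# (bHLH + PAS for the activators, photolyase + FAD-binding for the
# cryptochromes, bZIP for the second-loop insect regulators, zinc finger +
# ligand-binding domain for the nuclear receptors). CRY1/CRY2 and
# REV-ERBa/RORa intentionally share a PANTHER family and differ only at the
# subfamily level, so the subfamily-preference vetting stage is exercised.
default_architectures <- function() {
  arch <- list(
    CLK = list(c("PF00010", "HLH", 55), c("PF00989", "PAS", 70),
               c("PF14598", "PAS_11", 60)),
    CYC = list(c("PF00010", "HLH", 55), c("PF00989", "PAS", 70),
               c("PF08447", "PAS_3", 60)),
    TIM = list(c("PF04821", "TIMELESS", 120), c("PF05029", "TIMELESS_C", 90)),
    PER = list(c("PF00989", "PAS", 70), c("PF08447", "PAS_3", 60),
               c("PF12114", "Period_C", 90)),
    CRY1 = list(c("PF00875", "DNA_photolyase", 130),
                c("PF03441", "FAD_binding_7", 100)),
    CRY2 = list(c("PF00875", "DNA_photolyase", 130),
                c("PF03441", "FAD_binding_7", 100)),
    PDP1e = list(c("PF00170", "bZIP_1", 60)),
    VRI = list(c("PF00170", "bZIP_1", 60)),
    `REV-ERBa` = list(c("PF00105", "zf-C4", 70),
                      c("PF00104", "Hormone_recep", 180)),
    RORa = list(c("PF00105", "zf-C4", 70),
                c("PF00104", "Hormone_recep", 180))
  )
  lapply(arch, function(dl) {
    tibble(accession = vapply(dl, `[`, "", 1),
           name = vapply(dl, `[`, "", 2),
           len = as.integer(vapply(dl, `[`, "", 3)))
  })
}

# PANTHER family/subfamily per component. CRY1/CRY2 and REV-ERBa/RORa share
# a family and are told apart by subfamily only.
default_families <- function() {
  tibble(
    component = clock_components(),
    family_acc = c("PTHR23042", "PTHR23043", "PTHR22940", "PTHR11269",
                   "PTHR11455", "PTHR11455", "PTHR15310", "PTHR15311",
                   "PTHR24082", "PTHR24082"),
    subfamily_acc = c("PTHR23042:SF14", "PTHR23043:SF2", "PTHR22940:SF7",
                      "PTHR11269:SF4", "PTHR11455:SF3", "PTHR11455:SF5",
                      "PTHR15310:SF1", "PTHR15311:SF2", "PTHR24082:SF161",
                      "PTHR24082:SF82")
  )
}

# Bait accessions (component, UniProt accession, source species code).
default_baits <- function() {
  tibble(
    component = clock_components(),
    accession = c("O61735", "O61734", "P49021", "P07663", "O77059",
                  "A0A212FAM3", "Q8SZT1", "Q9VMS4", "Q3UV55", "P51448"),
    source_species = c("Dm", "Dm", "Dm", "Dm", "Dm", "Dp", "Dm", "Dm",
                       "Mm", "Mm")
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: per-species
#' proteomes carrying diverged orthologs of the ten clock baits with
#' component-specific domain architectures, within-species paralogs, ORF
#' fragments, Trinity-style isoform structure, near-duplicate transcripts,
#' single-domain decoy proteins in an unrelated family, and an ortholog pair
#' table derived from the planted truth with injectable false
#' negatives/positives.
#'
#' @param n_species Number of synthetic species (default 5).
#' @param components Clock components to plant (default all ten).
#' @param divergence_per_species Substitution probability per residue
#'   between bait and ortholog (default 0.10; must be in [0, 0.5]).
#' @param paralog_rate Probability that a (species, component) carries one
#'   additional, more diverged paralog (default 0.2).
#' @param paralog_divergence Substitution rate for paralogs (default 0.25).
#' @param fragment_rate Probability that an ortholog is planted as an ORF
#'   fragment (5'-partial, 3'-partial or internal, equiprobable;
#'   default 0.2).
#' @param decoy_count Decoy proteins per species, each carrying exactly one
#'   bait domain inside an unrelated family (default 3).
#' @param near_duplicate_rate Probability that a gene emits an additional
#'   near-duplicate transcript at >= 98% identity (default 0.2).
#' @param isoform_probs Probabilities of 1, 2, ... transcript isoforms per
#'   gene (default `c(0.5, 0.3, 0.2)`).
#' @param subfamily_frac Fraction of true orthologs annotated with the
#'   bait's PANTHER subfamily (default 1).
#' @param ortholog_fn_rate,ortholog_fp_rate Pair-table noise: probability of
#'   dropping a true pair / of pairing a decoy with a random bait
#'   (default 0).
#' @param utr5_len,utr3_len Approximate UTR lengths in nucleotides
#'   (defaults 60 and 40).
#' @param min_protein_len Proteins are padded to at least this many residues
#'   so fragments stay above the ORF-caller's reporting floor (default 240).
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 5,
                         components = clock_components(),
                         divergence_per_species = 0.10,
                         paralog_rate = 0.2,
                         paralog_divergence = 0.25,
                         fragment_rate = 0.2,
                         decoy_count = 3,
                         near_duplicate_rate = 0.2,
                         isoform_probs = c(0.5, 0.3, 0.2),
                         subfamily_frac = 1,
                         ortholog_fn_rate = 0,
                         ortholog_fp_rate = 0,
                         utr5_len = 60,
                         utr3_len = 40,
                         min_protein_len = 240,
                         seed = 1L) {
  rates <- c(divergence_per_species, paralog_rate, fragment_rate,
             near_duplicate_rate, subfamily_frac,
             ortholog_fn_rate, ortholog_fp_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("synth_config(): all rates must be in [0, 1].")
  }
  if (divergence_per_species > 0.5) {
    stop("synth_config(): divergence_per_species must be in [0, 0.5].")
  }
  bad <- setdiff(components, clock_components())
  if (length(bad)) stop_with_ids("Unknown clock component(s)", bad)
  cfg <- list(
    n_species = as.integer(n_species),
    species = sprintf("species_%02d", seq_len(n_species)),
    components = components,
    architectures = default_architectures()[components],
    families = default_families()[
      default_families()$component %in% components, ],
    baits = default_baits()[default_baits()$component %in% components, ],
    divergence_per_species = divergence_per_species,
    paralog_rate = paralog_rate,
    paralog_divergence = paralog_divergence,
    fragment_rate = fragment_rate,
    decoy_count = as.integer(decoy_count),
    near_duplicate_rate = near_duplicate_rate,
    isoform_probs = isoform_probs / sum(isoform_probs),
    subfamily_frac = subfamily_frac,
    ortholog_fn_rate = ortholog_fn_rate,
    ortholog_fp_rate = ortholog_fp_rate,
    utr5_len = utr5_len,
    utr3_len = utr3_len,
    min_protein_len = as.integer(min_protein_len),
    leader_len = 40L, linker_len = 30L, tail_len = 40L,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synth_config")
}
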