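#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults describe a
#' desk-scale cohort that is structurally faithful to a real tumor screen:
#' a few patients with tens of expressed somatic missense variants each,
#' binomially sampled tumor/normal/RNA read counts at realistic allele
#' frequencies, log-normal gene expression with an expression boost for the
#' designated immunogenic variants, and Poisson plate counts with an
#' elevated spot rate for immunogenic stimuli.
#'
#' @param seed Master seed; all randomness flows from it through named
#'   substreams (proteins / evidence / plates / epitopes), so regenerating
#'   one artifact never perturbs another.
#' @param n_patients,n_variants_per_patient Cohort scale.
#' @param protein_length Length-2 range of protein lengths (residues).
#' @param vaf_shape1,vaf_shape2 Beta parameters of the tumor allele
#'   frequency.
#' @param vaf_floor Lower floor applied to tumor VAF.
#' @param normal_vaf Contamination allele frequency in the normal sample.
#' @param dna_depth,rna_depth Length-2 ranges of sequencing depth.
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters.
#' @param fraction_immunogenic Fraction of variants designated
#'   truth-immunogenic.
#' @param tpm_multiplier Expression multiplier applied to immunogenic
#'   variants.
#' @param background_rate Poisson mean of spots/well for non-immunogenic
#'   stimuli and negative controls.
#' @param effect_rate Additional spots/well for stimuli containing
#'   immunogenic peptides (30 spots/well is ~ +300 SFC net at 1e5
#'   cells/well).
#' @param pha_rate Spots/well for the PHA positive control.
#' @param replicates Wells per condition.
#' @param cells_per_well PBMC plated per well.
#' @param hla_alleles HLA class I alleles assigned to every simulated
#'   patient.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_patients = 4,
                       n_variants_per_patient = 20,
                       protein_length = c(60, 200),
                       vaf_shape1 = 5, vaf_shape2 = 15,
                       vaf_floor = 0.05,
                       normal_vaf = 0.005,
                       dna_depth = c(30, 150),
                       rna_depth = c(10, 100),
                       tpm_meanlog = 3, tpm_sdlog = 1,
                       fraction_immunogenic = 0.2,
                       tpm_multiplier = 4,
                       background_rate = 3,
                       effect_rate = 30,
                       pha_rate = 100,
                       replicates = 3,
                       cells_per_well = 1e5,
                       hla_alleles = c("HLA-A*02:01", "HLA-A*01:01",
                                       "HLA-B*07:02", "HLA-B*08:01")) {
  cfg <- as.list(environment())
  if (cfg$fraction_immunogenic < 0 || cfg$fraction_immunogenic > 1) {
    abort("fraction_immunogenic must be in [0, 1]")
  }
  if (cfg$background_rate < 0 || cfg$effect_rate < 0 || cfg$pha_rate < 0) {
    abort("plate spot rates must be >= 0")
  }
  if (cfg$vaf_shape1 <= 0 || cfg$vaf_shape2 <= 0 || cfg$tpm_sdlog <= 0) {
    abort("invalid distribution parameters")
  }
  structure(cfg, class = "sim_config")
}

random_protein <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

# uniform integers in [lo, hi], safe when lo == hi
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

#' Simulate a synthetic tumor cohort
#'
#' Generates, per patient, random proteins each carrying one implanted
#' missense SNV, with binomially sampled tumor/normal DNA and tumor RNA
#' read counts, log-normal TPM (boosted for truth-immunogenic variants),
#' genotypes, and ground-truth immunogenicity labels. Reproducible:
#' identical output for a fixed config.
#'
#' @param config A [sim_config()].
#' @return A list: `proteins` (named character vector), `variants` (variant
#'   tibble, see [read_variant_table()]), `truth` (per-variant
#'   `is_immunogenic`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_patients * config$n_variants_per_patient

  set.seed(substream_seed(config$seed, "proteins"))
  lens <- sample_range(config$protein_length, n_total)
  prots <- vapply(lens, random_protein, character(1))
  names(prots) <- sprintf("GENE%04d", seq_len(n_total))

  set.seed(substream_seed(config$seed, "evidence"))
  patient <- rep(sprintf("P%02d", seq_len(config$n_patients)),
                 each = config$n_variants_per_patient)
  mut_pos <- vapply(lens, function(L) sample.int(L, 1L), integer(1))
  wt <- substr(prots, mut_pos, mut_pos)
  mut <- vapply(wt, function(w) sample(setdiff(AA_STANDARD, w), 1L), character(1))
  tumor_vaf <- pmax(rbeta(n_total, config$vaf_shape1, config$vaf_shape2),
                    config$vaf_floor)
  t_depth <- sample_range(config$dna_depth, n_total)
  n_depth <- sample_range(config$dna_depth, n_total)
  r_depth <- sample_range(config$rna_depth, n_total)
  immunogenic <- runif(n_total) < config$fraction_immunogenic
  tpm <- rlnorm(n_total, config$tpm_meanlog, config$tpm_sdlog) *
    ifelse(immunogenic, config$tpm_multiplier, 1)

  variants <- tibble(
    patient_id = patient,
    chrom = sprintf("chr%d", 1 + (seq_len(n_total) - 1L) %% 22),
    pos = 1000L + 100L * seq_len(n_total),
    ref = sample(c("A", "C", "G", "T"), n_total, TRUE),
    alt = NA_character_,
    gene = names(prots),
    hgvs_protein = sprintf("p.%s%d%s", AA1_TO_3[wt], mut_pos, AA1_TO_3[mut]),
    tumor_dna_depth = t_depth,
    tumor_dna_alt = rbinom(n_total, t_depth, tumor_vaf),
    normal_dna_depth = n_depth,
    normal_dna_alt = rbinom(n_total, n_depth, config$normal_vaf),
    rna_depth = r_depth,
    rna_alt = rbinom(n_total, r_depth, tumor_vaf),
    tpm = tpm,
    tumor_genotype = ifelse(tumor_vaf >= 0.9, "hom_alt", "het"),
    sequence_id = names(prots)
  )
  variants$alt <- vapply(variants$ref,
                         function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                         character(1))
  truth <- tibble(patient_id = patient, gene = names(prots),
                  is_immunogenic = immunogenic)
  list(proteins = prots, variants = variants, truth = truth)
}

#' Simulate ELISpot/Fluorospot plates for a stimulation design
#'
#' Draws Poisson spot counts for each stimulus, cytokine and replicate:
#' `background_rate` spots/well for non-immunogenic stimuli and negative
#' controls, `background_rate + effect_rate` for stimuli marked
#' immunogenic, and `pha_rate` for the PHA positive control. Negative
#' controls (`DMSO`, `media`) and `PHA` wells are added per patient.
#'
#' @param design Tibble with columns `patient_id`, `stimulus`,
#'   `immunogenic` (logical).
#' @param config A [sim_config()].
#' @param cytokines Cytokines to plate (default both).
#' @return A plate-well tibble (see [read_plate_csv()]).
#' @export
simulate_plates <- function(design, config = sim_config(),
                            cytokines = c("IFNg", "IL5")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "plates"))
  controls <- design %>%
    distinct(.data$patient_id) %>%
    tidyr::expand_grid(stimulus = c("DMSO", "media", "PHA")) %>%
    mutate(immunogenic = FALSE)
  full <- bind_rows(design, controls) %>%
    tidyr::expand_grid(cytokine = cytokines,
                       replicate = seq_len(config$replicates)) %>%
    mutate(
      rate = dplyr::case_when(
        .data$stimulus == "PHA" ~ config$pha_rate,
        .data$immunogenic ~ config$background_rate + config$effect_rate,
        .default = config$background_rate
      )
    )
  full %>%
    mutate(
      spot_count = rpois(dplyr::n(), .data$rate),
      cells_per_well = config$cells_per_well
    ) %>%
    select("patient_id", "stimulus", "cytokine", "replicate", "spot_count",
           "cells_per_well")
}

#' Generate a synthetic reference epitope set
#'
#' Seeded random 9-10-mers standing in for a reference set of known
#' immunogenic epitopes, optionally spiked with exact copies of chosen
#' candidate peptides so the foreignness score has known high-scorers.
#'
#' @param n Number of random epitopes.
#' @param seed Seed for the epitope substream.
#' @param include Peptides to append verbatim.
#' @return Character vector of epitopes.
#' @export
make_reference_epitopes <- function(n = 50, seed = 1, include = character()) {
  if (n < 0) abort("n must be >= 0")
  set.seed(substream_seed(seed, "epitopes"))
  eps <- character(0)
  if (n > 0) {
    lens <- sample(9:10, n, replace = TRUE)
    eps <- vapply(lens, random_protein, character(1))
  }
  c(eps, include)
}
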