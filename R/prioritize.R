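#' Compute per-variant allele-frequency evidence
#'
#' Adds the derived quantities the IPV filters and ranking act on: tumor and
#' normal DNA VAF, RNA VAF (alt reads / depth; defined as 0 at zero depth,
#' with a `zero_depth` flag) and the tumor genotype priority (1 = hom_alt,
#' 2 = het, 3 = hom_ref; homozygous-alternate tumors rank highest).
#'
#' @param variants A variant tibble (see [read_variant_table()]).
#' @return The input with columns `tumor_dna_vaf`, `normal_dna_vaf`,
#'   `rna_vaf`, `zero_depth`, `genotype_priority` appended.
#' @export
compute_evidence <- function(variants) {
  variants <- validate_variant_table(variants)
  safe_vaf <- function(alt, depth) ifelse(depth > 0, alt / depth, 0)
  mutate(
    variants,
    tumor_dna_vaf = safe_vaf(.data$tumor_dna_alt, .data$tumor_dna_depth),
    normal_dna_vaf = safe_vaf(.data$normal_dna_alt, .data$normal_dna_depth),
    rna_vaf = safe_vaf(.data$rna_alt, .data$rna_depth),
    zero_depth = .data$tumor_dna_depth == 0 | .data$normal_dna_depth == 0 |
      .data$rna_depth == 0,
    genotype_priority = dplyr::recode(.data$tumor_genotype,
                                      hom_alt = 1L, het = 2L, hom_ref = 3L)
  )
}

#' Apply the six IPV variant filters
#'
#' Evaluates, per variant, the six selection criteria and their conjunction:
#'
#' 1. `c1_tumor_vaf_ge_2pct`: tumor DNA VAF >= 0.02.
#' 2. `c2_nonsynonymous`: the protein HGVS annotation is a single-residue
#'    missense substitution (nonsense, frameshift, synonymous and in-frame
#'    indels are rejected — peptide design needs one mutant residue to
#'    center on).
#' 3. `c3_tumor_ge_normal_ratio`: tumor VAF >= normal VAF (a variant absent
#'    from normal passes).
#' 4. `c4_rna_observed`: at least one RNA read supports the variant.
#' 5. `c5_normal_le_5pct_and_tumor_ge_5pct`: normal VAF <= 0.05 and tumor
#'    VAF >= 0.05 (both bounds inclusive).
#' 6. `c6_coverage_ge_10`: at least 10 reads cover the site in both tumor
#'    and normal DNA.
#'
#' Criteria 1 and 5 are both applied as printed even though 5 subsumes 1;
#' both flags are reported.
#'
#' @param variants A variant tibble; evidence columns are added if absent.
#' @return The input with the six criterion flags and `overall_pass`.
#' @export
apply_ipv_filters <- function(variants) {
  if (!"tumor_dna_vaf" %in% names(variants)) {
    variants <- compute_evidence(variants)
  }
  cls <- parse_hgvs_protein(variants$hgvs_protein)$class
  mutate(
    variants,
    c1_tumor_vaf_ge_2pct = .data$tumor_dna_vaf >= 0.02,
    c2_nonsynonymous = cls == "missense",
    c3_tumor_ge_normal_ratio = .data$tumor_dna_vaf >= .data$normal_dna_vaf,
    c4_rna_observed = .data$rna_alt >= 1,
    c5_normal_le_5pct_and_tumor_ge_5pct =
      .data$normal_dna_vaf <= 0.05 & .data$tumor_dna_vaf >= 0.05,
    c6_coverage_ge_10 = .data$tumor_dna_depth >= 10 & .data$normal_dna_depth >= 10,
    overall_pass = .data$c1_tumor_vaf_ge_2pct & .data$c2_nonsynonymous &
      .data$c3_tumor_ge_normal_ratio & .data$c4_rna_observed &
      .data$c5_normal_le_5pct_and_tumor_ge_5pct & .data$c6_coverage_ge_10
  )
}

#' Midrank percentile ranks
#'
#' Percentile of each value within the vector using the midrank convention:
#' `(rank - 0.5) / n * 100`, ties sharing their mean rank. Higher values get
#' higher percentiles; for a tie-free vector the mean percentile is exactly
#' 50, and the result is invariant under positive affine transforms.
#'
#' @param values Numeric vector, length >= 1.
#' @return Numeric vector of percentiles in `[0, 100]`.
#' @export
percentile_ranks <- function(values) {
  if (length(values) == 0) abort("percentile_ranks() needs at least one value")
  if (anyNA(values)) abort("percentile_ranks() does not accept NA values")
  (rank(values, ties.method = "average") - 0.5) / length(values) * 100
}

#' Rank one patient's filtered variants
#'
#' The IPV ranking: a stable lexicographic sort on RNA VAF (descending), TPM
#' (descending) and tumor genotype priority (ascending, hom_alt first), ties
#' broken by input order. Percentile ranks (midrank convention, per donor)
#' for TPM, tumor DNA VAF and RNA VAF are attached along with their sum —
#' these are reporting metrics, not ranking keys.
#'
#' @param variants Filter-passing variants of a single patient (evidence
#'   columns are added if absent).
#' @return The input reordered, with `ipv_rank`, `tpm_pctile`,
#'   `dna_vaf_pctile`, `rna_vaf_pctile`, `pctile_sum` appended.
#' @export
rank_variants <- function(variants) {
  if (!"tumor_dna_vaf" %in% names(variants)) {
    variants <- compute_evidence(variants)
  }
  if (n_distinct(variants$patient_id) > 1) {
    abort("rank_variants() expects variants from a single patient; use prioritize_variants() for a cohort")
  }
  if (nrow(variants) == 0) {
    return(mutate(variants, ipv_rank = integer(0), tpm_pctile = double(0),
                  dna_vaf_pctile = double(0), rna_vaf_pctile = double(0),
                  pctile_sum = double(0)))
  }
  ord <- order(-variants$rna_vaf, -variants$tpm, variants$genotype_priority)
  out <- variants[ord, ]
  mutate(
    out,
    ipv_rank = row_number(),
    tpm_pctile = percentile_ranks(.data$tpm),
    dna_vaf_pctile = percentile_ranks(.data$tumor_dna_vaf),
    rna_vaf_pctile = percentile_ranks(.data$rna_vaf),
    pctile_sum = .data$tpm_pctile + .data$dna_vaf_pctile + .data$rna_vaf_pctile
  )
}

#' Filter and rank a cohort's variants
#'
#' Convenience wrapper running [apply_ipv_filters()] and, per patient,
#' [rank_variants()] on the passing variants.
#'
#' @param variants Variant tibble for one or more patients.
#' @param top Optional integer: keep only the `top` highest-ranked variants
#'   per patient.
#' @return Ranked tibble of passing variants across all patients.
#' @export
prioritize_variants <- function(variants, top = NULL) {
  flagged <- apply_ipv_filters(variants)
  passing <- filter(flagged, .data$overall_pass)
  ranked <- passing %>%
    group_split(.data$patient_id) %>%
    map(rank_variants) %>%
    list_rbind()
  if (!is.null(top)) ranked <- top_candidates(ranked, top)
  ranked
}

#' Take the top-ranked candidates per patient
#'
#' @param ranked Output of [rank_variants()] or [prioritize_variants()].
#' @param n Number of candidates to keep per patient (the screens used the
#'   top ten per prediction method).
#' @return The first `min(n, available)` variants by `ipv_rank`, per patient.
#' @export
top_candidates <- function(ranked, n = 10) {
  if (n < 0) abort("n must be >= 0")
  ranked %>%
    group_by(.data$patient_id) %>%
    arrange(.data$ipv_rank, .by_group = TRUE) %>%
    slice_head(n = n) %>%
    ungroup()
}
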