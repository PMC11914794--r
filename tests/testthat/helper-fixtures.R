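# in-code fixtures

variant_row <- function(patient_id = "P1", gene = "G1",
                        hgvs_protein = "p.Ala5Thr",
                        tumor_dna_depth = 100, tumor_dna_alt = 20,
                        normal_dna_depth = 100, normal_dna_alt = 0,
                        rna_depth = 50, rna_alt = 10, tpm = 50,
                        tumor_genotype = "het", sequence_id = gene,
                        pos = 1000, chrom = "chr1", ref = "A", alt = "G") {
  tibble::tibble(
    patient_id = patient_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, hgvs_protein = hgvs_protein,
    tumor_dna_depth = tumor_dna_depth, tumor_dna_alt = tumor_dna_alt,
    normal_dna_depth = normal_dna_depth, normal_dna_alt = normal_dna_alt,
    rna_depth = rna_depth, rna_alt = rna_alt, tpm = tpm,
    tumor_genotype = tumor_genotype, sequence_id = sequence_id
  )
}

# a tiny plate: one patient, triplicate controls + stimuli with fixed counts
plate_fixture <- function(patient_id = "P1", stimuli, cytokine = "IFNg",
                          cells = 1e5, replicates = 3) {
  rows <- lapply(names(stimuli), function(s) {
    tibble::tibble(
      patient_id = patient_id, stimulus = s, cytokine = cytokine,
      replicate = seq_len(replicates), spot_count = stimuli[[s]],
      cells_per_well = cells
    )
  })
  dplyr::bind_rows(rows)
}

# constant-ic50 predictor for deterministic design tests
fixed_predictor <- function(table) {
  function(peptides, alleles) {
    key <- paste(peptides, alleles)
    tibble::tibble(
      peptide = peptides, allele = alleles,
      ic50_nm = unname(table[key]),
      stability_hours = 5
    )
  }
}
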