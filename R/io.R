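#' Read a somatic variant table
#'
#' Reads the canonical tab-separated variant table: one row per somatic
#' variant with tumor/normal DNA and tumor RNA allele counts, gene-level TPM,
#' a protein-level HGVS annotation and the tumor genotype. This table is the
#' contract between upstream variant calling/annotation (out of scope here)
#' and the prioritization functions.
#'
#' Required columns: `patient_id, chrom, pos, ref, alt, gene, hgvs_protein,
#' tumor_dna_depth, tumor_dna_alt, normal_dna_depth, normal_dna_alt,
#' rna_depth, rna_alt, tpm, tumor_genotype`. An optional `sequence_id` column
#' names the protein record used for peptide design; it defaults to `gene`.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per variant, in file order.
#' @export
read_variant_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    chrom = readr::col_character(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    gene = readr::col_character(),
    hgvs_protein = readr::col_character(),
    tumor_genotype = readr::col_character(),
    sequence_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_variant_table(df)
}

required_variant_cols <- c(
  "patient_id", "chrom", "pos", "ref", "alt", "gene", "hgvs_protein",
  "tumor_dna_depth", "tumor_dna_alt", "normal_dna_depth", "normal_dna_alt",
  "rna_depth", "rna_alt", "tpm", "tumor_genotype"
)

#' Validate a variant table
#'
#' Checks column presence, numeric parsing, count/depth consistency and the
#' genotype vocabulary. Violations are fatal and name the offending column or
#' line (line numbers count the header as line 1).
#'
#' @param df A data frame of variants.
#' @return The validated tibble (invisibly identical content).
#' @export
validate_variant_table <- function(df) {
  missing <- setdiff(required_variant_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("variant table missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (!"sequence_id" %in% names(df)) df$sequence_id <- df$gene
  if (nrow(df) == 0) return(df)

  count_cols <- c("pos", "tumor_dna_depth", "tumor_dna_alt", "normal_dna_depth",
                  "normal_dna_alt", "rna_depth", "rna_alt")
  for (col in count_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(sprintf("non-numeric value in column '%s' at line %s", col,
                    paste(which(is.na(suppressWarnings(as.numeric(v)))) + 1L,
                          collapse = ", ")))
    }
    if (any(v < 0) || any(v != floor(v))) {
      abort(sprintf("column '%s' must hold non-negative integers (line %s)",
                    col, paste(which(v < 0 | v != floor(v)) + 1L, collapse = ", ")))
    }
  }
  if (any(df$tpm < 0)) {
    abort(sprintf("tpm must be >= 0 (line %s)",
                  paste(which(df$tpm < 0) + 1L, collapse = ", ")))
  }
  line_check <- function(bad, msg) {
    if (any(bad)) abort(sprintf("%s (line %s)", msg,
                                paste(which(bad) + 1L, collapse = ", ")))
  }
  line_check(df$tumor_dna_alt > df$tumor_dna_depth,
             "tumor_dna_alt exceeds tumor_dna_depth")
  line_check(df$normal_dna_alt > df$normal_dna_depth,
             "normal_dna_alt exceeds normal_dna_depth")
  line_check(df$rna_alt > df$rna_depth, "rna_alt exceeds rna_depth")
  line_check(df$ref == df$alt, "ref allele equals alt allele")
  line_check(!df$tumor_genotype %in% c("hom_ref", "het", "hom_alt"),
             "tumor_genotype must be one of hom_ref, het, hom_alt")
  df
}

#' Write a variant table
#'
#' @param df A validated variant tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and checked against the 20 standard residues.
#' Record ids must be unique: they are the keys the variant table's
#' `sequence_id` column points at.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% AA_STANDARD),
                 logical(1))
  if (any(bad)) {
    abort(paste0("non-amino-acid character in record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a peptide binding/stability prediction table
#'
#' Adapter for precomputed predictor output (e.g. NetMHCpan-style runs
#' exported as TSV). Rows are keyed by `(peptide, allele)`; a duplicated key
#' with conflicting values is an error, identical duplicates are collapsed.
#'
#' @param path TSV with columns `peptide, allele, ic50_nm, stability_hours`
#'   (`stability_hours` may be empty/NA).
#' @return A tibble of predictions.
#' @export
read_predictions <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    peptide = readr::col_character(),
    allele = readr::col_character(),
    ic50_nm = readr::col_double(),
    stability_hours = readr::col_double()
  ), progress = FALSE)
  need <- c("peptide", "allele", "ic50_nm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("predictions missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"stability_hours" %in% names(df)) df$stability_hours <- NA_real_
  if (nrow(df) == 0) return(as_tibble(df))
  assert_standard_aa(df$peptide, "predictions peptide column")
  if (any(!is.finite(df$ic50_nm)) || any(df$ic50_nm <= 0)) {
    abort("ic50_nm must be a positive finite number (IC50 in nM)")
  }
  if (any(!is.na(df$stability_hours) & df$stability_hours < 0)) {
    abort("stability_hours must be >= 0")
  }
  df <- distinct(df)
  key <- paste(df$peptide, df$allele, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("conflicting duplicate prediction(s) for (peptide, allele): ",
                 paste(gsub("\r", "/", dup), collapse = ", ")))
  }
  as_tibble(df)
}

#' Write a prediction table
#' @param df Prediction tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read ELISpot/Fluorospot plate counts
#'
#' One row per well: a stimulus (peptide pool, single-variant peptide set,
#' `"DMSO"`, `"media"` or `"PHA"`), the cytokine read out, the replicate
#' index, the raw spot count and the number of PBMC plated in the well.
#'
#' @param path CSV with columns `patient_id, stimulus, cytokine, replicate,
#'   spot_count, cells_per_well`.
#' @return A tibble of plate wells.
#' @export
read_plate_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    stimulus = readr::col_character(),
    cytokine = readr::col_character(),
    replicate = readr::col_double(),
    spot_count = readr::col_double(),
    cells_per_well = readr::col_double()
  ), progress = FALSE)
  validate_plate_wells(df)
}

#' Validate plate wells
#' @param df A data frame of wells.
#' @return The validated tibble.
#' @export
validate_plate_wells <- function(df) {
  need <- c("patient_id", "stimulus", "cytokine", "replicate", "spot_count",
            "cells_per_well")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("plate table missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (nrow(df) == 0) return(df)
  if (any(!df$cytokine %in% c("IFNg", "IL5"))) {
    abort(paste0("unknown cytokine label: ",
                 paste(unique(setdiff(df$cytokine, c("IFNg", "IL5"))), collapse = ", ")))
  }
  if (any(df$cells_per_well <= 0)) abort("cells_per_well must be > 0")
  if (any(df$spot_count < 0) || any(!is.finite(df$spot_count))) {
    abort("spot_count must be a finite non-negative number")
  }
  if (any(df$replicate < 1)) abort("replicate index must be >= 1")
  df
}

#' Write plate counts to CSV
#' @param df Plate-well tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a reference epitope set
#'
#' The reference set of known immunogenic epitopes that the foreignness score
#' aligns candidates against. Accepts either a FASTA file or a single-column
#' text/TSV file of peptide sequences (a header line `peptide` is allowed).
#'
#' @param path FASTA or single-column text file.
#' @return Character vector of epitope sequences.
#' @export
read_reference_epitopes <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && startsWith(first, ">")) {
    eps <- unname(read_protein_fasta(path))
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    if (length(lines) > 0 && tolower(lines[1]) == "peptide") lines <- lines[-1]
    eps <- toupper(lines)
    if (length(eps) > 0) assert_standard_aa(eps, "reference epitopes")
  }
  eps
}

#' Write a reference epitope set
#' @param epitopes Character vector of peptides.
#' @param path Output path (single-column TSV with header `peptide`).
#' @return `path`, invisibly.
#' @export
write_reference_epitopes <- function(epitopes, path) {
  writeLines(c("peptide", epitopes), path)
  invisible(path)
}
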