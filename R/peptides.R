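#' Build a protein mutation context from an HGVS annotation
#'
#' Parses a protein-level HGVS substitution, verifies the annotated reference
#' residue against the protein sequence, and returns the context peptide
#' design works from. Only single-residue missense substitutions are
#' supported: nonsense, frameshift, synonymous and in-frame indel classes
#' have no single mutant residue to center a peptide on.
#'
#' @param protein Amino-acid sequence (character scalar, standard residues).
#' @param hgvs_protein Annotation such as `"p.Asn4Lys"` or `"p.N4K"`.
#' @return A list with `protein`, `mut_protein` (sequence with the
#'   substitution applied), `mut_pos` (1-based), `wt_residue`, `mut_residue`.
#' @export
context_from_hgvs <- function(protein, hgvs_protein) {
  assert_standard_aa(protein, "protein")
  p <- parse_hgvs_protein(hgvs_protein)
  if (p$class != "missense") {
    abort(sprintf("unsupported variant class '%s' for %s: peptide design requires a missense substitution",
                  p$class, hgvs_protein))
  }
  if (p$pos < 1 || p$pos > nchar(protein)) {
    abort(sprintf("mutation position %d outside protein of length %d",
                  p$pos, nchar(protein)))
  }
  ref <- substr(protein, p$pos, p$pos)
  if (ref != p$wt_residue) {
    abort(sprintf("reference residue mismatch at position %d: protein has %s, annotation %s says %s",
                  p$pos, ref, hgvs_protein, p$wt_residue))
  }
  mut_protein <- protein
  substr(mut_protein, p$pos, p$pos) <- p$mut_residue
  list(protein = protein, mut_protein = mut_protein, mut_pos = p$pos,
       wt_residue = p$wt_residue, mut_residue = p$mut_residue)
}

# vectorized over start/len
peptide_row <- function(ctx, start, len, klass, design_offset = NA_integer_) {
  tibble(
    klass = klass,
    sequence = substring(ctx$mut_protein, start, start + len - 1L),
    wt_sequence = substring(ctx$protein, start, start + len - 1L),
    mut_offset = ctx$mut_pos - as.integer(start) + 1L,
    length = as.integer(len),
    window_start = as.integer(start),
    design_offset = as.integer(design_offset),
    clamped = FALSE
  )
}

#' Design the two overlapping IPV 20-mers
#'
#' For a missense variant, IPV emits two 20-mer peptides placing the mutant
#' residue at positions 6 and 15 respectively, so that between them the
#' majority of possible class I and class II epitopes spanning the mutation
#' are covered. Windows that would fall off a protein terminus are shifted
#' minimally to fit while keeping length 20 (`clamped = TRUE`, mutant offset
#' recomputed); a protein shorter than 20 residues yields a single clamped
#' candidate equal to the whole protein. Identical windows collapse to one.
#'
#' @param ctx A context from [context_from_hgvs()].
#' @return A tibble of 1-2 candidates, `klass = "ipv_long"`.
#' @export
design_ipv_long <- function(ctx) {
  L <- nchar(ctx$protein)
  if (L < 20) {
    row <- peptide_row(ctx, 1L, L, "ipv_long", design_offset = 6L)
    row$clamped <- TRUE
    return(row)
  }
  rows <- map(c(6L, 15L), function(off) {
    start <- ctx$mut_pos - (off - 1L)
    start_clamped <- min(max(start, 1L), L - 19L)
    row <- peptide_row(ctx, start_clamped, 20L, "ipv_long", design_offset = off)
    row$clamped <- start_clamped != start
    row
  })
  out <- list_rbind(rows)
  out[!duplicated(out$window_start), ]
}

#' Enumerate all mutation-spanning 8-12-mers
#'
#' Every window of each requested length that contains the mutant residue,
#' paired with its wild-type counterpart. With at least 11 flanking residues
#' on both sides there are `8+9+10+11+12 = 50` such peptides; a mutation at
#' a terminus yields one window per length. Order is deterministic: length
#' ascending, window start ascending.
#'
#' @param ctx A context from [context_from_hgvs()].
#' @param lengths Integer vector of peptide lengths (default `8:12`).
#' @return A tibble of candidates, `klass = "tesla_short"` (empty, with a
#'   warning, if the protein is shorter than the smallest length).
#' @export
enumerate_short_spanning <- function(ctx, lengths = 8:12) {
  L <- nchar(ctx$protein)
  empty <- peptide_row(ctx, 1L, 0L, character(0))[0, ]
  if (L < min(lengths)) {
    warn(sprintf("protein of length %d is shorter than the smallest window (%d); no peptides enumerated",
                 L, min(lengths)))
    return(empty)
  }
  all_starts <- integer(0)
  all_lens <- integer(0)
  for (k in sort(lengths)) {
    if (k > L) next
    starts <- seq.int(max(1L, ctx$mut_pos - k + 1L), min(L - k + 1L, ctx$mut_pos))
    all_starts <- c(all_starts, starts)
    all_lens <- c(all_lens, rep(k, length(starts)))
  }
  if (length(all_starts) == 0) return(empty)
  peptide_row(ctx, all_starts, all_lens, "tesla_short")
}

#' Select the top-binding short peptides from IPV long peptides
#'
#' Scores every mutation-spanning 8-12-mer found inside the given IPV
#' 20-mers against the patient's HLA alleles and keeps the `n` unique
#' sequences with the strongest (lowest) best IC50. Ties break by length
#' ascending, then alphabetically.
#'
#' @param longs Tibble of `ipv_long` candidates (from [design_ipv_long()],
#'   possibly for several variants; must carry `sequence`, `wt_sequence`,
#'   `mut_offset`).
#' @param alleles Character vector of the patient's HLA class I alleles.
#' @param predictor A predictor function (see [mock_predictor()] /
#'   [predictor_from_table()]).
#' @param n Number of short peptides to keep.
#' @return A tibble of candidates, `klass = "ipv_short"`, IC50 ascending.
#' @export
select_ipv_short <- function(longs, alleles, predictor, n = 10) {
  shorts <- map(seq_len(nrow(longs)), function(i) {
    row <- longs[i, ]
    len <- nchar(row$sequence)
    all_starts <- integer(0)
    all_lens <- integer(0)
    for (k in 8:12) {
      if (k > len) next
      starts <- seq.int(max(1L, row$mut_offset - k + 1L),
                        min(len - k + 1L, row$mut_offset))
      all_starts <- c(all_starts, starts)
      all_lens <- c(all_lens, rep(k, length(starts)))
    }
    if (length(all_starts) == 0) return(NULL)
    out <- tibble(
      klass = "ipv_short",
      sequence = substring(row$sequence, all_starts, all_starts + all_lens - 1L),
      wt_sequence = substring(row$wt_sequence, all_starts,
                              all_starts + all_lens - 1L),
      mut_offset = row$mut_offset - all_starts + 1L,
      length = all_lens,
      window_start = NA_integer_,
      design_offset = NA_integer_,
      clamped = FALSE
    )
    for (col in setdiff(names(longs), names(out))) out[[col]] <- row[[col]]
    out
  }) %>% list_rbind()
  shorts <- shorts[!duplicated(shorts$sequence), ]
  scored <- best_binding(shorts$sequence, alleles, predictor)
  shorts$best_ic50_nm <- scored$best_ic50_nm
  shorts$best_allele <- scored$best_allele
  ord <- order(shorts$best_ic50_nm, shorts$length, shorts$sequence)
  shorts <- shorts[ord, ]
  shorts[seq_len(min(n, nrow(shorts))), ]
}

#' Lengthen a TESLA short peptide to its containing IPV 20-mer
#'
#' Returns the IPV 20-mer of the same variant whose sequence contains the
#' short peptide as a substring. If both 20-mers contain it, the one whose
#' mutant offset lies closest to the center of the matched short window is
#' chosen, ties going to the offset-6 peptide.
#'
#' @param short A single-row `tesla_short` candidate.
#' @param ipv_longs The variant's `ipv_long` candidates.
#' @return The chosen 20-mer as a one-row tibble, `klass = "tesla_long"`,
#'   with the originating short sequence in `tesla_short_sequence`.
#' @export
lengthen_tesla <- function(short, ipv_longs) {
  hit <- stringr::str_detect(ipv_longs$sequence, stringr::fixed(short$sequence))
  if (!any(hit)) {
    abort(sprintf("no IPV 20-mer contains the short peptide %s", short$sequence))
  }
  cand <- ipv_longs[hit, ]
  pos <- stringr::str_locate(cand$sequence, stringr::fixed(short$sequence))[, "start"]
  center <- pos + (nchar(short$sequence) - 1) / 2
  dist <- abs(center - cand$mut_offset)
  best <- which(dist == min(dist))
  if (length(best) > 1) {
    pref <- best[cand$design_offset[best] == 6L]
    best <- if (length(pref) > 0) pref[1] else best[1]
  }
  out <- cand[best, ]
  out$klass <- "tesla_long"
  out$tesla_short_sequence <- short$sequence
  out
}

#' Design candidate peptides for ranked variants
#'
#' Runs [design_ipv_long()] and [enumerate_short_spanning()] for every
#' variant in a ranked table, looking each variant's protein up by its
#' `sequence_id`.
#'
#' @param ranked Ranked variant tibble (see [prioritize_variants()]).
#' @param proteins Named character vector of protein sequences.
#' @param classes Which candidate classes to emit (subset of
#'   `c("ipv_long", "tesla_short")`; the predictor-dependent `ipv_short` /
#'   `tesla_long` classes are built by [select_ipv_short()] and
#'   [lengthen_tesla()]).
#' @return A tibble of candidates with `patient_id`, `gene`, `sequence_id`,
#'   `hgvs_protein` carried along.
#' @export
design_peptides <- function(ranked, proteins,
                            classes = c("ipv_long", "tesla_short")) {
  classes <- arg_match(classes, c("ipv_long", "tesla_short"), multiple = TRUE)
  rows <- map(seq_len(nrow(ranked)), function(i) {
    v <- ranked[i, ]
    if (!v$sequence_id %in% names(proteins)) {
      abort(sprintf("no protein sequence for sequence_id '%s'", v$sequence_id))
    }
    ctx <- context_from_hgvs(proteins[[v$sequence_id]], v$hgvs_protein)
    parts <- list()
    if ("ipv_long" %in% classes) parts$long <- design_ipv_long(ctx)
    if ("tesla_short" %in% classes) parts$short <- enumerate_short_spanning(ctx)
    out <- list_rbind(parts)
    if (nrow(out) > 0) {
      out$patient_id <- v$patient_id
      out$gene <- v$gene
      out$sequence_id <- v$sequence_id
      out$hgvs_protein <- v$hgvs_protein
    }
    out
  })
  list_rbind(rows)
}
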