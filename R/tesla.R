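#' TESLA candidate-selection thresholds
#'
#' The consortium's published cutoffs for a minimal-epitope candidate: best
#' HLA binding affinity below 68 nM, binding stability above 1.7 hours,
#' tumor abundance above 10 TPM, agretopicity below 0.1 and foreignness
#' above 1e-16. All comparisons are strict.
#'
#' @param ic50_nm,stability_hours,tpm,agretopicity,foreignness Cutoff values.
#' @return Named list of thresholds.
#' @export
tesla_thresholds <- function(ic50_nm = 68, stability_hours = 1.7, tpm = 10,
                             agretopicity = 0.1, foreignness = 1e-16) {
  list(ic50_nm = ic50_nm, stability_hours = stability_hours, tpm = tpm,
       agretopicity = agretopicity, foreignness = foreignness)
}

#' Agretopicity: mutant-to-wild-type affinity ratio
#'
#' The ratio of the mutant peptide's predicted IC50 to the wild-type
#' counterpart's IC50 on the same HLA allele (the mutant's best allele).
#' Values well below 1 mean the mutation created binding the wild-type
#' peptide lacks.
#'
#' @param mut_ic50_nm,wt_ic50_nm Positive IC50 values in nM.
#' @return `mut_ic50_nm / wt_ic50_nm`.
#' @export
agretopicity <- function(mut_ic50_nm, wt_ic50_nm) {
  if (any(!is.finite(mut_ic50_nm)) || any(!is.finite(wt_ic50_nm)) ||
      any(mut_ic50_nm <= 0) || any(wt_ic50_nm <= 0)) {
    abort("agretopicity() requires positive finite IC50 values")
  }
  mut_ic50_nm / wt_ic50_nm
}

#' Gapless local alignment score
#'
#' Maximum over all gapless local alignments (every offset, every contiguous
#' sub-window) of the summed substitution scores between two peptides, with
#' a floor of 0. This is the similarity kernel of the foreignness score.
#'
#' @param a,b Amino-acid sequences (standard residues).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return Integer alignment score (>= 0).
#' @export
alignment_score <- function(a, b, matrix = blosum62()) {
  assert_standard_aa(c(a, b), "alignment input")
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x)
  n <- length(y)
  best <- 0
  # for each diagonal, max-subarray (Kadane) over the aligned pair scores
  for (d in seq.int(-(n - 1L), m - 1L)) {
    i0 <- max(1L, 1L + d)
    j0 <- i0 - d
    len <- min(m - i0, n - j0) + 1L
    s <- matrix[cbind(x[i0:(i0 + len - 1L)], y[j0:(j0 + len - 1L)])]
    # max contiguous-subarray sum via prefix sums
    p <- cumsum(s)
    d_best <- max(p - cummin(c(0, p[-len])))
    if (d_best > best) best <- d_best
  }
  as.integer(best)
}

#' Foreignness: similarity to known immunogenic epitopes
#'
#' The recognition-probability-style score used by the TESLA selection
#' criteria: with gapless local alignment scores `s(p, e)` against each
#' reference epitope `e`, `S = sum(exp(-k * (a - s)))` and the foreignness
#' is `R = S / (1 + S)`, a value in `[0, 1)`. An epitope scoring exactly at
#' the displacement `a` contributes `exp(0) = 1`; an empty reference set
#' gives 0. `R` is monotone non-decreasing in every alignment score and
#' under adding reference epitopes.
#'
#' @param peptide Candidate peptide.
#' @param reference_epitopes Character vector of reference epitopes.
#' @param midpoint_a Alignment-score displacement (default 26).
#' @param steepness_k Steepness of the alignment-score weighting
#'   (default 4.87); must be positive.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return Foreignness score in `[0, 1)`.
#' @export
foreignness <- function(peptide, reference_epitopes, midpoint_a = 26,
                        steepness_k = 4.87, matrix = blosum62()) {
  if (steepness_k <= 0) abort("steepness_k must be > 0")
  if (length(reference_epitopes) == 0) return(0)
  s <- map_dbl(reference_epitopes, function(e) {
    alignment_score(peptide, e, matrix)
  })
  S <- sum(exp(-steepness_k * (midpoint_a - s)))
  if (!is.finite(S)) return(1 - 1e-16)
  S / (1 + S)
}

#' Compute the TESLA metrics for short candidate peptides
#'
#' For each mutation-spanning 8-12-mer: best IC50 and stability across the
#' patient's alleles, tumor abundance (TPM, carried on the candidate table),
#' agretopicity (wild-type counterpart scored on the mutant's best allele),
#' and foreignness against the reference epitope set.
#'
#' @param candidates Tibble of `tesla_short` candidates with `sequence`,
#'   `wt_sequence` and `tpm` columns.
#' @param alleles Patient HLA alleles.
#' @param predictor A predictor function.
#' @param reference_epitopes Character vector for the foreignness score.
#' @param midpoint_a,steepness_k Foreignness parameters (see
#'   [foreignness()]).
#' @param thresholds Output of [tesla_thresholds()].
#' @return The candidates with metric columns and pass/fail flags appended
#'   (see [tesla_filter()]).
#' @export
tesla_metrics <- function(candidates, alleles, predictor, reference_epitopes,
                          midpoint_a = 26, steepness_k = 4.87,
                          thresholds = tesla_thresholds()) {
  if (!"tpm" %in% names(candidates)) {
    abort("candidates must carry a tpm column (tumor abundance of the source gene)")
  }
  mut <- best_binding(candidates$sequence, alleles, predictor)
  wt <- predictor(candidates$wt_sequence, mut$best_allele)
  out <- candidates
  out$best_ic50_nm <- mut$best_ic50_nm
  out$best_allele <- mut$best_allele
  out$stability_hours <- mut$stability_hours
  out$wt_ic50_nm <- wt$ic50_nm
  out$agretopicity <- agretopicity(out$best_ic50_nm, out$wt_ic50_nm)
  out$foreignness <- map_dbl(out$sequence, foreignness,
                             reference_epitopes = reference_epitopes,
                             midpoint_a = midpoint_a, steepness_k = steepness_k)
  tesla_filter(out, thresholds)
}

#' Apply the TESLA thresholds
#'
#' Strict-inequality flags for the five criteria and their conjunction. A
#' candidate with missing stability cannot demonstrate the stability
#' criterion and fails with `stability_missing = TRUE` rather than silently
#' passing.
#'
#' @param metrics Tibble with `best_ic50_nm`, `stability_hours`, `tpm`,
#'   `agretopicity`, `foreignness`.
#' @param thresholds Output of [tesla_thresholds()].
#' @return The input with flags `c_affinity`, `c_stability`, `c_abundance`,
#'   `c_agretopicity`, `c_foreignness`, `stability_missing`, `overall_pass`.
#' @export
tesla_filter <- function(metrics, thresholds = tesla_thresholds()) {
  mutate(
    as_tibble(metrics),
    c_affinity = .data$best_ic50_nm < thresholds$ic50_nm,
    stability_missing = is.na(.data$stability_hours),
    c_stability = !is.na(.data$stability_hours) &
      .data$stability_hours > thresholds$stability_hours,
    c_abundance = .data$tpm > thresholds$tpm,
    c_agretopicity = .data$agretopicity < thresholds$agretopicity,
    c_foreignness = .data$foreignness > thresholds$foreignness,
    overall_pass = .data$c_affinity & .data$c_stability & .data$c_abundance &
      .data$c_agretopicity & .data$c_foreignness
  )
}

#' Rank filter-passing TESLA candidates
#'
#' Ascending best IC50; ties by descending foreignness, then alphabetical
#' sequence. Ranks are assigned 1..n.
#'
#' @param metrics Tibble of candidates (typically filtered to
#'   `overall_pass`).
#' @return The input reordered with a `tesla_rank` column.
#' @export
tesla_rank <- function(metrics) {
  if (nrow(metrics) == 0) return(mutate(metrics, tesla_rank = integer(0)))
  if ("patient_id" %in% names(metrics) && n_distinct(metrics$patient_id) > 1) {
    abort("tesla_rank() expects candidates from a single patient")
  }
  ord <- order(metrics$best_ic50_nm, -metrics$foreignness, metrics$sequence)
  out <- metrics[ord, ]
  mutate(out, tesla_rank = row_number())
}
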