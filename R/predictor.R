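# Predictors map (peptide, allele) pairs to predicted binding affinity
# (IC50, nM) and binding stability (hours). A predictor is a function
# f(peptides, alleles) over equal-length character vectors returning a tibble
# with columns peptide, allele, ic50_nm, stability_hours.

# 32-bit FNV-1a over a string, in double arithmetic (exact below 2^53)
fnv1a32 <- function(str) {
  h <- 2166136261
  for (b in utf8ToInt(str)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

fnv_unit <- function(key) fnv1a32(key) / 4294967296

#' Deterministic mock binding predictor
#'
#' A stand-in for external binding/stability predictors with the same
#' interface, for simulation and testing. IC50 is drawn log-uniform in
#' `[1, 50000)` nM and stability uniform in `[0.1, 10)` hours, both from a
#' counter-free generator keyed by the 32-bit FNV-1a hash of
#' `"seed|peptide|allele"` — identical inputs yield identical outputs on any
#' platform, and different peptides or alleles decorrelate.
#'
#' @param seed Integer seed folded into every hash key.
#' @return A predictor function `f(peptides, alleles)`.
#' @export
mock_predictor <- function(seed = 0) {
  force(seed)
  function(peptides, alleles) {
    stopifnot(length(peptides) == length(alleles))
    assert_standard_aa(peptides, "peptides")
    u1 <- map_dbl(paste(seed, peptides, alleles, "ic50", sep = "|"), fnv_unit)
    u2 <- map_dbl(paste(seed, peptides, alleles, "stab", sep = "|"), fnv_unit)
    tibble(
      peptide = peptides,
      allele = alleles,
      ic50_nm = 10^(u1 * log10(50000)),
      stability_hours = 0.1 + u2 * 9.9
    )
  }
}

#' Predictor backed by a precomputed prediction table
#'
#' Wraps a table read by [read_predictions()] into the predictor interface.
#' A requested `(peptide, allele)` pair absent from the table is an error
#' naming the pair.
#'
#' @param predictions Tibble with `peptide`, `allele`, `ic50_nm`,
#'   `stability_hours`.
#' @return A predictor function `f(peptides, alleles)`.
#' @export
predictor_from_table <- function(predictions) {
  key <- paste(predictions$peptide, predictions$allele, sep = "\r")
  ic50 <- stats::setNames(predictions$ic50_nm, key)
  stab <- stats::setNames(predictions$stability_hours, key)
  function(peptides, alleles) {
    stopifnot(length(peptides) == length(alleles))
    k <- paste(peptides, alleles, sep = "\r")
    miss <- !k %in% names(ic50)
    if (any(miss)) {
      abort(paste0("no prediction for (peptide, allele) pair(s): ",
                   paste(gsub("\r", "/", unique(k[miss])), collapse = ", ")))
    }
    tibble(peptide = peptides, allele = alleles,
           ic50_nm = unname(ic50[k]), stability_hours = unname(stab[k]))
  }
}

#' Best predicted binding across a patient's alleles
#'
#' For each peptide, the minimum IC50 across the supplied HLA alleles; the
#' reported stability comes from that same best allele.
#'
#' @param peptides Character vector of peptides.
#' @param alleles Character vector of HLA alleles (length >= 1).
#' @param predictor A predictor function.
#' @return Tibble with `peptide`, `best_ic50_nm`, `best_allele`,
#'   `stability_hours`, one row per input peptide (input order).
#' @export
best_binding <- function(peptides, alleles, predictor) {
  if (length(alleles) == 0) abort("best_binding() needs at least one allele")
  grid <- tidyr::expand_grid(peptide = unique(peptides), allele = alleles)
  pred <- predictor(grid$peptide, grid$allele)
  best <- pred %>%
    group_by(.data$peptide) %>%
    arrange(.data$ic50_nm, .data$allele, .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    rename(best_ic50_nm = "ic50_nm", best_allele = "allele")
  out <- left_join(tibble(peptide = peptides), best, by = "peptide")
  select(out, "peptide", "best_ic50_nm", "best_allele", "stability_hours")
}
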