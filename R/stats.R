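as_contingency <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2, 2))) abort("contingency table must be 2x2")
    m <- x
  } else if (is.numeric(x) && length(x) == 4) {
    # row-major: a, b, c, d
    m <- matrix(x, nrow = 2, byrow = TRUE)
  } else {
    abort("supply a 2x2 matrix or a numeric vector c(a, b, c, d)")
  }
  if (any(m < 0) || any(m != floor(m))) {
    abort("contingency entries must be non-negative integers")
  }
  if (sum(m) == 0) abort("contingency table must have at least one count")
  m
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-mass convention: the sum,
#' over all tables with the observed margins, of hypergeometric probabilities
#' no larger than the observed table's (equal-probability ties included up
#' to a small relative tolerance). This is the convention of
#' `stats::fisher.test()` and the one under which the printed 2x2 p-values
#' of pool-comparison tables reproduce exactly.
#'
#' @param x A 2x2 matrix (rows = groups, columns = positive/negative) or a
#'   length-4 vector `c(a, b, c, d)` read row-wise.
#' @return The two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(x) {
  m <- as_contingency(x)
  unname(stats::fisher.test(m)$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. `U` is computed with midranks for
#' ties. The p-value is exact (full enumeration of the rank distribution)
#' when the combined sample size is at most `exact_max` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest combined sample size for the exact path
#'   (default 16).
#' @return A one-row tibble: `U` (for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 16) {
  if (length(x) == 0 || length(y) == 0) {
    abort("mann_whitney_u() requires two non-empty samples")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble(
    U = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Build the long-vs-short peptide contingency table
#'
#' Re-stratifies a cohort summary by peptide length: positive/negative
#' counts of the 20-mer pools (`ipv_long` + `tesla_long`) against those of
#' the 8-12-mer pools (`tesla_short` + `ipv_short`), for one cytokine.
#'
#' @param summary Output of [summarize_cohort()].
#' @param cytokine `"IFNg"` or `"IL5"`.
#' @param long_pools,short_pools Pool labels contributing to each row.
#' @return A 2x2 integer matrix (rows long/short, columns
#'   positive/negative).
#' @export
build_length_contingency <- function(summary, cytokine,
                                     long_pools = c("ipv_long", "tesla_long"),
                                     short_pools = c("tesla_short", "ipv_short")) {
  s <- filter(summary, .data$cytokine == !!cytokine)
  missing <- setdiff(c(long_pools, short_pools), s$pool)
  if (length(missing) > 0) {
    abort(paste0("summary is missing pool class(es): ",
                 paste(missing, collapse = ", ")))
  }
  row_of <- function(pools) {
    rows <- filter(s, .data$pool %in% pools)
    c(sum(rows$n_positive), sum(rows$n_negative))
  }
  m <- rbind(long = row_of(long_pools), short = row_of(short_pools))
  colnames(m) <- c("positive", "negative")
  storage.mode(m) <- "integer"
  m
}

#' Compare percentile ranks of positive vs negative candidates
#'
#' The per-donor percentile ranks of a prioritization metric (TPM, tumor DNA
#' VAF, RNA VAF, or their sum) are compared between candidates whose
#' peptides elicited a positive cytokine response and those that did not,
#' with a two-sided Mann-Whitney test.
#'
#' @param candidates Tibble carrying the percentile columns from
#'   [rank_variants()] and a logical `positive` column.
#' @param metric One of `"tpm"`, `"dna_vaf"`, `"rna_vaf"`, `"sum"`.
#' @return A `rank_comparison` object (supports `tidy()`, `glance()`,
#'   `autoplot()`).
#' @export
compare_metric_ranks <- function(candidates,
                                 metric = c("tpm", "dna_vaf", "rna_vaf", "sum")) {
  metric <- arg_match(metric)
  col <- switch(metric, tpm = "tpm_pctile", dna_vaf = "dna_vaf_pctile",
                rna_vaf = "rna_vaf_pctile", sum = "pctile_sum")
  if (!col %in% names(candidates) || !"positive" %in% names(candidates)) {
    abort(sprintf("candidates must carry '%s' and 'positive' columns", col))
  }
  keep <- !is.na(candidates$positive)   # untested candidates carry no label
  pos <- candidates[[col]][keep & candidates$positive %in% TRUE]
  neg <- candidates[[col]][keep & candidates$positive %in% FALSE]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("need at least one positive and one negative candidate")
  }
  mw <- mann_whitney_u(pos, neg)
  structure(
    list(metric = metric, positive = pos, negative = neg,
         U = mw$U, p_value = mw$p_value, method = mw$method,
         significant = mw$p_value <= 0.05),
    class = "rank_comparison"
  )
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf(
    "Percentile-rank comparison (%s): %d positive vs %d negative\n  U = %g, two-sided p = %.4g (%s)%s\n",
    x$metric, length(x$positive), length(x$negative), x$U, x$p_value,
    x$method, if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Tidy a rank comparison
#' @param x A `rank_comparison` object.
#' @param ... Unused.
#' @return One-row tibble of the test result.
#' @export
tidy.rank_comparison <- function(x, ...) {
  tibble(
    metric = x$metric,
    n_positive = length(x$positive),
    n_negative = length(x$negative),
    median_positive = stats::median(x$positive),
    median_negative = stats::median(x$negative),
    statistic = x$U,
    p_value = x$p_value,
    method = x$method
  )
}

#' Glance at a rank comparison
#' @param x A `rank_comparison` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `significant`.
#' @export
glance.rank_comparison <- function(x, ...) {
  tibble(statistic = x$U, p_value = x$p_value, significant = x$significant)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
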