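test_that("best_binding takes the minimum IC50 and its allele's stability", {
  pred <- fixed_predictor(c(
    "SIINFEKL HLA-A*02:01" = 40, "SIINFEKL HLA-B*07:02" = 900
  ))
  out <- best_binding("SIINFEKL", c("HLA-A*02:01", "HLA-B*07:02"), pred)
  expect_equal(out$best_ic50_nm, 40)
  expect_equal(out$best_allele, "HLA-A*02:01")
  one <- best_binding("SIINFEKL", "HLA-B*07:02", pred)
  expect_equal(one$best_ic50_nm, 900)
  expect_error(best_binding("SIINFEKL", character(0), pred), "at least one allele")
  tab <- predictor_from_table(tibble::tibble(
    peptide = "SIINFEKL", allele = "HLA-A*02:01",
    ic50_nm = 40, stability_hours = 2
  ))
  expect_error(best_binding("SIINFEKL", c("HLA-A*02:01", "HLA-C*01:02"), tab),
               "SIINFEKL/HLA-C\\*01:02")
})

test_that("agretopicity is the mutant/wild-type affinity ratio", {
  expect_equal(agretopicity(5, 100), 0.05)
  expect_equal(agretopicity(42, 42), 1)
  expect_error(agretopicity(5, 0), "positive")
  expect_error(agretopicity(-1, 10), "positive")
})

test_that("self-alignment of SIINFEKL sums the BLOSUM62 diagonal to 38", {
  expect_equal(alignment_score("SIINFEKL", "SIINFEKL"), 38L)
  expect_error(alignment_score("SIINFEKX", "SIINFEKL"), "non-standard")
})

test_that("alignment equals the exhaustive all-window oracle", {
  set.seed(23)
  for (i in 1:30) {
    a <- random_aa(sample(8:12, 1))
    b <- random_aa(sample(8:12, 1))
    expect_equal(alignment_score(a, b), align_oracle(a, b))
    # self-alignment dominates alignment to anything else of equal length
    expect_gte(alignment_score(a, a), alignment_score(a, b))
  }
})

test_that("foreignness closed forms hold", {
  expect_equal(foreignness("SIINFEKL", character(0)), 0)
  # one epitope whose score equals the displacement a: S = exp(0) = 1, R = 1/2
  expect_equal(foreignness("SIINFEKL", "SIINFEKL", midpoint_a = 38), 0.5)
  expect_error(foreignness("SIINFEKL", "SIINFEKL", steepness_k = 0), "> 0")
})

test_that("foreignness is monotone in the reference set and bounded", {
  set.seed(29)
  for (i in 1:60) {
    pep <- random_aa(sample(8:12, 1))
    eps <- vapply(seq_len(sample(1:4, 1)), function(j) random_aa(9), character(1))
    r_small <- foreignness(pep, eps)
    r_big <- foreignness(pep, c(eps, random_aa(10)))
    expect_gte(r_big, r_small)
    expect_gte(r_small, 0)
    expect_lt(r_big, 1)
  }
})

test_that("the five TESLA thresholds are strict", {
  base <- tibble::tibble(best_ic50_nm = 10, stability_hours = 5, tpm = 100,
                         agretopicity = 0.01, foreignness = 0.5)
  expect_true(tesla_filter(base)$overall_pass)
  # the worked boundary case: all five just on the passing side
  edge <- tibble::tibble(best_ic50_nm = 67.9, stability_hours = 1.8, tpm = 11,
                         agretopicity = 0.09, foreignness = 1e-15)
  expect_true(tesla_filter(edge)$overall_pass)
  # exact threshold values fail (strict inequalities)
  expect_false(tesla_filter(dplyr::mutate(base, best_ic50_nm = 68))$c_affinity)
  expect_false(tesla_filter(dplyr::mutate(base, stability_hours = 1.7))$c_stability)
  expect_false(tesla_filter(dplyr::mutate(base, tpm = 10))$c_abundance)
  expect_false(tesla_filter(dplyr::mutate(base, agretopicity = 0.1))$c_agretopicity)
  expect_false(tesla_filter(dplyr::mutate(base, foreignness = 1e-16))$c_foreignness)
})

test_that("missing stability fails explicitly rather than passing silently", {
  m <- tibble::tibble(best_ic50_nm = 10, stability_hours = NA_real_, tpm = 100,
                      agretopicity = 0.01, foreignness = 0.5)
  f <- tesla_filter(m)
  expect_true(f$stability_missing)
  expect_false(f$c_stability)
  expect_false(f$overall_pass)
})

test_that("tesla_filter equals brute-force strict inequalities on random tuples", {
  set.seed(31)
  th <- tesla_thresholds()
  m <- tibble::tibble(
    best_ic50_nm = runif(300, 1, 150),
    stability_hours = runif(300, 0, 4),
    tpm = runif(300, 0, 30),
    agretopicity = runif(300, 0, 0.3),
    foreignness = 10^runif(300, -20, -10)
  )
  f <- tesla_filter(m)
  manual <- m$best_ic50_nm < th$ic50_nm & m$stability_hours > th$stability_hours &
    m$tpm > th$tpm & m$agretopicity < th$agretopicity &
    m$foreignness > th$foreignness
  expect_equal(f$overall_pass, manual)
})

test_that("tesla_rank sorts by IC50 with foreignness then sequence tie-breaks", {
  m <- tibble::tibble(
    sequence = c("AAA", "CCC", "DDD"),
    best_ic50_nm = c(5, 60, 30),
    foreignness = 0.5
  )
  expect_equal(tesla_rank(m)$best_ic50_nm, c(5, 30, 60))
  expect_equal(tesla_rank(m)$tesla_rank, 1:3)
  tie <- tibble::tibble(sequence = c("AAA", "CCC"), best_ic50_nm = 10,
                        foreignness = c(0.2, 0.9))
  expect_equal(tesla_rank(tie)$sequence, c("CCC", "AAA"))
  expect_equal(tesla_rank(m[1, ])$tesla_rank, 1L)
})

test_that("mock predictor is deterministic, bounded and allele-sensitive", {
  p <- mock_predictor(7)
  a <- p("SIINFEKL", "HLA-A*02:01")
  b <- p("SIINFEKL", "HLA-A*02:01")
  expect_identical(a, b)
  expect_false(p("SIINFEKL", "HLA-B*07:02")$ic50_nm == a$ic50_nm)
  expect_false(mock_predictor(8)("SIINFEKL", "HLA-A*02:01")$ic50_nm == a$ic50_nm)
  set.seed(37)
  peps <- vapply(1:100, function(i) random_aa(sample(8:12, 1)), character(1))
  out <- p(peps, rep("HLA-A*02:01", 100))
  expect_true(all(out$ic50_nm >= 1 & out$ic50_nm <= 50000))
  expect_true(all(out$stability_hours >= 0.1 & out$stability_hours <= 10))
})

test_that("tesla_metrics wires affinity, agretopicity and foreignness together", {
  prot <- random_aa(40)
  wt <- substr(prot, 20, 20)
  ctx <- context_from_hgvs(prot, paste0("p.", wt, "20",
                                        setdiff(c("A", "G"), wt)[1]))
  cands <- enumerate_short_spanning(ctx)
  cands$tpm <- 50
  pred <- mock_predictor(11)
  ref <- cands$sequence[1]   # exact copy: that candidate scores itself
  m <- tesla_metrics(cands, c("HLA-A*02:01", "HLA-B*07:02"), pred, ref)
  expect_equal(nrow(m), nrow(cands))
  i <- 1
  expect_equal(m$agretopicity[i], m$best_ic50_nm[i] / m$wt_ic50_nm[i])
  # wild-type scored on the mutant's best allele
  expect_equal(m$wt_ic50_nm[i],
               pred(m$wt_sequence[i], m$best_allele[i])$ic50_nm)
  # the self-matching candidate has foreignness >= 0.5 (self score >= a)
  expect_gte(m$foreignness[1], 0.5)
  expect_error(tesla_metrics(dplyr::select(cands, -"tpm"), "HLA-A*02:01",
                             pred, ref), "tpm")
})
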