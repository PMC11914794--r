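test_that("HGVS parsing classifies substitution classes", {
  p <- parse_hgvs_protein(c("p.Asn4Lys", "p.A2T", "p.Gln10Ter", "p.L7fs",
                            "p.Ala5=", "p.Q10*", "p.Ala5_Thr7del", "junk"))
  expect_equal(p$class, c("missense", "missense", "nonsense", "frameshift",
                          "synonymous", "nonsense", "other", "unparseable"))
  expect_equal(p$pos[1], 4L)
  expect_equal(p$wt_residue[1], "N")
  expect_equal(p$mut_residue[1], "K")
})

test_that("context_from_hgvs verifies the annotated residue", {
  ctx <- context_from_hgvs("MSTNACDE", "p.Asn4Lys")
  expect_equal(ctx$mut_pos, 4L)
  expect_equal(ctx$wt_residue, "N")
  expect_equal(ctx$mut_residue, "K")
  expect_equal(ctx$mut_protein, "MSTKACDE")
  expect_error(context_from_hgvs("MSTN", "p.A2T"), "mismatch at position 2")
  expect_error(context_from_hgvs("MSTN", "p.Gln10Ter"), "unsupported variant class")
  expect_error(context_from_hgvs("MSTN", "p.Ala9Thr"), "outside protein")
})

test_that("IPV long design places the mutation at offsets 6 and 15", {
  prot <- random_aa(40)
  hgvs <- paste0("p.", substr(prot, 20, 20), "20",
                 setdiff(c("A", "G"), substr(prot, 20, 20))[1])
  ctx <- context_from_hgvs(prot, hgvs)
  d <- design_ipv_long(ctx)
  expect_equal(nrow(d), 2)
  expect_equal(d$mut_offset, c(6L, 15L))
  expect_equal(d$window_start, c(15L, 6L))
  expect_equal(d$length, c(20L, 20L))
  expect_false(any(d$clamped))
  # mutant residue sits at the stated offset; wild type differs only there
  for (i in 1:2) {
    expect_equal(substr(d$sequence[i], d$mut_offset[i], d$mut_offset[i]),
                 ctx$mut_residue)
    diffs <- which(strsplit(d$sequence[i], "")[[1]] !=
                     strsplit(d$wt_sequence[i], "")[[1]])
    expect_equal(diffs, d$mut_offset[i])
  }
})

test_that("IPV long design clamps windows at protein edges", {
  prot <- random_aa(40)
  # mut_pos 3: both windows shift to residues 1-20 and collapse to one
  wt <- substr(prot, 3, 3)
  ctx <- context_from_hgvs(prot, paste0("p.", wt, "3",
                                        setdiff(c("A", "G"), wt)[1]))
  d <- design_ipv_long(ctx)
  expect_equal(nrow(d), 1)
  expect_equal(d$window_start, 1L)
  expect_equal(d$mut_offset, 3L)
  expect_true(d$clamped)
  expect_equal(d$length, 20L)
  # mut_pos 10: offset-6 window fits, offset-15 window clamps to start 1
  wt10 <- substr(prot, 10, 10)
  ctx10 <- context_from_hgvs(prot, paste0("p.", wt10, "10",
                                          setdiff(c("A", "G"), wt10)[1]))
  d10 <- design_ipv_long(ctx10)
  expect_equal(d10$window_start, c(5L, 1L))
  expect_equal(d10$mut_offset, c(6L, 10L))
  expect_equal(d10$clamped, c(FALSE, TRUE))
  expect_equal(d10$length, c(20L, 20L))
})

test_that("short proteins collapse to a single whole-protein candidate", {
  prot <- random_aa(12)
  wt <- substr(prot, 5, 5)
  ctx <- context_from_hgvs(prot, paste0("p.", wt, "5",
                                        setdiff(c("A", "G"), wt)[1]))
  d <- design_ipv_long(ctx)
  expect_equal(nrow(d), 1)
  expect_equal(d$length, 12L)
  expect_true(d$clamped)
  expect_equal(d$sequence, ctx$mut_protein)
})

test_that("mutation-spanning enumeration matches counts and the brute oracle", {
  prot <- random_aa(40)
  wt <- substr(prot, 20, 20)
  ctx <- context_from_hgvs(prot, paste0("p.", wt, "20",
                                        setdiff(c("A", "G"), wt)[1]))
  sp <- enumerate_short_spanning(ctx)
  expect_equal(nrow(sp), 50)    # 8+9+10+11+12 windows
  expect_setequal(sp$sequence, spanning_oracle(ctx$mut_protein, 20))

  # terminal mutation: one window per length
  wt1 <- substr(prot, 1, 1)
  ctx1 <- context_from_hgvs(prot, paste0("p.", wt1, "1",
                                         setdiff(c("A", "G"), wt1)[1]))
  sp1 <- enumerate_short_spanning(ctx1)
  expect_equal(nrow(sp1), 5)
  expect_equal(sp1$mut_offset, rep(1L, 5))

  # protein shorter than the smallest window
  tiny <- random_aa(7)
  wt7 <- substr(tiny, 4, 4)
  ctx7 <- context_from_hgvs(tiny, paste0("p.", wt7, "4",
                                         setdiff(c("A", "G"), wt7)[1]))
  expect_warning(sp7 <- enumerate_short_spanning(ctx7), "shorter")
  expect_equal(nrow(sp7), 0)
})

test_that("every emitted candidate differs from wild type at exactly mut_offset", {
  set.seed(19)
  for (i in 1:25) {
    L <- sample(25:80, 1)
    prot <- random_aa(L)
    pos <- sample(L, 1)
    wt <- substr(prot, pos, pos)
    mut <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], wt), 1)
    ctx <- context_from_hgvs(prot, paste0("p.", wt, pos, mut))
    cands <- dplyr::bind_rows(design_ipv_long(ctx), enumerate_short_spanning(ctx))
    for (j in seq_len(nrow(cands))) {
      diffs <- which(strsplit(cands$sequence[j], "")[[1]] !=
                       strsplit(cands$wt_sequence[j], "")[[1]])
      expect_equal(diffs, cands$mut_offset[j])
      expect_equal(substr(cands$sequence[j], cands$mut_offset[j],
                          cands$mut_offset[j]), mut)
    }
  }
})

test_that("select_ipv_short returns unique top binders in IC50 order", {
  prot <- random_aa(60)
  wt <- substr(prot, 30, 30)
  ctx <- context_from_hgvs(prot, paste0("p.", wt, "30",
                                        setdiff(c("A", "G"), wt)[1]))
  longs <- design_ipv_long(ctx)
  pred <- mock_predictor(5)
  sel <- select_ipv_short(longs, c("HLA-A*02:01", "HLA-B*07:02"), pred, n = 10)
  expect_equal(nrow(sel), 10)
  expect_false(any(duplicated(sel$sequence)))
  expect_true(all(diff(sel$best_ic50_nm) >= 0))
  expect_true(all(sel$length %in% 8:12))
  # brute-force check of the scoring: best IC50 over alleles per peptide
  for (i in sample(nrow(sel), 3)) {
    manual <- min(pred(rep(sel$sequence[i], 2),
                       c("HLA-A*02:01", "HLA-B*07:02"))$ic50_nm)
    expect_equal(sel$best_ic50_nm[i], manual)
  }
  # n larger than the candidate count returns everything
  all_cands <- select_ipv_short(longs, "HLA-A*02:01", pred, n = 1000)
  expect_true(nrow(all_cands) < 1000)
  expect_false(any(duplicated(all_cands$sequence)))
})

test_that("lengthen_tesla picks the containing 20-mer deterministically", {
  prot <- random_aa(60)
  wt <- substr(prot, 30, 30)
  ctx <- context_from_hgvs(prot, paste0("p.", wt, "30",
                                        setdiff(c("A", "G"), wt)[1]))
  longs <- design_ipv_long(ctx)
  shorts <- enumerate_short_spanning(ctx)
  # a 9-mer inside the offset-6 window only (starts at the mutation)
  s1 <- shorts[shorts$length == 9 & shorts$mut_offset == 1, ]
  out <- lengthen_tesla(s1, longs)
  expect_equal(out$klass, "tesla_long")
  expect_true(grepl(s1$sequence, out$sequence, fixed = TRUE))
  # an 8-mer inside both windows resolves deterministically
  s2 <- shorts[shorts$length == 8 & shorts$mut_offset == 4, ]
  out2 <- lengthen_tesla(s2, longs)
  expect_equal(nrow(out2), 1)
  expect_identical(out2, lengthen_tesla(s2, longs))
  # a peptide contained in neither errors
  fake <- s1
  fake$sequence <- paste(rep("W", 12), collapse = "")
  expect_error(lengthen_tesla(fake, longs), "no IPV 20-mer")
})

test_that("design_peptides assembles both classes per variant", {
  proteins <- c(G1 = random_aa(50), G2 = random_aa(50))
  wt1 <- substr(proteins[["G1"]], 25, 25)
  wt2 <- substr(proteins[["G2"]], 10, 10)
  ranked <- dplyr::bind_rows(
    variant_row(gene = "G1", hgvs_protein = paste0("p.", wt1, "25",
                                                   setdiff(c("A","G"), wt1)[1])),
    variant_row(gene = "G2", hgvs_protein = paste0("p.", wt2, "10",
                                                   setdiff(c("A","G"), wt2)[1]))
  )
  pep <- design_peptides(ranked, proteins)
  expect_setequal(unique(pep$klass), c("ipv_long", "tesla_short"))
  expect_setequal(unique(pep$gene), c("G1", "G2"))
  expect_equal(sum(pep$klass == "ipv_long" & pep$gene == "G1"), 2)
  expect_error(design_peptides(variant_row(gene = "G9"), proteins),
               "no protein sequence")
})
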