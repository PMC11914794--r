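#' Run the full synthetic-cohort analysis end-to-end
#'
#' Exercises the whole stack on one simulated cohort: variant simulation,
#' IPV filtering/ranking, peptide design for the four candidate classes,
#' TESLA metric scoring with the mock predictor, plate simulation (pool and
#' per-variant stimulations), screen calling, the cohort summary, and the
#' Fig-6-style percentile-rank comparisons of positive vs negative
#' candidates.
#'
#' Candidate positivity labels are taken from each variant's own IFNg
#' re-stimulation call (deconvolution-style screening of every
#' filter-passing variant's long peptides).
#'
#' @param config A [sim_config()].
#' @param top_n Pool size per patient and class (default 10).
#' @param include_tesla Compute the TESLA metric branch (predictor scoring,
#'   thresholds, ranks and the two TESLA-derived pools). Disable for large
#'   replicate sweeps that only need the IPV branch.
#' @param n_reference_epitopes Size of the synthetic foreignness reference
#'   set.
#' @return A list with elements `cohort`, `ranked`, `peptides`, `tesla`
#'   (NULL unless requested), `pool_design`, `plates`, `calls`, `summary`,
#'   `candidates` (ranked variants with positivity labels), `comparisons`
#'   (one [compare_metric_ranks()] result per metric).
#' @export
run_cohort_analysis <- function(config = sim_config(), top_n = 10,
                                include_tesla = TRUE,
                                n_reference_epitopes = 50) {
  cohort <- simulate_cohort(config)
  ranked <- prioritize_variants(cohort$variants)
  if (nrow(ranked) == 0) abort("no variants passed the IPV filters")
  peptides <- design_peptides(ranked, cohort$proteins)
  longs <- filter(peptides, .data$klass == "ipv_long")
  shorts <- filter(peptides, .data$klass == "tesla_short")

  tpm_lookup <- select(ranked, "patient_id", "gene", "tpm")
  imm_lookup <- cohort$truth

  top_ipv <- top_candidates(ranked, top_n)
  pool_members <- list(
    ipv_long = select(filter(longs, paste(longs$patient_id, longs$gene) %in%
                               paste(top_ipv$patient_id, top_ipv$gene)),
                      "patient_id", "gene")
  )

  tesla <- NULL
  if (include_tesla) {
    ref <- make_reference_epitopes(n_reference_epitopes, seed = config$seed)
    predictor <- mock_predictor(config$seed)
    scored <- shorts %>%
      left_join(tpm_lookup, by = c("patient_id", "gene")) %>%
      tesla_metrics(config$hla_alleles, predictor, ref)
    tesla_ranked <- scored %>%
      filter(.data$overall_pass) %>%
      group_split(.data$patient_id) %>%
      map(tesla_rank) %>%
      list_rbind()
    top_tesla <- tesla_ranked %>%
      group_by(.data$patient_id) %>%
      slice_head(n = top_n) %>%
      ungroup()
    # lengthen each top TESLA short to its containing IPV 20-mer
    tesla_long <- map(seq_len(nrow(top_tesla)), function(i) {
      s <- top_tesla[i, ]
      vl <- filter(longs, .data$patient_id == s$patient_id, .data$gene == s$gene)
      tryCatch(lengthen_tesla(s, vl), error = function(e) NULL)
    }) %>% list_rbind()
    ipv_short <- longs %>%
      filter(paste(.data$patient_id, .data$gene) %in%
               paste(top_ipv$patient_id, top_ipv$gene)) %>%
      group_split(.data$patient_id) %>%
      map(function(pl) {
        out <- select_ipv_short(pl, config$hla_alleles, predictor, n = top_n)
        out
      }) %>%
      list_rbind()
    tesla <- list(metrics = scored, ranked = tesla_ranked, top = top_tesla,
                  long = tesla_long, ipv_short = ipv_short,
                  reference_epitopes = ref)
    pool_members$tesla_short <- select(top_tesla, "patient_id", "gene")
    pool_members$tesla_long <- if (nrow(tesla_long) > 0) {
      select(tesla_long, "patient_id", "gene")
    } else {
      tibble(patient_id = character(0), gene = character(0))
    }
    pool_members$ipv_short <- select(ipv_short, "patient_id", "gene")
  }

  # pool stimuli: positive truth iff the pool holds >= 1 immunogenic member
  pool_design <- imap(pool_members, function(members, pool) {
    members %>%
      left_join(imm_lookup, by = c("patient_id", "gene")) %>%
      group_by(.data$patient_id) %>%
      summarise(immunogenic = any(.data$is_immunogenic), .groups = "drop") %>%
      mutate(stimulus = pool)
  }) %>% list_rbind()
  # individual per-variant stimulations of every filter-passing variant
  variant_design <- ranked %>%
    left_join(imm_lookup, by = c("patient_id", "gene")) %>%
    mutate(stimulus = .data$gene, immunogenic = .data$is_immunogenic) %>%
    select("patient_id", "stimulus", "immunogenic")
  design <- bind_rows(select(pool_design, "patient_id", "stimulus", "immunogenic"),
                      variant_design)

  plates <- simulate_plates(design, config)
  calls <- call_screen(plates)
  summary <- summarize_cohort(calls, names(pool_members))

  variant_calls <- calls %>%
    filter(.data$cytokine == "IFNg",
           .data$stimulus %in% variant_design$stimulus) %>%
    select(gene = "stimulus", "patient_id", "positive")
  candidates <- ranked %>%
    left_join(variant_calls, by = c("patient_id", "gene"))

  comparisons <- NULL
  if (any(candidates$positive) && any(!candidates$positive)) {
    comparisons <- map(
      stats::setNames(c("tpm", "dna_vaf", "rna_vaf", "sum"),
                      c("tpm", "dna_vaf", "rna_vaf", "sum")),
      function(m) compare_metric_ranks(candidates, m)
    )
  }

  list(cohort = cohort, ranked = ranked, peptides = peptides, tesla = tesla,
       pool_design = pool_design, plates = plates, calls = calls,
       summary = summary, candidates = candidates, comparisons = comparisons)
}
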