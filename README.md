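# neoscreen

Somatic mutations in tumors create *neoepitopes* — mutant peptides that
patient T cells can recognize as non-self. Selecting which of the hundreds of
expressed variants in a tumor to synthesize and test against a patient's
PBMC is the central practical problem of personalized cancer-vaccine design,
and different selection philosophies give very different candidate lists.

`neoscreen` implements, end to end and offline, the two selection strategies
most often contrasted in this setting, together with the downstream assay
analysis used to judge them:

* **IPV (Identify–Prioritize–Validate)** — HLA-agnostic. Somatic variants
  are filtered on tumor/normal DNA evidence and RNA expression
  (tumor VAF ≥ 2%, missense, tumor ≥ normal VAF, ≥ 1 RNA read,
  normal VAF ≤ 5% and tumor VAF ≥ 5%, coverage ≥ 10× in both samples),
  ranked lexicographically by RNA VAF ↓, TPM ↓ and tumor genotype rank ↑,
  and each selected variant is encoded as **two overlapping 20-mers** with
  the mutant residue at positions 6 and 15 — covering both CD8 (class I)
  and CD4 (class II) epitopes without requiring the patient's HLA type.
* **TESLA consortium criteria** — minimal-epitope centric. Every
  mutation-spanning 8–12-mer is scored and kept only if
  IC50 < 68 nM, binding stability > 1.7 h, abundance > 10 TPM,
  agretopicity (mutant/wild-type IC50 ratio) < 0.1 and foreignness
  > 10⁻¹⁶, where foreignness is a recognition-probability score
  `R = S/(1+S)`, `S = Σₑ exp(−k·(a − s(p,e)))` over gapless BLOSUM62 local
  alignments `s` to a reference set of known immunogenic epitopes
  (defaults `a = 26`, `k = 4.87`).

Around the two pipelines the package provides ELISpot/Fluorospot screen
analysis (SFC per 10⁶ PBMC normalization, pooled media/DMSO background
subtraction, the strict >100 SFC positivity bar, pool summaries and
deconvolution), the pipeline-comparison statistics (two-sided Fisher's
exact test on 2×2 response tables, Mann-Whitney comparison of per-donor
percentile ranks of TPM / DNA VAF / RNA VAF between immunogenic and
non-immunogenic candidates), and a fully seeded synthetic-cohort simulator
so the whole workflow runs without patient data. Binding predictions are
consumed as tables (NetMHCpan-style exports) or generated by a
deterministic mock predictor; running external predictors is out of scope.

## Worked example

```r
library(neoscreen)
library(dplyr)

cfg    <- sim_config(seed = 42, n_patients = 2, n_variants_per_patient = 12)
cohort <- simulate_cohort(cfg)
ranked <- prioritize_variants(cohort$variants)
ranked %>% select(patient_id, gene, rna_vaf, tpm, ipv_rank, tpm_pctile) %>% head(5)
#> # A tibble: 5 × 6
#>   patient_id gene     rna_vaf   tpm ipv_rank tpm_pctile
#>   <chr>      <chr>      <dbl> <dbl>    <int>      <dbl>
#> 1 P01        GENE0011   0.611  32.1        1       54.2
#> 2 P01        GENE0001   0.551  17.8        2       37.5
#> 3 P01        GENE0004   0.531  47.6        3       70.8
#> 4 P01        GENE0006   0.256  73.6        4       79.2
#> 5 P01        GENE0002   0.226  85.0        5       87.5
```

Each row is one filter-passing somatic variant: `ipv_rank` is its IPV
priority within the patient (RNA VAF first — GENE0011's 0.611 beats
GENE0002's higher TPM), and `tpm_pctile` its per-donor midrank expression
percentile, later used to ask whether immunogenic candidates were ranked
high.

The full simulated study — peptide design, TESLA scoring with the mock
predictor, plates, screen calls and comparison — runs in one call:

```r
res <- run_cohort_analysis(cfg, include_tesla = TRUE, n_reference_epitopes = 20)
res$comparisons$tpm
#> Percentile-rank comparison (tpm): 5 positive vs 19 negative
#>   U = 86.5, two-sided p = 0.006073 (normal approximation) *
```

Here the 5 candidates whose individual peptides elicited a positive IFNγ
call sat at significantly higher TPM percentiles than the 19 that did not
(this cohort was simulated with a 4× expression boost for truth-immunogenic
variants, so the separation is expected). `res$summary` holds the per-pool
positive/negative counts; `fisher_exact_two_sided()` compares any two
pools, and `build_length_contingency()` re-stratifies the summary into
long (20-mer) vs short (8–12-mer) responses.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "neoscreen", package = "neoscreen")`, with subcommands
`simulate`, `prioritize`, `design`, `tesla`, `screen` and `compare`; every
output file gets a JSON provenance manifest.

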