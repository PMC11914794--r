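---
title: "Methods: neoepitope prioritization and screen analysis in neoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoepitope prioritization and screen analysis in neoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `neoscreen`, in the spirit of a methods section: what is
computed, why the defaults are what they are, and what the synthetic
validation does and does not establish.

## The two selection models

### IPV: expression-driven, HLA-agnostic

IPV treats a neoepitope candidate as *a somatic variant that the tumor
demonstrably expresses*. Its unit of analysis is the variant, not the
minimal epitope. Six conjunctive filters establish somatic origin and
expression (`apply_ipv_filters()`):

| criterion | predicate | rationale |
|---|---|---|
| c1 | tumor DNA VAF ≥ 0.02 | minimal tumor evidence |
| c2 | missense substitution | one mutant residue to center peptides on |
| c3 | tumor VAF ≥ normal VAF | tumor association (ratio ≥ 1) |
| c4 | ≥ 1 RNA alt read | the variant is transcribed |
| c5 | normal VAF ≤ 0.05 **and** tumor VAF ≥ 0.05 | somatic, not germline/artifact |
| c6 | ≥ 10× coverage in tumor and normal DNA | counts are interpretable |

Two conventions deserve note. First, c1 is logically subsumed by c5's
tumor-side bound; both are applied and reported separately because the
criteria list is a published contract, and collapsing them silently would
change the reported per-criterion diagnostics. Second, c3 passes when the
normal VAF is 0: the tumor/normal ratio is then undefined, but a variant
absent from normal is maximally tumor-associated, which is the criterion's
intent. All VAF boundaries are inclusive as written (a variant at exactly
5%/5% passes c5). VAFs at zero depth are defined as 0 and flagged
(`zero_depth`) rather than propagating NaN.

Passing variants are ranked by a stable lexicographic sort: RNA VAF
descending, TPM descending, tumor genotype priority ascending
(hom_alt = 1 < het = 2 < hom_ref = 3), residual ties by input order. The
percentile ranks attached by `rank_variants()` use the midrank convention
`(rank − 0.5)/n × 100`, computed per donor; no convention was published
for them, and midrank was chosen because it is symmetric (mean exactly 50
on tie-free data), affine-invariant, and handles ties without arbitrary
direction. The percentile sum is a reporting metric only — it is *not* the
ranking key.

Peptide design (`design_ipv_long()`) emits two 20-mers per variant with
the mutant residue at positions 6 and 15, so their union covers every
residue from 14 before to 14 after the mutation and their intersection the
±5 core. Near a terminus the window is shifted minimally to keep length 20
(`clamped = TRUE`, offset recomputed); the original rule is silent about
termini, and shift-to-fit preserves the pool's uniform peptide length,
which matters experimentally (synthesis and equimolar pooling). Proteins
shorter than 20 residues collapse to a single whole-protein candidate, and
windows made identical by clamping are deduplicated.

### TESLA: minimal-epitope thresholds

The TESLA-style branch enumerates **mutation-spanning** 8–12-mers
(`enumerate_short_spanning()`). Windows that do not contain the mutant
residue are wild-type self peptides and cannot be neoepitopes, so they are
excluded by construction; a brute-force substring oracle in the test suite
pins the combinatorics (50 windows with ≥ 11 flanking residues, 5 for a
terminal mutation).

Each candidate is scored on five axes (`tesla_metrics()`):

* **Affinity / stability** — minimum IC50 across the patient's alleles;
  stability is taken from that same best allele.
* **Abundance** — the source gene's TPM.
* **Agretopicity** — mutant IC50 / wild-type IC50, with the wild-type
  counterpart scored *on the mutant's best allele*: the ratio compares
  presentation of the same ligand pair on one HLA molecule. Using each
  peptide's own best allele would conflate allele choice with the
  mutation's effect.
* **Foreignness** — `R = S/(1+S)` with
  `S = Σₑ exp(−k (a − s(p, e)))`, where `s` is the best gapless local
  alignment score under BLOSUM62 against each reference epitope. Defaults
  `a = 26`, `k = 4.87` follow the published recognition-probability model
  this score derives from; both are arguments and are recorded in run
  manifests, since the upstream description pins only "as described"
  without parameters. `R` is bounded in [0, 1), monotone in every
  alignment score and under reference-set growth, and an empty reference
  set gives exactly 0.

Thresholds (IC50 < 68 nM, stability > 1.7 h, TPM > 10,
agretopicity < 0.1, foreignness > 10⁻¹⁶) are all **strict**, matching the
published wording ("less than", "greater than", "above"); boundary values
fail. A missing stability prediction fails the stability criterion with an
explicit `stability_missing` flag — a candidate cannot pass a criterion it
was never evaluated on. The post-filter ranking key was never published;
`tesla_rank()` uses ascending best IC50 (ties: foreignness descending,
then sequence), isolated in one function so an alternative key is a
one-line change.

The mock predictor replaces external affinity/stability tools in
simulation and testing. It hashes `"seed|peptide|allele"` with 32-bit
FNV-1a and maps the hash to IC50 (log-uniform on [1, 50000) nM — IC50s are
naturally log-scaled) and stability (uniform on [0.1, 10) h). It is
counter-free and platform-independent: the same triple always gives the
same prediction, and no call order can perturb another.

## Screen analysis

Raw spot counts are averaged over replicate wells per condition, converted
to SFC per 10⁶ PBMC (×10 at the standard 100,000 cells/well), and
background-subtracted. The background is the pooled mean of the media and
DMSO negative-control conditions of the same patient/cytokine; the source
protocol subtracts "the negative control (culture media and DMSO)" without
stating how the two are combined, and the pooled mean uses all control
wells while both condition means remain recoverable from the output. A
call is positive only when net SFC strictly exceeds the threshold
(default 100 SFC/10⁶ PBMC): a net of exactly 100 is negative. Negative
nets are reported as computed, not clipped, so assay drift stays visible.
PHA wells are excluded from calling but validated; a PHA net at or below
threshold marks the patient/cytokine as `QC-warn` without dropping data,
since no exclusion rule was published. Deconvolution is threshold
re-application to the individual per-variant calls of a positive pool; an
empty deconvolution (pool positive, no single member positive) is a valid,
observed outcome.

## Comparison statistics

`fisher_exact_two_sided()` uses the probability-mass two-sided convention
(sum of all same-margin table probabilities ≤ the observed table's,
equal-probability ties included) via `stats::fisher.test()`. This is the
convention under which the published pool-comparison p-values reproduce
exactly from their printed counts, which the acceptance tests assert to
printed precision; an independent margin-enumeration oracle in the test
suite confirms the implementation on 500 random tables. `mann_whitney_u()`
reports midrank U and an exact enumeration p-value for combined n ≤ 16
without ties, otherwise the tie- and continuity-corrected normal
approximation; the exact path is verified against full permutation
enumeration. Significance is reported at p ≤ 0.05 with no
multiple-testing correction, matching the comparison design being
reproduced. `compare_metric_ranks()` drops candidates without a screen
call (label NA) from both groups.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates random proteins (uniform over the 20
standard residues) with one implanted missense SNV each, binomial read
counts, and log-normal expression. Defaults, chosen once as a desk-scale
caricature of a sequenced tumor cohort:

* 4 patients × 20 variants. Real cohorts carry hundreds of expressed
  variants per patient (the motivating study reports a median of a few
  hundred); that scale is reachable by config but unnecessary for
  validating the machinery.
* Tumor VAF ~ Beta(5, 15) floored at 0.05 (mean ≈ 0.25, essentially all
  variants clear the somatic filters — the interesting behavior
  downstream of filtering); normal contamination VAF 0.005; DNA depth
  uniform 30–150×, RNA depth 10–100×.
* TPM ~ LogNormal(meanlog 3, sdlog 1); truth-immunogenic variants
  (fraction 0.2) receive a 4× TPM multiplier. The multiplier is the
  calibration the power property is defined at: log 4 ≈ 1.39 is a
  1.4-standard-deviation shift in log-expression, which an a priori
  Mann-Whitney power calculation puts well above 80% power at ~16 positive
  vs ~64 negative candidates.
* Plates: Poisson spot counts, background 3 spots/well (≈ 30 SFC),
  +30 spots/well for immunogenic stimuli (≈ +300 SFC net, comfortably
  above the 100-SFC bar), PHA 100 spots/well, triplicates at 100,000
  cells/well. Poisson is the natural noise model for counts of secreting
  cells; no empirical noise model was published.

All randomness flows from one seed through named substreams (proteins /
evidence / plates / epitopes), so regenerating plates never perturbs the
cohort. The acceptance script runs the full chain once with the TESLA
branch, then 50-seed sweeps (IPV branch only, for speed) for the TPM power
property and the null false-positive rate; these problem sizes complete in
a couple of minutes on one core.

What passing these simulations shows: the filters, ranking, design
combinatorics, threshold logic, normalization and statistics compose
correctly, and the stack detects a known expression signal with the
designed power while controlling false positives under the null. What it
does not show: performance on real tumors. The generator has no mutational
signatures, no isoform ambiguity, no HLA-frequency structure, no
predictor error correlated with peptide chemistry, and its immunogenicity
truth is assigned, not biological. Cohort-level biological outcomes (which
genes deconvolute positive in which patient) are properties of patient
material and are outside what synthetic validation can claim.

## Known limitations

* Only single-residue missense variants are designed for; frameshift and
  stop-loss neo-ORFs, splice products and proteasomal processing are out
  of scope.
* One protein sequence per variant, named by `sequence_id`; isoform choice
  is the caller's responsibility.
* The foreignness reference set is an explicit input; results depend on
  its composition, and the synthetic stand-in (`make_reference_epitopes()`,
  labelled synthetic throughout) only provides known high-scorers via
  spike-ins.
* Candidates with peptides containing non-standard residues are rejected
  at I/O rather than silently dropped downstream.
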