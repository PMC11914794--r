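Package: neoscreen
Title: Neoepitope Prioritization, Peptide Design, and Immune Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tumor neoepitope candidate selection and in vitro screen
    analysis. Implements the Identify-Prioritize-Validate (IPV) strategy
    (somatic-variant filtering on tumor/normal allele frequencies, RNA evidence
    and coverage; ranking by RNA VAF, expression and tumor genotype; overlapping
    long 20-mer peptide design) alongside the TESLA consortium candidate-selection
    criteria (mutation-spanning 8-12-mer enumeration; HLA binding affinity,
    binding stability, tumor abundance, agretopicity and alignment-based
    foreignness thresholds). Includes ELISpot/Fluorospot plate analysis with
    spot-forming-cell normalization, background subtraction and positivity
    calling; exact 2x2 and rank-based pipeline-comparison statistics; and a
    seeded synthetic-cohort simulator so the full workflow runs end-to-end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
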