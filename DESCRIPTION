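Package: pgxpanel
Title: Pharmacogenetic Panel Interpretation and Implementation-Pilot Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Interprets rsID-level genotype calls from an eight-gene
    pharmacogenetic panel (CYP2C19, CYP2D6, CYP2C9, CYP3A5, SLCO1B1,
    CYP4F2, VKORC1 and the CYP2C cluster): star-allele diplotype
    inference, CPIC-based phenotype translation with legacy CYP2D6
    activity-score cutoffs, drug-induced CYP2D6 phenoconversion,
    gene-drug actionability classification against a 27-drug panel list,
    eligibility screening, enrollment-funnel accounting and per-patient
    consult notes. Ships deterministic fixture cohorts and stochastic
    generators (Hardy-Weinberg diplotype sampling, Bernoulli-stage
    enrollment funnels) so every stage of the pipeline is testable
    without protected health data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
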