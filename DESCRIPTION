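Package: panelval
Title: Analytic Validation Toolkit for Tumor/Normal NGS Panel Assays
Version: 0.1.0
Authors@R:
    person("Panelval", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis layer for the analytic validation of a
    targeted tumor/normal next-generation sequencing oncology panel. Provides
    seeded generators for in silico variant spike-in titrations, purity
    admixture mixing, per-gene copy-number coverage profiles and RNA
    chimeric-read evidence tables; tiered threshold-based somatic SNV/indel
    calling with germline subtraction and depth QC; purity-adjusted
    copy-number presence/absence calling; junction-spanning-read fusion
    calling; and the confusion-matrix arithmetic (sensitivity, specificity,
    positive predictive value, VAF concordance) used to summarise assay
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
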