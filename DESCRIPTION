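Package: repaircarrier
Title: Germline DNA Repair Gene Variant Tiering and Carrier Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes rare germline variants in DNA repair genes into
    protein-truncating (Tier 1) and damaging-missense (Tier 2) categories
    using ClinVar assertions, CADD and REVEL scores and protein-domain
    disruption flags, applies exome quality-control filters at the sample
    and variant-call level, and tests gene-level carrier burden between
    case cohorts and allele-count population summaries with a two-sided
    Fisher's exact test. Ships a synthetic cohort generator with
    configurable per-gene carrier rates so the whole pipeline is testable
    without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
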