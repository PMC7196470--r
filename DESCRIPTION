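Package: modburden
Title: Modifier-Gene Burden Analysis for SCN1A-Related Epilepsy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-reference burden analysis of rare and low-frequency variants
    in epilepsy gene panels, designed for exome cohorts of SCN1A-related
    epilepsy patients. Implements MAF/CADD variant category filtering (types
    A-E), reference-ratio expected counts with exact Fisher testing across a
    gene-set by variant-category by patient-group grid, sex- and X-linkage-
    aware allele-fraction comparisons between severity groups, longitudinal
    IQ/DQ severity classification by interpolation to age six, descriptive
    family and extreme-patient variant reports, and a synthetic-cohort
    generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
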