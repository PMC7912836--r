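Package: cilicopd
Title: Multi-Cohort Concordance Analysis of Cilia and Ciliopathy Gene
    Expression in COPD
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing curated cilia- and ciliopathy-associated
    gene expression between COPD and non-COPD subjects across multiple
    public transcriptomic cohorts. Provides curated geneset merging with
    source provenance, per-dataset differential expression on log2 data
    (Welch or Student two-sample t statistics with Benjamini-Hochberg
    step-up FDR), cross-dataset concordance tiers and Venn partitions,
    cross-compartment (whole lung vs small airway epithelium) hit calling,
    single-cell fraction-expressing annotation with low/intermediate/high
    binning, and a synthetic multi-cohort study generator with planted,
    partially concordant effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
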