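Package: gastroshare
Title: Paired Oral-Gastric Microbiome Diversity and Taxa-Sharing Analysis
Version: 0.1.0
Authors@R:
    person("gastroshare", "developers", email = "dev@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis for paired saliva and gastric
    biopsy shotgun-metagenomic taxonomic profiles from case-control cohorts:
    count-table and metadata input/output with validation, prevalence
    filtering, classified-read descriptives with bootstrap-supported t-tests
    and post hoc power, Shannon-Wiener alpha-diversity, Bray-Curtis
    dissimilarity with principal coordinates analysis and a PERMANOVA-style
    permutation test, per-taxon Spearman group association with
    Benjamini-Hochberg false discovery rate control, a per-subject oral to
    gastric taxa-sharing procedure with group summaries and exclusivity
    calls, and a seeded synthetic paired-cohort generator with ground-truth
    bookkeeping for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
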