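Package: protpair
Title: Paired Presence-Absence and Differential Analysis of Label-Free
    Proteomes
Version: 1.0.0
Authors@R:
    person("protpair", "developers", email = "protpair@example.org",
           role = c("aut", "cre"))
Description: Analysis of paired two-condition label-free shotgun proteomics
    experiments in which missing values are pervasive. Binarizes intensity
    tables into presence/absence appearance patterns, detects
    condition-unique proteins with a pooled two-proportion z-test, runs
    three-way paired differential expression (paired t, exact Wilcoxon
    signed rank, appearance-proportion test) with Benjamini-Hochberg FDR
    control, estimates observed/expected overabundance and plug-in FDR at
    p-value thresholds, projects samples by PCA of binary appearance
    patterns, and scores ranked-list gene-set enrichment with the exact
    minimum-hypergeometric (mHG) statistic. Includes a seeded synthetic
    paired-proteome generator with planted condition-unique, shifted, and
    enriched-set ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
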