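Package: silacswitch
Title: Label-Switch SILAC Differential Proteomics and Codon-Bias Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting differential proteome
    composition from label-switched SILAC peptide ratios. Implements
    identification-probability thresholding at a target FDR, the
    label-switch consistency filter on peptide-level log2 ratios,
    aggregation to per-replicate protein ratios, empirical-Bayes moderated
    one-sample t-testing with Benjamini-Hochberg FDR control, codon-usage
    profiling of coding sequences, random-forest codon importance for
    up- versus down-regulated protein classes, top-percentile codon
    subsets, and a rescue comparison between two differential datasets.
    A synthetic-data generator emulates the statistical structure of a
    three-replicate label-switch SILAC experiment so that every stage is
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
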