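Package: lncregnet
Title: lncRNA-mRNA Co-Expression and Regulatory Network Analysis for
    Paired Microarray Designs
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for paired two-condition expression
    microarrays carrying both mRNA and long non-coding RNA (lncRNA)
    probes. Provides detection-flag filtering and quantile
    normalization, paired t-test differential expression with
    Benjamini-Hochberg false discovery rate control, genome-wide
    screening for strongly negatively correlated lncRNA-mRNA pairs with
    cis/trans classification by genomic window, hypergeometric
    over-representation analysis against GMT gene-set collections,
    transcription-factor association and lncRNA-TF-target network
    construction with Cytoscape-compatible SIF/GraphML export, and
    bootstrap resampling power analysis for small paired designs. A
    synthetic-data generator plants recoverable differential effects,
    negatively coupled probe pairs and TF-coregulated modules so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    igraph,
    optparse
Config/testthat/edition: 3
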