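Package: cdvnet
Title: Condition-Specific Co-Expression Modules and Gene Condition
    Specificity for Bulk Transcriptome Compendia
Version: 0.1.0
Authors@R:
    person("Riley", "Hartmann", email = "rhartmann@posteo.net",
           role = c("aut", "cre"))
Description: Tools for condition-specific gene co-expression analysis of
    large bulk RNA-seq compendia. Samples are partitioned into condition
    clusters by k-means with silhouette-guided selection of k, and
    weighted co-expression modules are detected on the global sample set
    and within each cluster. Each gene's agreement with its module is
    summarised by the gene-module consistency coefficient (GMC, a Pearson
    correlation with the module eigengene), and its condition specificity
    by the correlation difference value (CDV), the difference between the
    cluster-module GMC and the gene's correlation with the
    cluster-restricted global-module eigengene. Includes hypergeometric
    enrichment of cluster metadata and functional bins with
    Benjamini-Hochberg control, Fowlkes-Mallows and adjusted mutual
    information partition similarity, CDV threshold sweeps, function-level
    CDV maps, a tree-ensemble regulatory network with CDV-annotated
    Cytoscape export, and a synthetic compendium generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
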