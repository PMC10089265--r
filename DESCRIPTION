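Package: invanet
Title: Co-Occurrence Networks, Keystone Taxa and Functional-Gene Analysis
    for Paired Invasion Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for paired invaded/native rhizosphere
    microbiome surveys combining 16S amplicon OTU tables with
    high-throughput qPCR (quantitative microbial element cycling, QMEC)
    assays of carbon, nitrogen, phosphorus and sulfur cycling genes.
    Provides absolute quantification of functional genes from qPCR cycle
    thresholds against a 16S reference, rarefaction and alpha-diversity
    estimators, Bray-Curtis/PCoA/ANOSIM beta diversity, Kruskal-Wallis
    differential-abundance screens, prevalence-filtered Spearman
    co-occurrence networks with keystone-taxon identification by degree
    centrality, random-forest and LMG driver-importance analysis,
    redundancy analysis, inverse-distance-weighted spatial interpolation,
    and a paired-design synthetic-data generator with planted keystone
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    randomForest,
    xml2,
    yaml,
    jsonlite
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
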