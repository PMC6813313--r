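Package: tadlink
Title: Integrative Differential 3D-Genome Analysis Within Insulated Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-condition, replicated comparisons of chromosome
    organization and chromatin state. Implements ICE balancing of binned Hi-C
    contact matrices, ratio insulation scoring with TAD and boundary calling,
    mean boundary score (MBS) differential analysis, common-TAD identification
    with an intra-TAD interaction-change statistic, A/B compartment
    eigenvectors with saddle-plot compartmentalization strength, switching
    detection, domain-level integration of ChIP-seq peaks and RNA-seq fold
    changes, and a logistic-regression linkage model relating differential
    expression to chromatin changes shared within TADs and loops. A synthetic
    data generator produces contact maps, peak, gene, and loop tables with
    known ground truth so that every stage of the pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    DESeq2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
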