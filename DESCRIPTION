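Package: crosstalkOmics
Title: Cell-Type Secretomes, Membranomes and Crosstalk Networks from Fluid
    Proteomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative omics workflow for inferring cell-type-specific
    secretomes and membranomes from the proteome of a shared biological fluid.
    Protein identifier lists from several species are collapsed onto a
    reference-species gene space through a homology mapping chain; cell-type
    reference transcriptomes are defined from log2 expression matrices with a
    background-expression-cutoff rule, fold-change filtering and an
    empirical-Bayes moderated group test under FDR control; genes are
    classified by secretion-confidence rank and by plasma-membrane/cell-surface
    Gene Ontology annotation; set overlaps are tested with the hypergeometric
    distribution; and a bipartite crosstalk network linking one cell type's
    secreted factors to the other cell type's membrane proteins is assembled
    from consolidated protein-protein interaction catalogues. A seeded
    synthetic-data generator with planted ground truth supports end-to-end
    validation, and proximity-ligation-assay count comparisons are included
    for wet-lab follow-up statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, GeneSetEnrichment, Network,
    SystemsBiology
RoxygenNote: 7.3.3
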