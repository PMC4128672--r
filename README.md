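# crosstalkOmics

Cell-type-specific secretomes, membranomes and bipartite crosstalk
networks from the proteome of a shared biological fluid.

## The problem

Some cell types cannot be cultured well enough to measure what they
secrete. In the seminiferous tubules of the mammalian testis, Sertoli
(nurse) cells and developing germ cells bathe in testicular fluid (TF),
which carries the diffusible proteins they exchange. `crosstalkOmics`
implements an integrative strategy that side-steps culture entirely: it
combines a shotgun proteome of the fluid (from one or more species), cell
type–resolved transcriptomes, a secretion-confidence catalogue, plasma
membrane / cell-surface GO annotation, and public protein–protein
interaction evidence, to reconstruct which cell type secretes what and
which surface receptors on the opposite cell type it may engage.

The package is written for systems biologists working on cell–cell
communication through fluids (testicular, follicular, cerebrospinal,
synovial, ...), and comes with a seeded synthetic-data generator with
planted ground truth so that every stage, and the pipeline end to end, is
testable without any external download.

## The method

For each cell type *c* with fluid proteome *F*, reference secretome *S*
(secretion ranks 0–2) and membranome *M* (genes annotated to GO:0005886
"plasma membrane" or GO:0009986 "cell surface"):

1. **Identifier mapping.** Species protein lists are collapsed onto
   reference-species genes through the partial maps
   protein → gene → homology group → reference gene; species gene sets are
   unioned into the fluid proteome *F*.
2. **Transcriptomes.** From a log2 intensity matrix, the background
   expression cutoff BEC is the overall median. A probeset enters the
   transcriptome *T<sub>c</sub>* iff its maximum target-cell intensity is
   ≥ 2·BEC, its linear fold change 2^(Δ mean log2) is ≥ 2, and its
   empirical-Bayes moderated F test (variance shrinkage
   s̃² = (d₀s₀² + d s²)/(d₀ + d), hyperparameters by method of moments on
   log s²) gives a Benjamini–Hochberg adjusted p ≤ 0.01. Genes selected in
   both cell classes (opposite-pattern probesets) are discarded.
3. **Integration.** Cell secretome = *T<sub>c</sub>* ∩ *F* ∩ *S*;
   cell membranome = *T<sub>c</sub>* ∩ *M*. Overlap enrichment is tested
   with an upper-tail hypergeometric: drawing n = |*T<sub>c</sub>* ∩ *F*|
   genes from N = |*T<sub>c</sub>*| with K = |*T<sub>c</sub>* ∩ *S*|
   successes, observing k = |cell secretome|.
4. **Network.** Consolidated interaction catalogues (pair order
   normalized, provenance merged) are scanned for edges joining one cell
   type's secreted factors to the *other* cell type's membrane proteins,
   yielding a bipartite-by-construction network with four node classes
   and per-edge provenance, exported to GraphML / SIF / TSV.
5. **Validation statistics.** Proximity-ligation-assay (PLA) field counts
   are compared between the full assay and single-antibody controls with
   a classical pooled-variance Student's t-test.

## Worked example

```r
library(crosstalkOmics)

dir <- file.path(tempdir(), "demo")
world <- generateWorld(worldConfig(seed = 1))   # planted ground truth
configPath <- writeWorld(world, dir)            # all pipeline inputs + config.yaml
res <- runPipeline(configPath)

print(res$report, row.names = FALSE)
```

```
                stage count
    tf_proteome_genes   222
     gc_transcriptome   298
     sc_transcriptome   199
  conflicts_discarded     0
  reference_secretome   436
 reference_membranome   333
        gc_tf_overlap   157
        sc_tf_overlap    65
         gc_secretome    57
         sc_secretome    27
        gc_membranome    59
        sc_membranome    31
  network_gc_secreted    15
  network_sc_secreted    11
  network_gc_membrane    12
  network_sc_membrane    14
        network_edges    29
   network_provenance    26
```

Of the 2000 synthetic genes, 222 were identified in the fluid after
homology mapping; 298 genes form the germ-cell transcriptome, of which
157 are in the fluid and 57 survive the triple intersection — the
germ-cell secretome. The enrichment of secreted genes among the
fluid-identified germ-cell genes is strong:

```r
res$enrichment$GC
#> EnrichmentResult: 57/157 in sample vs 62/298 in population
#>   expected 32.66, p = 1.66e-13
```

Against the planted truth, the recovered germ-cell secretome has
precision 1.00 and recall 0.98, and the network

```r
res$network
#> CrosstalkNetwork
#>   15 GC-secreted + 11 SC-secreted factors
#>   14 SC-membrane + 12 GC-membrane proteins
#>   29 edges, 26 distinct provenance ids
```

contains exactly the catalogue edges eligible under the recovered gene
sets. A thin command-line wrapper with `run` and `generate-world`
subcommands is installed at `inst/scripts/crosstalk-omics.R`.

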