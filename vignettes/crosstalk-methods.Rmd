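---
title: "Methods: inferring cell-type secretomes and crosstalk networks from a fluid proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring cell-type secretomes and crosstalk networks from a fluid proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstalkOmics)
```

# Scope and assumptions

`crosstalkOmics` reconstructs which of two interacting cell types secretes
which proteins into a shared fluid, and which membrane proteins on the
opposite cell type those factors may engage. The method assumes:

* the fluid proteome is a (noisy, incomplete) sample of the proteins both
  cell types release;
* cell-type-resolved expression is available as a log2 intensity matrix
  with at least two replicates per cell population (needed for variance
  estimation);
* secretion and membrane localization can be read from precomputed
  catalogues (confidence ranks; direct GO annotation) in the reference
  gene space;
* physical interactions observed in any system are admissible evidence
  for a possible ligand–receptor contact here.

The pipeline is deliberately assembled from set operations around two
statistical cores — the moderated group test and the hypergeometric
overlap test — so every stage count is auditable.

# Identifier mapping

Protein lists from each species are collapsed onto reference genes by
composing three partial lookup tables (protein → species gene → homology
group → reference gene). Each table must be a function (unique keys);
composition is allowed to fail, and failures are returned as `unmapped`
rather than dropped, so the conservation property "every input id lands
in exactly one of provenance or unmapped" can be asserted on every run.
Identifier strings are opaque and case-sensitive — no UniProt/Entrez
syntax validation — so synthetic and real dialects both pass through.

Two design points were genuinely open. First, real studies may chain two
homology resources; the package models a *single* gene-to-group table and
expects the caller to pre-merge resources, because no principled
precedence between them exists and pre-merging keeps the map a function.
Second, provenance (which source proteins support each reference gene) is
retained through all downstream stages so network nodes can be traced to
the peptide-level evidence.

# Transcriptome definition

**BEC.** The background expression cutoff is the median of *all* matrix
entries (probesets × samples). For an even count, the mean of the two
central order statistics is used; this convention must be fixed for the
cutoff to be reproducible. On typical microarray data the BEC sits near
6 log2 units.

**Selection rule.** A probeset enters the target cell type's
transcriptome iff

1. `max` intensity over target samples ≥ `becMultiplier` × BEC
   (default 2 — the multiplication is applied to the log2 value itself,
   which keeps selected signals far from background);
2. linear fold change `2^(mean_t − mean_r)` ≥ `foldChangeMin`
   (default 2; this is the geometric-mean ratio, identical to requiring a
   log2 mean difference ≥ 1);
3. BH-adjusted moderated-test p ≤ `adjPMax` (default 0.01).

A gene enters the transcriptome as soon as *any* of its probesets passes;
genes whose probesets pass in **both** cell classes (opposite expression
patterns) are discarded from both transcriptomes, guaranteeing
disjointness. Probesets without a gene mapping stay in the statistics
table but contribute no genes. Selection is monotone in the thresholds:
raising `foldChangeMin` or lowering `adjPMax` can only remove genes.

**Moderated test.** Per probeset, the pooled two-group residual variance
s² (d = n₁ + n₂ − 2 df) is shrunk toward a prior s₀² with weight d₀:
s̃² = (d₀s₀² + d·s²)/(d₀ + d); the squared standardized mean difference
is referred to F(1, d₀ + d). The hyperparameters are fitted by method of
moments on log s² (mean and variance matched to the scaled-F model; the
trigamma inversion uses a Newton iteration). `priorDf = 0` recovers the
classical pooled-variance t/F test exactly — this is the oracle route the
tests exploit — and `priorDf = Inf` tests every probeset against the
common prior variance. With three replicates per population, moderation
matters: at d = 7 the raw variances are unstable and shrinkage buys
substantial power without anti-conservative behaviour. The test suite
cross-checks the hyperparameter fit against the established
empirical-Bayes implementation in `limma` but the package computes its
own fit at run time.

Degenerate inputs: all-zero variances with `priorDf = 0` raise an error
instructing a positive prior; a zero variance with zero mean difference
yields statistic 0, p = 1.

# Annotation

The reference secretome keeps genes with secretion-confidence rank ≤ 2
(rank 3 — a long signal peptide predicted by a single method — is too
weak). Genes absent from the rank table are treated as non-secreted, not
as errors, since secretion catalogues cover only part of the genome. The
membranome keeps genes *directly* annotated with GO:0005886 or GO:0009986
(OR semantics). The ontology graph is deliberately not traversed: the
workflow filters a flat gene2go-style file, and propagating up the graph
would pull in thousands of genes annotated to descendants with different
meanings. GO evidence codes and NOT qualifiers are ignored (and a note is
logged), matching the flat-file filtering practice.

# Integration and enrichment

Cell secretome = transcriptome ∩ fluid proteome ∩ reference secretome;
cell membranome = transcriptome ∩ reference membranome. The container
class asserts the subset chain
`cellSecretome ⊆ tfOverlap ⊆ transcriptome` as a validity invariant.

Overlap enrichment is a one-sided upper-tail hypergeometric test
P(X ≥ k), parameterized by counts so it is reusable for any set pair: the
population is the cell-type transcriptome (N), successes its secreted
subset (K), the sample its fluid-proteome overlap (n), and k the observed
triple intersection. This is the canonical test for "a significant
proportion of the secreted genes was retrieved in the fluid". The tail is
computed by the log-space-stable distribution function; an independent
sampling-without-replacement estimator (`permutationEnrichment`) and, in
the tests, exhaustive subset enumeration guard the closed form. For the
Sertoli-cell contrast the population success count K is always computed
from the data at hand, never assumed. No multiple-testing correction is
applied across enrichment calls — only two exist in the design.

# Network assembly

Interaction catalogues are consolidated by normalizing each unordered
pair lexicographically and unioning (pair, provenance) rows. A catalogue
edge becomes a crosstalk edge iff one endpoint is in a cell type's
secretome and the other is in the *opposite* cell type's membranome;
both orientations of each pair are examined, self-interactions are
excluded, and isolated nodes are dropped. The network is therefore
bipartite by construction, with node classes
{GC_secreted, SC_secreted, GC_membrane, SC_membrane}.

A gene can legitimately hold both a secreted and a membrane role (e.g. a
shed surface protein). Rather than silently dropping one role, such genes
appear as two nodes; node identifiers are formed as `gene::class`, which
also makes the GraphML export/import round trip lossless (nodes, edges,
classes and provenance are preserved exactly — a tested invariant).
Edges are stored with a semantic direction secreted → membrane recovered
from the node classes, although the underlying interaction evidence is
undirected.

# PLA statistics

Per-field signal counts (signals per 0.25 mm²) are compared between the
full assay and single-antibody controls with a classical pooled-variance
Student's t-test, two-sided, on untransformed counts — the conventional
analysis for such densities. Welch's correction is not used (the
classical default when no variance qualifier is stated); at the observed
densities (hundreds vs tens of signals with ~10 fields per condition) the
two give indistinguishable conclusions, which the simulation in the test
suite confirms: at means 312 vs 29 with ten Poisson fields each, p < 0.01
in over 99% of seeds.

# The synthetic world

`generateWorld()` draws every pipeline input from a single seeded stream.
The generative model, and the defaults that define the study conditions:

* **Genes and expression**: 2000 reference genes; 300 germ-cell- and 200
  Sertoli-preferential genes are expressed at 10 log2 units in the
  non-preferential class and 10 + 2 in the preferential class; all other
  genes sit at the background level 5; Gaussian noise sd 0.5; three cell
  populations (SC, pSpc, rSpt) with 3 samples each; 1–3 probesets per
  gene plus 50 decoy probesets without gene annotation. With these
  levels the overall median (BEC) is ≈5.1, so the 2×BEC intensity gate
  (≈10.2) passes expressed genes and excludes background, mirroring the
  intended use of the rule.
* **Secretion and membrane**: ranks 0–3 with probabilities
  (0.05, 0.07, 0.08, 0.05), the rest unranked; membrane annotation with
  probability 0.15, assigned one or both membrane GO terms plus random
  decoy terms.
* **Detection in the fluid**: per species, an independent Bernoulli draw
  with probability `plogis(1.5 · (meanExpr − 12) + 2 · secreted)`. At the
  defaults an expressed non-secreted gene is detected in at least one of
  the two species with probability ≈0.45 and an expressed secreted gene
  with ≈0.93, so fluid detection is strongly but not deterministically
  associated with secretion — the structure the enrichment test is meant
  to pick up. Setting the bonus to 0 decouples them (the null world).
* **Mapping**: one species gene and homology group per reference gene,
  an extra protein id with probability 0.3 (database redundancy, giving
  the many-to-one collapse), and a missing gene-to-group link with
  probability 0.05 (mapping loss).
* **Interactions**: 30 cross-type edges planted between the true
  secretomes and opposite membranomes, 500 background edges drawn away
  from eligible cross pairs, provenance ids from a pool of 150 studies,
  distributed over three catalogues with ~25% duplication.
* **PLA**: Poisson counts at means 312 (full assay) and 29 (control),
  10 fields per condition.

What the generator does **not** emulate: probe-level normalization
artefacts and probe-sequence effects, peptide-level mass-spectrometry
sampling (detection is gene-level Bernoulli), real orthology structure
(paralogy, one-to-many groups), correlated noise between samples, and GO
annotation bias. A pipeline that recovers planted truth here is validated
for its logic and statistics, not for robustness to those real-data
pathologies.

# Calibration and problem sizes used by the test suite

The test suite verifies, among others, two end-to-end claims at fixed
seeds: on the default world the pipeline recovers the planted germ-cell
secretome with precision ≥0.9 and recall ≥0.8 and reproduces the
catalogue scan exactly; and on 50 null worlds (`effectLog2 = 0`,
`secretionBonus = 0`) the enrichment test rejects at α = 0.05 within
binomial tolerance of 5%, while transcriptome selection returns genes in
at most a few worlds, consistent with BH control at 0.01 under a global
null. In the null worlds the selected transcriptomes are (correctly)
empty, so the enrichment calibration is evaluated on the planted
germ-cell set, whose detected subset is an exchangeable draw when the
secretion bonus is zero — exactly the hypergeometric null. Structural
invariants (transcriptome disjointness, the subset chain, bipartiteness,
round-trip fidelity) are asserted over additional random worlds of 500 to
800 genes; unit fixtures use tens to hundreds of probesets. These sizes
are the package's own choice of test conditions: large enough for the
asymptotic claims to bind, small enough to iterate on quickly.

# Known limitations

* Transcriptome contrasts are two-group (target vs reference); a joint
  multi-population F over all three cell types is not implemented, but
  the exposed target/reference label sets support any pairwise pooling.
* The pipeline consumes one expression study per run; multi-species
  expression integration is done by mapping each study's probesets to
  reference genes beforehand, or by running selection per study and
  unioning with `resolveConflicts()` applied to the union.
* Interaction evidence is taken at face value: no confidence scoring, no
  per-species filtering beyond the mapping step, and the distinct
  provenance count does not attempt to deduplicate a study reported under
  different database record ids.
* Enrichment p-values are exact only under exchangeable sampling of the
  fluid overlap; real detection depends on abundance, which is partially
  confounded with expression level.
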