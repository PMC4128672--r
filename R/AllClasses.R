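#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median p.adjust pf phyper plogis pt rbinom rnorm rpois
#'   runif setNames var
#' @importFrom utils read.delim write.table head
NULL

.checkCharacterSet <- function(x, what) {
  if (anyNA(x)) return(sprintf("%s must not contain NA", what))
  if (anyDuplicated(x)) return(sprintf("%s must not contain duplicates", what))
  TRUE
}

#' MappingChain: a three-step homology mapping chain
#'
#' Holds the protein -> species gene, species gene -> homology group and
#' homology group -> reference-species gene lookup tables used to collapse
#' species-specific protein identifier lists onto a common reference gene
#' space. Each table is a named character vector (names are source ids,
#' values target ids); every table is a partial function, so identifiers
#' without an entry simply fail to map and are reported as unmapped.
#'
#' @slot proteinToGene named character vector, protein id -> species gene id.
#' @slot geneToGroup named character vector, species gene id -> homology
#'   group id.
#' @slot groupToReference named character vector, homology group id ->
#'   reference-species gene id.
#' @slot referenceSpecies single string naming the reference species.
#'
#' @seealso [MappingChain()], [mapProteinsToReference()]
#' @exportClass MappingChain
setClass("MappingChain",
  representation(
    proteinToGene = "character",
    geneToGroup = "character",
    groupToReference = "character",
    referenceSpecies = "character"
  ),
  prototype(referenceSpecies = "reference")
)

setValidity("MappingChain", function(object) {
  msgs <- character()
  for (slotName in c("proteinToGene", "geneToGroup", "groupToReference")) {
    tab <- slot(object, slotName)
    if (length(tab)) {
      if (is.null(names(tab)) || any(!nzchar(names(tab))) || anyNA(names(tab)))
        msgs <- c(msgs, sprintf("%s must be a fully named character vector", slotName))
      else if (anyDuplicated(names(tab)))
        msgs <- c(msgs, sprintf("%s keys must be unique (maps are functions)", slotName))
      if (anyNA(tab))
        msgs <- c(msgs, sprintf("%s values must not be NA", slotName))
    }
  }
  if (length(object@referenceSpecies) != 1L || !nzchar(object@referenceSpecies))
    msgs <- c(msgs, "referenceSpecies must be a single non-empty string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MappingChain
#'
#' @param proteinToGene,geneToGroup,groupToReference named character vectors
#'   (or 2-column data frames with columns source/target) giving each mapping
#'   step.
#' @param referenceSpecies label of the reference species gene space.
#' @return A [MappingChain-class] object.
#' @examples
#' chain <- MappingChain(
#'   proteinToGene = c(p1 = "gA", p2 = "gA"),
#'   geneToGroup = c(gA = "h1"),
#'   groupToReference = c(h1 = "mG"),
#'   referenceSpecies = "mouse"
#' )
#' @export
MappingChain <- function(proteinToGene = character(), geneToGroup = character(),
                         groupToReference = character(),
                         referenceSpecies = "reference") {
  new("MappingChain",
    proteinToGene = .asLookup(proteinToGene),
    geneToGroup = .asLookup(geneToGroup),
    groupToReference = .asLookup(groupToReference),
    referenceSpecies = referenceSpecies
  )
}

.asLookup <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("mapping tables need two columns (source, target)")
    out <- setNames(as.character(x[[2L]]), as.character(x[[1L]]))
    return(out)
  }
  if (is.null(x)) return(character())
  storage.mode(x) <- "character"
  x
}

setMethod("show", "MappingChain", function(object) {
  cat("MappingChain to reference species '", object@referenceSpecies, "'\n",
    sep = "")
  cat("  protein -> gene entries:  ", length(object@proteinToGene), "\n", sep = "")
  cat("  gene -> group entries:    ", length(object@geneToGroup), "\n", sep = "")
  cat("  group -> reference genes: ", length(object@groupToReference), "\n", sep = "")
})

#' ReferenceGeneSet: a non-redundant reference-species gene set
#'
#' The result of collapsing one or more protein identifier lists through a
#' [MappingChain-class]. Keeps, for every reference gene, the set of source
#' protein ids that mapped to it (provenance), and the input ids that failed
#' at any step of the chain (unmapped).
#'
#' @slot genes character vector of reference gene ids (unique, sorted).
#' @slot unmapped character vector of input protein ids that failed to map.
#' @slot provenance named list, gene id -> character vector of source
#'   protein ids.
#' @slot species character vector of contributing species labels.
#' @slot referenceSpecies single string.
#' @exportClass ReferenceGeneSet
setClass("ReferenceGeneSet",
  representation(
    genes = "character",
    unmapped = "character",
    provenance = "list",
    species = "character",
    referenceSpecies = "character"
  ),
  prototype(referenceSpecies = "reference")
)

setValidity("ReferenceGeneSet", function(object) {
  msgs <- character()
  ok <- .checkCharacterSet(object@genes, "genes")
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (!setequal(names(object@provenance), object@genes))
    msgs <- c(msgs, "provenance must have exactly one entry per gene")
  if (any(lengths(object@provenance) == 0L))
    msgs <- c(msgs, "every gene needs at least one provenance protein id")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ReferenceGeneSet", function(object) {
  cat("ReferenceGeneSet (", object@referenceSpecies, " gene space)\n", sep = "")
  cat("  species:  ", paste(object@species, collapse = ", "), "\n", sep = "")
  cat("  genes:    ", length(object@genes), "\n", sep = "")
  cat("  unmapped: ", length(object@unmapped), " input ids\n", sep = "")
})

#' ExpressionStudy: a labelled log2 expression matrix
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' probeset x sample log2 intensity matrix, a `cell_type` column in
#' `colData`, and a `gene` column in `rowData` linking probesets to
#' reference-species gene ids (NA where a probeset has no gene).
#'
#' @exportClass ExpressionStudy
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msgs <- character()
  if (!"cell_type" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must contain a 'cell_type' column")
  else {
    ct <- SummarizedExperiment::colData(object)$cell_type
    if (anyNA(ct) || any(!nzchar(ct)))
      msgs <- c(msgs, "all samples must carry a non-empty cell_type label")
    else if (any(table(ct) < 2L))
      msgs <- c(msgs, "each cell type needs >= 2 samples for variance estimation")
  }
  if (!"gene" %in% colnames(SummarizedExperiment::rowData(object)))
    msgs <- c(msgs, "rowData must contain a 'gene' column (NA allowed)")
  if (length(SummarizedExperiment::assays(object)) < 1L)
    msgs <- c(msgs, "an intensity assay is required")
  else if (anyNA(SummarizedExperiment::assay(object)))
    msgs <- c(msgs, "the intensity matrix must not contain missing values")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param intensities numeric matrix of log2 intensities, rows probesets
#'   (rownames required), columns samples (colnames required).
#' @param sampleCells named character vector or data frame mapping each
#'   sample to its cell-type label.
#' @param probesetToGene named character vector (or 2-column data frame)
#'   mapping probesets to reference gene ids; probesets without an entry get
#'   NA.
#' @return An [ExpressionStudy-class].
#' @export
ExpressionStudy <- function(intensities, sampleCells, probesetToGene = character()) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensity matrix needs probeset rownames and sample colnames")
  sampleCells <- .asLookup(sampleCells)
  missing <- setdiff(colnames(intensities), names(sampleCells))
  if (length(missing))
    stop("samples without a cell-type label: ", paste(missing, collapse = ", "))
  p2g <- .asLookup(probesetToGene)
  geneCol <- unname(p2g[rownames(intensities)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2intensity = intensities),
    colData = S4Vectors::DataFrame(
      cell_type = unname(sampleCells[colnames(intensities)]),
      row.names = colnames(intensities)
    ),
    rowData = S4Vectors::DataFrame(gene = geneCol, row.names = rownames(intensities))
  )
  new("ExpressionStudy", se)
}

#' Selection parameters for transcriptome definition
#'
#' @slot becMultiplier multiplier applied to the background expression cutoff
#'   (BEC, the overall median log2 intensity); a probeset must reach
#'   `becMultiplier * BEC` in at least one target-cell sample.
#' @slot foldChangeMin minimum linear-scale fold change of the target group
#'   over the reference group.
#' @slot adjPMax maximum Benjamini-Hochberg adjusted p-value.
#' @slot priorDf prior degrees of freedom for variance moderation;
#'   `NA` (default) estimates it from the data by method of moments, `0`
#'   recovers the classical pooled test, `Inf` uses the common prior variance
#'   for every probeset.
#' @exportClass SelectionParams
setClass("SelectionParams",
  representation(
    becMultiplier = "numeric",
    foldChangeMin = "numeric",
    adjPMax = "numeric",
    priorDf = "numeric"
  ),
  prototype(becMultiplier = 2, foldChangeMin = 2, adjPMax = 0.01,
    priorDf = NA_real_)
)

setValidity("SelectionParams", function(object) {
  msgs <- character()
  if (!(length(object@becMultiplier) == 1L && object@becMultiplier > 0))
    msgs <- c(msgs, "becMultiplier must be a single positive number")
  if (!(length(object@foldChangeMin) == 1L && object@foldChangeMin > 0))
    msgs <- c(msgs, "foldChangeMin must be a single positive number")
  if (!(length(object@adjPMax) == 1L && object@adjPMax > 0 && object@adjPMax <= 1))
    msgs <- c(msgs, "adjPMax must lie in (0, 1]")
  if (!(length(object@priorDf) == 1L && (is.na(object@priorDf) || object@priorDf >= 0)))
    msgs <- c(msgs, "priorDf must be NA, a non-negative number or Inf")
  if (length(msgs)) msgs else TRUE
})

#' @param becMultiplier,foldChangeMin,adjPMax,priorDf see slot documentation.
#' @rdname SelectionParams-class
#' @export
SelectionParams <- function(becMultiplier = 2, foldChangeMin = 2,
                            adjPMax = 0.01, priorDf = NA_real_) {
  new("SelectionParams", becMultiplier = becMultiplier,
    foldChangeMin = foldChangeMin, adjPMax = adjPMax,
    priorDf = as.numeric(priorDf))
}

#' TranscriptomeResult: one cell type's reference transcriptome
#'
#' @slot cellType label of the cell class the transcriptome belongs to.
#' @slot genes character vector of selected reference gene ids.
#' @slot stats data frame with one row per probeset: probeset, gene,
#'   max_target, fold_change, raw_p, adj_p, selected.
#' @slot bec the background expression cutoff used (log2 intensity units).
#' @exportClass TranscriptomeResult
setClass("TranscriptomeResult",
  representation(
    cellType = "character",
    genes = "character",
    stats = "data.frame",
    bec = "numeric"
  )
)

setValidity("TranscriptomeResult", function(object) {
  msgs <- character()
  needed <- c("probeset", "gene", "max_target", "fold_change", "raw_p",
    "adj_p", "selected")
  if (!all(needed %in% colnames(object@stats)))
    msgs <- c(msgs, paste("stats must contain columns:",
      paste(needed, collapse = ", ")))
  ok <- .checkCharacterSet(object@genes, "genes")
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TranscriptomeResult", function(object) {
  cat("TranscriptomeResult for cell type '", object@cellType, "'\n", sep = "")
  cat("  BEC: ", format(object@bec, digits = 4), " (log2 units)\n", sep = "")
  cat("  probesets tested: ", nrow(object@stats), ", selected: ",
    sum(object@stats$selected), "\n", sep = "")
  cat("  genes: ", length(object@genes), "\n", sep = "")
})

#' SecretionRankTable: secretion-confidence ranks per gene
#'
#' Ranks follow the convention of curated secreted-protein catalogues:
#' 0 = known secreted, 1 = signal peptide predicted by two methods,
#' 2 = predicted by one method, 3 = weak evidence. Genes absent from the
#' table are treated as non-secreted.
#'
#' @slot ranks named integer vector, gene id -> rank in 0..3.
#' @exportClass SecretionRankTable
setClass("SecretionRankTable", representation(ranks = "integer"))

setValidity("SecretionRankTable", function(object) {
  r <- object@ranks
  if (length(r) && (is.null(names(r)) || anyDuplicated(names(r))))
    return("ranks must be named by unique gene ids")
  if (length(r) && (anyNA(r) || any(r < 0L | r > 3L)))
    return("ranks must be integers in [0, 3]")
  TRUE
})

#' @param ranks named integer vector or data frame (gene, rank).
#' @rdname SecretionRankTable-class
#' @export
SecretionRankTable <- function(ranks) {
  if (is.data.frame(ranks))
    ranks <- setNames(as.integer(ranks[[2L]]), as.character(ranks[[1L]]))
  new("SecretionRankTable", ranks = setNames(as.integer(ranks), names(ranks)))
}

#' GoAnnotation: direct GO term assignments per gene
#'
#' Only direct annotations are stored; no propagation up the ontology graph
#' is performed.
#'
#' @slot annotations data frame with columns gene, go_id (duplicates
#'   collapsed).
#' @exportClass GoAnnotation
setClass("GoAnnotation", representation(annotations = "data.frame"))

setValidity("GoAnnotation", function(object) {
  a <- object@annotations
  if (!all(c("gene", "go_id") %in% colnames(a)))
    return("annotations needs columns 'gene' and 'go_id'")
  if (nrow(a) && !all(grepl("^GO:[0-9]+$", a$go_id)))
    return("go_id values must look like 'GO:' followed by digits")
  TRUE
})

#' @param annotations data frame with columns gene and go_id.
#' @rdname GoAnnotation-class
#' @export
GoAnnotation <- function(annotations) {
  a <- data.frame(gene = as.character(annotations$gene),
    go_id = as.character(annotations$go_id), stringsAsFactors = FALSE)
  a <- unique(a)
  rownames(a) <- NULL
  new("GoAnnotation", annotations = a)
}

#' CellGeneSets: the integrated gene sets of one cell type
#'
#' @slot cellType cell class label.
#' @slot transcriptome genes preferentially expressed in this cell type.
#' @slot tfOverlap transcriptome genes whose product was identified in the
#'   fluid proteome.
#' @slot cellSecretome tfOverlap genes also in the reference secretome
#'   (the triple intersection).
#' @slot cellMembranome transcriptome genes annotated to the plasma
#'   membrane / cell surface.
#' @exportClass CellGeneSets
setClass("CellGeneSets",
  representation(
    cellType = "character",
    transcriptome = "character",
    tfOverlap = "character",
    cellSecretome = "character",
    cellMembranome = "character"
  )
)

setValidity("CellGeneSets", function(object) {
  msgs <- character()
  if (!all(object@tfOverlap %in% object@transcriptome))
    msgs <- c(msgs, "tfOverlap must be a subset of the transcriptome")
  if (!all(object@cellSecretome %in% object@tfOverlap))
    msgs <- c(msgs, "cellSecretome must be a subset of tfOverlap")
  if (!all(object@cellMembranome %in% object@transcriptome))
    msgs <- c(msgs, "cellMembranome must be a subset of the transcriptome")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CellGeneSets", function(object) {
  cat("CellGeneSets for '", object@cellType, "'\n", sep = "")
  cat("  transcriptome: ", length(object@transcriptome), "\n", sep = "")
  cat("  fluid overlap: ", length(object@tfOverlap), "\n", sep = "")
  cat("  secretome:     ", length(object@cellSecretome), "\n", sep = "")
  cat("  membranome:    ", length(object@cellMembranome), "\n", sep = "")
})

#' EnrichmentResult: a hypergeometric overlap test
#'
#' @slot k successes in the sample.
#' @slot n sample size.
#' @slot K successes in the population.
#' @slot N population size.
#' @slot expected expected successes under the null, n*K/N.
#' @slot pValue upper-tail probability P(X >= k).
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(k = "integer", n = "integer", K = "integer", N = "integer",
    expected = "numeric", pValue = "numeric")
)

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (object@k > min(object@n, object@K)) msgs <- c(msgs, "k must be <= min(n, K)")
  if (object@n > object@N || object@K > object@N)
    msgs <- c(msgs, "n and K must be <= N")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d/%d in sample vs %d/%d in population\n",
    object@k, object@n, object@K, object@N))
  cat(sprintf("  expected %.2f, p = %.3g\n", object@expected, object@pValue))
})

#' InteractionCatalog: consolidated physical interaction evidence
#'
#' Edges are unordered gene pairs stored with normalized order
#' (geneA <= geneB lexicographically), one row per (pair, provenance id).
#'
#' @slot edges data frame with columns geneA, geneB, provenance.
#' @exportClass InteractionCatalog
setClass("InteractionCatalog", representation(edges = "data.frame"))

setValidity("InteractionCatalog", function(object) {
  e <- object@edges
  if (!all(c("geneA", "geneB", "provenance") %in% colnames(e)))
    return("edges needs columns geneA, geneB, provenance")
  if (nrow(e) && any(e$geneA > e$geneB))
    return("pair order must be normalized (geneA <= geneB)")
  if (nrow(e) && any(e$geneA == e$geneB))
    return("self-loops are not allowed in an InteractionCatalog")
  TRUE
})

#' @param edges data frame with columns geneA, geneB, provenance (pair order
#'   need not be normalized; self-loops are dropped with a warning).
#' @rdname InteractionCatalog-class
#' @export
InteractionCatalog <- function(edges) {
  e <- data.frame(geneA = as.character(edges$geneA),
    geneB = as.character(edges$geneB),
    provenance = as.character(edges$provenance), stringsAsFactors = FALSE)
  selfLoop <- e$geneA == e$geneB
  if (any(selfLoop)) {
    warning(sum(selfLoop), " self-loop(s) dropped from interaction catalogue")
    e <- e[!selfLoop, , drop = FALSE]
  }
  flip <- e$geneA > e$geneB
  tmp <- e$geneA[flip]
  e$geneA[flip] <- e$geneB[flip]
  e$geneB[flip] <- tmp
  e <- unique(e)
  e <- e[order(e$geneA, e$geneB, e$provenance), , drop = FALSE]
  rownames(e) <- NULL
  new("InteractionCatalog", edges = e)
}

setMethod("show", "InteractionCatalog", function(object) {
  nPairs <- nrow(unique(object@edges[, c("geneA", "geneB")]))
  cat("InteractionCatalog: ", nrow(object@edges), " evidence rows, ",
    nPairs, " distinct pairs, ",
    length(unique(object@edges$provenance)), " provenance ids\n", sep = "")
})

#' CrosstalkNetwork: the bipartite secreted-to-membrane network
#'
#' Nodes are (gene, class) pairs; the four classes are GC_secreted,
#' SC_secreted, GC_membrane and SC_membrane. Every edge joins a secreted
#' node of one cell type to a membrane node of the other cell type. A gene
#' may legitimately hold both a secreted and a membrane role; such dual-role
#' genes appear as two nodes, distinguished by class, and node ids are
#' formed as `gene::class`.
#'
#' @slot nodes data frame with columns id, gene, class.
#' @slot edges data frame with columns secreted, membrane, secreted_class,
#'   membrane_class, provenance (provenance ids sorted and collapsed
#'   with '|').
#' @slot classCounts named integer vector of node counts per class.
#' @slot provenanceCount number of distinct provenance ids over all edges.
#' @exportClass CrosstalkNetwork
setClass("CrosstalkNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    classCounts = "integer",
    provenanceCount = "integer"
  )
)

.NETWORK_CLASSES <- c("GC_secreted", "SC_secreted", "GC_membrane", "SC_membrane")

setValidity("CrosstalkNetwork", function(object) {
  msgs <- character()
  if (!all(c("id", "gene", "class") %in% colnames(object@nodes)))
    msgs <- c(msgs, "nodes needs columns id, gene, class")
  if (nrow(object@nodes) && !all(object@nodes$class %in% .NETWORK_CLASSES))
    msgs <- c(msgs, "node classes must be one of the four crosstalk classes")
  e <- object@edges
  if (!all(c("secreted", "membrane", "secreted_class", "membrane_class",
    "provenance") %in% colnames(e)))
    msgs <- c(msgs, "edges needs columns secreted, membrane, *_class, provenance")
  if (nrow(e)) {
    okPair <- (e$secreted_class == "GC_secreted" & e$membrane_class == "SC_membrane") |
      (e$secreted_class == "SC_secreted" & e$membrane_class == "GC_membrane")
    if (!all(okPair))
      msgs <- c(msgs, "edges must join a secreted class to the other cell type's membrane class")
    if (any(e$secreted == e$membrane))
      msgs <- c(msgs, "self-interactions are excluded from crosstalk edges")
  }
  if (!identical(sort(names(object@classCounts)), sort(.NETWORK_CLASSES)))
    msgs <- c(msgs, "classCounts must cover exactly the four classes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CrosstalkNetwork", function(object) {
  cc <- object@classCounts
  cat("CrosstalkNetwork\n")
  cat(sprintf("  %d GC-secreted + %d SC-secreted factors\n",
    cc[["GC_secreted"]], cc[["SC_secreted"]]))
  cat(sprintf("  %d SC-membrane + %d GC-membrane proteins\n",
    cc[["SC_membrane"]], cc[["GC_membrane"]]))
  cat(sprintf("  %d edges, %d distinct provenance ids\n",
    nrow(object@edges), object@provenanceCount))
})

#' PlaCounts: proximity-ligation-assay signal counts per field
#'
#' @slot condition assay condition label (e.g. full assay vs single-antibody
#'   control).
#' @slot counts non-negative integer signal counts, one per microscope field
#'   of fixed area (signals per 0.25 mm^2).
#' @exportClass PlaCounts
setClass("PlaCounts",
  representation(condition = "character", counts = "integer"))

setValidity("PlaCounts", function(object) {
  if (length(object@condition) != 1L || !nzchar(object@condition))
    return("condition must be a single non-empty label")
  if (anyNA(object@counts) || any(object@counts < 0L))
    return("counts must be non-negative integers")
  TRUE
})

#' @param condition condition label.
#' @param counts numeric vector of per-field counts (coerced to integer).
#' @rdname PlaCounts-class
#' @export
PlaCounts <- function(condition, counts) {
  ci <- as.integer(round(counts))
  new("PlaCounts", condition = condition, counts = ci)
}

setMethod("show", "PlaCounts", function(object) {
  cat("PlaCounts '", object@condition, "': ", length(object@counts),
    " fields, mean ", format(mean(object@counts), digits = 4),
    " signals/0.25 mm^2\n", sep = "")
})
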