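#' Background expression cutoff (BEC)
#'
#' The BEC is the median of all log2 intensities in the matrix, pooled over
#' probesets and samples. For an even number of entries the mean of the two
#' central values is used (the standard median convention); this must be
#' fixed for the cutoff to be reproducible.
#'
#' @param study an [ExpressionStudy-class].
#' @return The overall median log2 intensity (a single number).
#' @export
computeBEC <- function(study) {
  stopifnot(is(study, "ExpressionStudy"))
  x <- SummarizedExperiment::assay(study)
  if (length(x) == 0L) stop("empty expression matrix")
  median(as.numeric(x))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values in the original input order; the step-up minimum over
#' the tail caps values at 1 and never decreases any p-value. Delegates to
#' the stock step-up implementation after validating the input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of FDR-adjusted p-values, same order as input.
#' @export
benjaminiHochberg <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Define one cell type's reference transcriptome
#'
#' A probeset enters the transcriptome of the target cell group when it
#' passes all three of:
#' \enumerate{
#'   \item intensity: its maximum log2 intensity over target-cell samples is
#'     at least `becMultiplier` times the BEC (overall median), keeping
#'     signals well clear of background;
#'   \item fold change: the linear-scale ratio of target to reference group
#'     means, `2^(mean_t - mean_r)`, is at least `foldChangeMin` (so the
#'     gene is preferentially expressed in the target cells);
#'   \item significance: its Benjamini-Hochberg adjusted p-value from
#'     [moderatedGroupTest()] is at most `adjPMax`.
#' }
#' The transcriptome gene set is the image of the selected probesets under
#' the probeset-to-gene map; a gene is included as soon as any one of its
#' probesets passes. Probesets without a gene mapping are retained in the
#' per-probeset statistics but contribute no genes.
#'
#' @param study an [ExpressionStudy-class].
#' @param targetCells,referenceCells cell-type label sets defining the
#'   contrast (e.g. `c("pSpc", "rSpt")` vs `"SC"`).
#' @param params a [SelectionParams-class].
#' @param cellType label stored on the result (defaults to the target labels
#'   joined with "+").
#' @return A [TranscriptomeResult-class].
#' @export
selectTranscriptome <- function(study, targetCells, referenceCells,
                                params = SelectionParams(),
                                cellType = paste(targetCells, collapse = "+")) {
  stopifnot(is(study, "ExpressionStudy"), is(params, "SelectionParams"))
  bec <- computeBEC(study)
  test <- moderatedGroupTest(study, targetCells, referenceCells,
    priorDf = params@priorDf)
  x <- SummarizedExperiment::assay(study)
  ct <- SummarizedExperiment::colData(study)$cell_type
  tIdx <- which(ct %in% targetCells)
  rIdx <- which(ct %in% referenceCells)
  maxTarget <- apply(x[, tIdx, drop = FALSE], 1L, max)
  foldChange <- 2^(rowMeans(x[, tIdx, drop = FALSE]) -
    rowMeans(x[, rIdx, drop = FALSE]))
  adjP <- benjaminiHochberg(test$raw_p)
  selected <- maxTarget >= params@becMultiplier * bec &
    foldChange >= params@foldChangeMin &
    adjP <= params@adjPMax
  geneCol <- as.character(SummarizedExperiment::rowData(study)$gene)
  stats <- data.frame(
    probeset = rownames(x),
    gene = geneCol,
    max_target = unname(maxTarget),
    fold_change = unname(foldChange),
    raw_p = test$raw_p,
    adj_p = adjP,
    selected = unname(selected),
    stringsAsFactors = FALSE
  )
  genes <- sort(unique(geneCol[selected & !is.na(geneCol)]))
  new("TranscriptomeResult", cellType = cellType, genes = genes,
    stats = stats, bec = bec)
}

#' Discard genes with opposite expression patterns
#'
#' A gene can be represented by several probesets, and occasionally those
#' probesets place it in the transcriptome of both cell classes. Such
#' ambiguous genes are removed from both transcriptomes and returned
#' separately, leaving the two gene sets disjoint.
#'
#' @param a,b [TranscriptomeResult-class] objects for two different cell
#'   classes from the same study.
#' @return list with elements `a`, `b` (conflict-free copies) and
#'   `discarded` (the genes removed from both).
#' @export
resolveConflicts <- function(a, b) {
  stopifnot(is(a, "TranscriptomeResult"), is(b, "TranscriptomeResult"))
  if (identical(a@cellType, b@cellType))
    stop("conflict resolution needs transcriptomes of two different cell classes")
  discarded <- sort(intersect(a@genes, b@genes))
  a@genes <- setdiff(a@genes, discarded)
  b@genes <- setdiff(b@genes, discarded)
  validObject(a)
  validObject(b)
  list(a = a, b = b, discarded = discarded)
}
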