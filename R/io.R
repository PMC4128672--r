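#' Read a protein identifier list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; identifiers are treated as opaque, case-sensitive strings.
#'
#' @param path path to a UTF-8 text file.
#' @return character vector of identifiers.
#' @export
readProteomeList <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a two-column mapping table
#'
#' Tab-separated with a required header line; the first column holds source
#' ids, the second target ids.
#'
#' @param path path to a TSV file.
#' @return named character vector (names = source, values = target).
#' @export
readMappingTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("mapping table needs two columns: ", path)
  if (anyDuplicated(tab[[1L]]))
    stop("mapping table keys must be unique (maps are functions): ", path)
  setNames(tab[[2L]], tab[[1L]])
}

#' Read an expression study from its three companion tables
#'
#' @param matrixPath TSV with probeset ids in the first column and one
#'   column of log2 intensities per sample.
#' @param samplesPath TSV with columns (sample, cell_type).
#' @param probesetToGenePath TSV with columns (probeset, gene); probesets
#'   missing here carry no gene.
#' @return An [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(matrixPath, samplesPath, probesetToGenePath) {
  mat <- read.delim(matrixPath, header = TRUE, sep = "\t",
    check.names = FALSE)
  m <- as.matrix(mat[, -1L, drop = FALSE])
  rownames(m) <- as.character(mat[[1L]])
  samples <- read.delim(samplesPath, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  ExpressionStudy(m,
    sampleCells = setNames(samples[[2L]], samples[[1L]]),
    probesetToGene = readMappingTable(probesetToGenePath))
}

#' Read a secretion-rank table
#'
#' TSV with header and columns (gene, rank).
#'
#' @param path path to the TSV file.
#' @return A [SecretionRankTable-class].
#' @export
readSecretionRanks <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  SecretionRankTable(setNames(as.integer(tab[[2L]]),
    as.character(tab[[1L]])))
}

#' Read GO annotations in gene2go column layout
#'
#' Expects the NCBI gene2go column order (tax_id, GeneID, GO_ID, Evidence,
#' Qualifier, GO_term, PubMed, Category), with or without a leading `#` on
#' the header line. Only the gene and GO_ID columns are consumed; evidence
#' codes and qualifiers are deliberately ignored.
#'
#' @param path path to the TSV file.
#' @return A [GoAnnotation-class].
#' @export
readGeneGo <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", comment.char = "", check.names = FALSE)
  if (ncol(tab) < 3L) stop("gene2go-style table needs at least 3 columns")
  message("GO evidence codes and qualifiers are ignored; ",
    "only direct gene-to-term rows are used")
  GoAnnotation(data.frame(gene = tab[[2L]], go_id = tab[[3L]],
    stringsAsFactors = FALSE))
}

#' Read an interaction edge table
#'
#' TSV with header and columns (geneA, geneB, provenance).
#'
#' @param path path to the TSV file.
#' @return An [InteractionCatalog-class].
#' @export
readInteractionTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  InteractionCatalog(data.frame(geneA = tab[[1L]], geneB = tab[[2L]],
    provenance = tab[[3L]], stringsAsFactors = FALSE))
}

#' Read PLA field counts
#'
#' TSV with header and columns (condition, field_id, count).
#'
#' @param path path to the TSV file.
#' @return named list of [PlaCounts-class], one per condition.
#' @export
readPlaCounts <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  conditions <- split(as.integer(tab[[3L]]), as.character(tab[[1L]]))
  lapply(setNames(names(conditions), names(conditions)), function(cond) {
    PlaCounts(cond, conditions[[cond]])
  })
}

#' Write / read a gene set as one id per line
#'
#' @param genes character vector of gene ids.
#' @param path output path.
#' @return `path` invisibly (write) or a character vector (read).
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(sort(unique(as.character(genes))), path)
  invisible(path)
}

#' @rdname writeGeneSet
#' @export
readGeneSet <- function(path) readProteomeList(path)

#' Write per-probeset selection statistics
#'
#' @param result a [TranscriptomeResult-class].
#' @param path output TSV path.
#' @export
writeSelectionStats <- function(result, path) {
  stopifnot(is(result, "TranscriptomeResult"))
  write.table(selectionStats(result), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Write enrichment results as TSV
#'
#' @param results named list of [EnrichmentResult-class] objects.
#' @param path output TSV path.
#' @export
writeEnrichmentTable <- function(results, path) {
  rows <- do.call(rbind, lapply(results, enrichmentAsData))
  rows <- cbind(data.frame(contrast = names(results)), rows)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
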