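#' Cell-type-specific secretome: the triple intersection
#'
#' A gene belongs to a cell type's secretome when it is preferentially
#' expressed in that cell type (transcriptome), its product was identified
#' in the fluid proteome, and it encodes a known or predicted secreted
#' protein (reference secretome).
#'
#' @param transcriptome,fluidProteome,secretome character vectors of
#'   reference gene ids.
#' @return sorted character vector, the triple intersection.
#' @export
cellSecretome <- function(transcriptome, fluidProteome, secretome) {
  sort(intersect(intersect(transcriptome, fluidProteome), secretome))
}

#' Cell-type-specific membranome: the pairwise intersection
#'
#' @param transcriptome,membranome character vectors of reference gene ids.
#' @return sorted character vector, the intersection.
#' @export
cellMembranome <- function(transcriptome, membranome) {
  sort(intersect(transcriptome, membranome))
}

#' Assemble the integrated gene sets of one cell type
#'
#' Convenience constructor computing the fluid-proteome overlap, the
#' cell-specific secretome (triple intersection) and the cell-specific
#' membranome from a conflict-resolved transcriptome.
#'
#' @param transcriptome a [TranscriptomeResult-class] or character vector of
#'   gene ids.
#' @param fluidProteome character vector of fluid-proteome gene ids.
#' @param secretome reference secretome gene ids (see
#'   [referenceSecretome()]).
#' @param membranome reference membranome gene ids (see
#'   [referenceMembranome()]).
#' @param cellType label; defaults to the transcriptome's label when one is
#'   supplied.
#' @return A [CellGeneSets-class].
#' @export
buildCellGeneSets <- function(transcriptome, fluidProteome, secretome,
                              membranome, cellType = NULL) {
  if (is(transcriptome, "TranscriptomeResult")) {
    if (is.null(cellType)) cellType <- cellTypeOf(transcriptome)
    transcriptome <- geneIds(transcriptome)
  }
  if (is.null(cellType)) stop("cellType label is required")
  transcriptome <- sort(unique(as.character(transcriptome)))
  tfOverlap <- sort(intersect(transcriptome, fluidProteome))
  new("CellGeneSets",
    cellType = cellType,
    transcriptome = transcriptome,
    tfOverlap = tfOverlap,
    cellSecretome = cellSecretome(transcriptome, fluidProteome, secretome),
    cellMembranome = cellMembranome(transcriptome, membranome))
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail hypergeometric test: the probability of observing at least
#' `k` successes when drawing `n` items without replacement from a
#' population of `N` items of which `K` are successes. Computation is
#' delegated to the log-space-stable distribution function of the
#' hypergeometric distribution. In the secretome workflow the population is
#' a cell type's transcriptome, the successes its secreted subset, and the
#' sample the subset identified in the fluid proteome.
#'
#' @param k observed successes in the sample.
#' @param n sample size.
#' @param K successes in the population.
#' @param N population size.
#' @return An [EnrichmentResult-class].
#' @examples
#' # germ-cell example: 66 of 177 fluid-identified genes secreted, against
#' # 747 secreted among 3923 transcriptome genes
#' res <- hypergeometricEnrichment(66, 177, 747, 3923)
#' pValueOf(res)
#' @export
hypergeometricEnrichment <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("k, n, K, N must be non-negative integers")
  if (k > min(n, K)) stop("k must not exceed min(n, K)")
  if (n > N || K > N) stop("n and K must not exceed N")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  new("EnrichmentResult", k = as.integer(k), n = as.integer(n),
    K = as.integer(K), N = as.integer(N),
    expected = n * K / N, pValue = p)
}

#' Monte-Carlo estimate of the hypergeometric upper tail
#'
#' Estimates P(X >= k) by repeatedly drawing `n` labels without replacement
#' from a population of `N` labels of which `K` are marked. Serves as an
#' independent stochastic check on [hypergeometricEnrichment()].
#'
#' @inheritParams hypergeometricEnrichment
#' @param reps number of Monte-Carlo draws.
#' @return list with the estimate (`pValue`), its binomial standard error
#'   (`se`) and `reps`.
#' @export
permutationEnrichment <- function(k, n, K, N, reps = 10000L) {
  stopifnot(reps >= 1, k <= min(n, K), n <= N, K <= N)
  if (k == 0) return(list(pValue = 1, se = 0, reps = as.integer(reps)))
  hits <- 0L
  for (i in seq_len(reps)) {
    drawn <- sample.int(N, n)
    if (sum(drawn <= K) >= k) hits <- hits + 1L
  }
  p <- hits / reps
  list(pValue = p, se = sqrt(p * (1 - p) / reps), reps = as.integer(reps))
}
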