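#' Reference secretome from secretion-confidence ranks
#'
#' Selects all genes whose secretion-confidence rank is at most `maxRank`.
#' With the conventional ranking (0 = known secreted up to 3 = weak,
#' single-method prediction), the default `maxRank = 2` keeps known and
#' confidently predicted secreted proteins and drops rank-3 entries. Genes
#' absent from the table are treated as non-secreted and never selected.
#'
#' @param table a [SecretionRankTable-class].
#' @param maxRank integer in 0..3.
#' @return sorted character vector of gene ids.
#' @export
referenceSecretome <- function(table, maxRank = 2L) {
  stopifnot(is(table, "SecretionRankTable"))
  if (length(maxRank) != 1L || is.na(maxRank) || maxRank < 0 || maxRank > 3)
    stop("maxRank must be a single integer in [0, 3]")
  sort(names(table@ranks)[table@ranks <= maxRank])
}

#' Reference membranome from GO annotation
#'
#' Selects genes directly annotated with at least one of the given GO terms
#' (OR semantics). The defaults are the cell-surface and plasma-membrane
#' terms GO:0009986 and GO:0005886. Only direct annotations count: the
#' ontology graph is not traversed, mirroring a flat gene2go-style filter.
#' GO evidence codes and NOT qualifiers, where present in the source file,
#' are ignored.
#'
#' @param annot a [GoAnnotation-class].
#' @param terms character vector of GO term ids.
#' @return sorted character vector of gene ids.
#' @export
referenceMembranome <- function(annot,
                                terms = c("GO:0009986", "GO:0005886")) {
  stopifnot(is(annot, "GoAnnotation"))
  if (length(terms) == 0L) stop("at least one GO term is required")
  a <- annot@annotations
  sort(unique(a$gene[a$go_id %in% terms]))
}
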