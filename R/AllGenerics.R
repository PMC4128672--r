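#' Accessors for crosstalkOmics classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("unmappedIds", function(object) standardGeneric("unmappedIds"))

#' @rdname accessors
#' @export
setGeneric("provenanceOf", function(object) standardGeneric("provenanceOf"))

#' @rdname accessors
#' @export
setGeneric("cellTypeOf", function(object) standardGeneric("cellTypeOf"))

#' @rdname accessors
#' @export
setGeneric("selectionStats", function(object) standardGeneric("selectionStats"))

#' @rdname accessors
#' @export
setGeneric("becOf", function(object) standardGeneric("becOf"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setGeneric("catalogEdges", function(object) standardGeneric("catalogEdges"))

#' @rdname accessors
#' @export
setGeneric("pValueOf", function(object) standardGeneric("pValueOf"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ReferenceGeneSet", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("geneIds", "TranscriptomeResult", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("unmappedIds", "ReferenceGeneSet", function(object) object@unmapped)

#' @rdname accessors
#' @export
setMethod("provenanceOf", "ReferenceGeneSet", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("cellTypeOf", "TranscriptomeResult", function(object) object@cellType)

#' @rdname accessors
#' @export
setMethod("cellTypeOf", "CellGeneSets", function(object) object@cellType)

#' @rdname accessors
#' @export
setMethod("selectionStats", "TranscriptomeResult", function(object) object@stats)

#' @rdname accessors
#' @export
setMethod("becOf", "TranscriptomeResult", function(object) object@bec)

#' @rdname accessors
#' @export
setMethod("networkNodes", "CrosstalkNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "CrosstalkNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("classCounts", "CrosstalkNetwork", function(object) object@classCounts)

#' @rdname accessors
#' @export
setMethod("catalogEdges", "InteractionCatalog", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("pValueOf", "EnrichmentResult", function(object) object@pValue)

#' Extract the gene sets of a CellGeneSets object as a named list
#'
#' @param object a [CellGeneSets-class].
#' @return list with elements transcriptome, tfOverlap, cellSecretome,
#'   cellMembranome.
#' @export
cellGeneSetList <- function(object) {
  stopifnot(is(object, "CellGeneSets"))
  list(
    transcriptome = object@transcriptome,
    tfOverlap = object@tfOverlap,
    cellSecretome = object@cellSecretome,
    cellMembranome = object@cellMembranome
  )
}

#' Coerce an EnrichmentResult to a one-row data frame
#'
#' @param object an [EnrichmentResult-class].
#' @export
enrichmentAsData <- function(object) {
  stopifnot(is(object, "EnrichmentResult"))
  data.frame(k = object@k, n = object@n, K = object@K, N = object@N,
    expected = object@expected, p_value = object@pValue)
}
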