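#' Collapse a species protein list onto reference-species genes
#'
#' Composes the three partial lookup tables of a [MappingChain-class]
#' (protein id -> species gene id -> homology group id -> reference gene id)
#' over a protein identifier list. Several proteins of one species routinely
#' collapse onto the same reference gene (orthologous and redundant database
#' entries), so the output gene set is usually much smaller than the input
#' protein list. Identifiers failing at any step of the chain are reported
#' in the `unmapped` slot rather than silently dropped.
#'
#' Identifier strings are opaque and case-sensitive; no format validation is
#' applied.
#'
#' @param proteinIds character vector of protein identifiers (duplicates are
#'   collapsed).
#' @param chain a [MappingChain-class].
#' @param species label recorded for provenance (e.g. "rat").
#' @return A [ReferenceGeneSet-class]; every reference gene carries the set
#'   of source protein ids that reached it.
#' @examples
#' chain <- MappingChain(
#'   proteinToGene = c(p1 = "gA", p2 = "gA"),
#'   geneToGroup = c(gA = "h1"),
#'   groupToReference = c(h1 = "mG"),
#'   referenceSpecies = "mouse"
#' )
#' rgs <- mapProteinsToReference(c("p1", "p2", "p3"), chain, species = "rat")
#' geneIds(rgs)      # "mG"
#' unmappedIds(rgs)  # "p3"
#' @export
mapProteinsToReference <- function(proteinIds, chain, species = "unknown") {
  stopifnot(is(chain, "MappingChain"))
  proteinIds <- unique(as.character(proteinIds))
  if (length(proteinIds) == 0L) {
    message("empty proteome for species '", species, "': returning empty gene set")
    return(new("ReferenceGeneSet", genes = character(), unmapped = character(),
      provenance = structure(list(), names = character()),
      species = species, referenceSpecies = chain@referenceSpecies))
  }
  speciesGene <- unname(chain@proteinToGene[proteinIds])
  group <- unname(chain@geneToGroup[speciesGene])
  refGene <- unname(chain@groupToReference[group])
  ok <- !is.na(refGene)
  provenance <- split(proteinIds[ok], refGene[ok])
  genes <- sort(names(provenance))
  provenance <- provenance[genes]
  new("ReferenceGeneSet",
    genes = genes,
    unmapped = proteinIds[!ok],
    provenance = provenance,
    species = species,
    referenceSpecies = chain@referenceSpecies)
}

#' Merge two reference gene sets
#'
#' Unions the gene sets of two [ReferenceGeneSet-class] objects expressed in
#' the same reference-species gene space, merging per-gene provenance and
#' the unmapped id lists. Merging is commutative and associative on the gene
#' set.
#'
#' @param a,b [ReferenceGeneSet-class] objects with identical
#'   `referenceSpecies`.
#' @return A merged [ReferenceGeneSet-class].
#' @export
mergeReferenceSets <- function(a, b) {
  stopifnot(is(a, "ReferenceGeneSet"), is(b, "ReferenceGeneSet"))
  if (!identical(a@referenceSpecies, b@referenceSpecies))
    stop("cannot merge gene sets from different reference species: '",
      a@referenceSpecies, "' vs '", b@referenceSpecies, "'")
  genes <- sort(union(a@genes, b@genes))
  provenance <- lapply(setNames(genes, genes), function(g) {
    sort(unique(c(
      if (g %in% names(a@provenance)) a@provenance[[g]] else character(),
      if (g %in% names(b@provenance)) b@provenance[[g]] else character()
    )))
  })
  new("ReferenceGeneSet",
    genes = genes,
    unmapped = sort(unique(c(a@unmapped, b@unmapped))),
    provenance = provenance,
    species = sort(unique(c(a@species, b@species))),
    referenceSpecies = a@referenceSpecies)
}
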