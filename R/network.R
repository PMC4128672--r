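#' Consolidate interaction catalogues
#'
#' Unions the edge tables of several [InteractionCatalog-class] objects
#' (e.g. separate downloads from different interaction databases) after
#' normalizing pair order, collapsing duplicate (pair, provenance) rows.
#'
#' @param sources list of [InteractionCatalog-class] objects.
#' @return A single consolidated [InteractionCatalog-class].
#' @export
consolidateInteractions <- function(sources) {
  if (is(sources, "InteractionCatalog")) sources <- list(sources)
  stopifnot(length(sources) >= 1L,
    all(vapply(sources, is, logical(1), "InteractionCatalog")))
  edges <- do.call(rbind, lapply(sources, catalogEdges))
  InteractionCatalog(edges)
}

.collapseProvenance <- function(x) paste(sort(unique(x)), collapse = "|")

#' Build the bipartite crosstalk network
#'
#' An interaction (s, m) from the catalogue becomes a crosstalk edge when
#' s is secreted by one cell type and m sits on the membrane of the OTHER
#' cell type: either s in the germ-cell secretome and m in the Sertoli-cell
#' membranome, or s in the Sertoli-cell secretome and m in the germ-cell
#' membranome. Both orientations of each unordered catalogue pair are
#' examined. Self-interactions are excluded. Nodes are (gene, class) pairs;
#' a gene may hold both a secreted and a membrane role and then appears as
#' two nodes. Nodes with no edges are excluded.
#'
#' @param gc [CellGeneSets-class] for the germ cells.
#' @param sc [CellGeneSets-class] for the Sertoli cells.
#' @param catalog an [InteractionCatalog-class] in reference gene space.
#' @return A [CrosstalkNetwork-class].
#' @export
buildCrosstalk <- function(gc, sc, catalog) {
  stopifnot(is(gc, "CellGeneSets"), is(sc, "CellGeneSets"),
    is(catalog, "InteractionCatalog"))
  if (length(intersect(gc@transcriptome, sc@transcriptome)))
    stop("cell transcriptomes overlap; resolve conflicts before building the network")
  e <- catalogEdges(catalog)
  # examine both orientations of each unordered pair
  cand <- rbind(
    data.frame(s = e$geneA, m = e$geneB, provenance = e$provenance,
      stringsAsFactors = FALSE),
    data.frame(s = e$geneB, m = e$geneA, provenance = e$provenance,
      stringsAsFactors = FALSE)
  )
  gcEdge <- cand$s %in% gc@cellSecretome & cand$m %in% sc@cellMembranome
  scEdge <- cand$s %in% sc@cellSecretome & cand$m %in% gc@cellMembranome
  keep <- (gcEdge | scEdge) & cand$s != cand$m
  cand <- cand[keep, , drop = FALSE]
  secretedClass <- ifelse(gcEdge[keep], "GC_secreted", "SC_secreted")
  membraneClass <- ifelse(gcEdge[keep], "SC_membrane", "GC_membrane")
  edges <- data.frame(secreted = cand$s, membrane = cand$m,
    secreted_class = secretedClass, membrane_class = membraneClass,
    provenance = cand$provenance, stringsAsFactors = FALSE)
  # collapse provenance ids per directed (secreted, membrane) pair
  if (nrow(edges)) {
    key <- paste(edges$secreted, edges$membrane, edges$secreted_class)
    prov <- vapply(split(edges$provenance, key), .collapseProvenance,
      character(1))
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$provenance <- unname(prov[paste(edges$secreted, edges$membrane,
      edges$secreted_class)])
    edges <- edges[order(edges$secreted, edges$membrane), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- unique(rbind(
    data.frame(gene = edges$secreted, class = edges$secreted_class,
      stringsAsFactors = FALSE),
    data.frame(gene = edges$membrane, class = edges$membrane_class,
      stringsAsFactors = FALSE)
  ))
  dual <- unique(nodes$gene[duplicated(nodes$gene)])
  if (length(dual))
    message("gene(s) holding both a secreted and a membrane role: ",
      paste(dual, collapse = ", "))
  nodes <- nodes[order(nodes$gene, nodes$class), , drop = FALSE]
  nodes <- data.frame(id = paste(nodes$gene, nodes$class, sep = "::"),
    gene = nodes$gene, class = nodes$class, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  cc <- setNames(integer(length(.NETWORK_CLASSES)), .NETWORK_CLASSES)
  tab <- table(nodes$class)
  cc[names(tab)] <- as.integer(tab)
  provCount <- length(unique(unlist(strsplit(edges$provenance, "|",
    fixed = TRUE))))
  new("CrosstalkNetwork", nodes = nodes, edges = edges, classCounts = cc,
    provenanceCount = as.integer(provCount))
}

#' Summarize a crosstalk network
#'
#' @param net a [CrosstalkNetwork-class].
#' @return list with per-class node counts, edge count, distinct provenance
#'   count, and the degree distribution (a table over node degrees).
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "CrosstalkNetwork"))
  e <- networkEdges(net)
  degrees <- if (nrow(e)) {
    table(c(paste(e$secreted, e$secreted_class, sep = "::"),
      paste(e$membrane, e$membrane_class, sep = "::")))
  } else {
    table(character())
  }
  list(
    class_counts = classCounts(net),
    n_nodes = nrow(networkNodes(net)),
    n_edges = nrow(e),
    n_provenance = net@provenanceCount,
    degree_distribution = table(as.integer(degrees))
  )
}

.asIgraph <- function(net) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  igraph::graph_from_data_frame(
    d = data.frame(
      from = paste(e$secreted, e$secreted_class, sep = "::"),
      to = paste(e$membrane, e$membrane_class, sep = "::"),
      provenance = e$provenance, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes$id, gene = nodes$gene,
      class = nodes$class, stringsAsFactors = FALSE))
}

#' Export a crosstalk network to GraphML
#'
#' Node attributes `gene` and `class` and the edge attribute `provenance`
#' (sorted ids joined with '|') are written; edges are directed
#' secreted -> membrane. [readNetworkGraphML()] restores an identical
#' [CrosstalkNetwork-class].
#'
#' @param net a [CrosstalkNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphML <- function(net, path) {
  igraph::write_graph(.asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a crosstalk network back from GraphML
#'
#' @param path a GraphML file written by [writeNetworkGraphML()].
#' @return A [CrosstalkNetwork-class].
#' @export
readNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    id = igraph::vertex_attr(g, "name"),
    gene = igraph::vertex_attr(g, "gene"),
    class = igraph::vertex_attr(g, "class"),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  lookup <- setNames(seq_len(nrow(nodes)), nodes$id)
  edges <- data.frame(
    secreted = nodes$gene[lookup[el[, 1L]]],
    membrane = nodes$gene[lookup[el[, 2L]]],
    secreted_class = nodes$class[lookup[el[, 1L]]],
    membrane_class = nodes$class[lookup[el[, 2L]]],
    provenance = if (nrow(el)) igraph::edge_attr(g, "provenance") else character(),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$secreted, edges$membrane), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$gene, nodes$class), , drop = FALSE]
  rownames(nodes) <- NULL
  cc <- setNames(integer(length(.NETWORK_CLASSES)), .NETWORK_CLASSES)
  tab <- table(nodes$class)
  cc[names(tab)] <- as.integer(tab)
  provCount <- length(unique(unlist(strsplit(edges$provenance, "|",
    fixed = TRUE))))
  new("CrosstalkNetwork", nodes = nodes, edges = edges, classCounts = cc,
    provenanceCount = as.integer(provCount))
}

#' Export a crosstalk network as SIF
#'
#' One line per edge: `secreted secretes_to membrane`, tab-separated.
#'
#' @inheritParams writeNetworkGraphML
#' @export
writeNetworkSIF <- function(net, path) {
  e <- networkEdges(net)
  lines <- sprintf("%s\tsecretes_to\t%s", e$secreted, e$membrane)
  writeLines(lines, path)
  invisible(path)
}

#' Export a crosstalk network edge list as TSV
#'
#' @inheritParams writeNetworkGraphML
#' @export
writeNetworkEdgeList <- function(net, path) {
  write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
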