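mkCellSets <- function(cellType, transcriptome, secretome, membranome) {
  new("CellGeneSets", cellType = cellType,
    transcriptome = sort(transcriptome),
    tfOverlap = sort(secretome),
    cellSecretome = sort(secretome),
    cellMembranome = sort(membranome))
}

test_that("consolidation normalizes pair order and merges provenance", {
  a <- InteractionCatalog(data.frame(geneA = "b", geneB = "a",
    provenance = "P1"))
  b <- InteractionCatalog(data.frame(geneA = "a", geneB = "b",
    provenance = "P1"))
  merged <- consolidateInteractions(list(a, b))
  expect_equal(nrow(catalogEdges(merged)), 1)
  expect_identical(catalogEdges(merged)$geneA, "a")

  c2 <- InteractionCatalog(data.frame(geneA = "a", geneB = "b",
    provenance = "P2"))
  merged2 <- consolidateInteractions(list(a, c2))
  e <- catalogEdges(merged2)
  expect_equal(nrow(e), 2)  # one pair, two provenance rows
  expect_setequal(e$provenance, c("P1", "P2"))
})

test_that("consolidating overlapping catalogues matches brute-force dedup", {
  set.seed(101)
  genes <- sprintf("MG%03d", 1:60)
  mkEdges <- function(n) data.frame(
    geneA = sample(genes, n, replace = TRUE),
    geneB = sample(genes, n, replace = TRUE),
    provenance = sprintf("PMID%02d", sample(30, n, replace = TRUE)),
    stringsAsFactors = FALSE)
  base <- mkEdges(80)
  base <- base[base$geneA != base$geneB, ]
  # three catalogues with ~25% planted pairwise duplication (some flipped)
  catRows <- split(base, sample(3, nrow(base), replace = TRUE))
  dups <- base[runif(nrow(base)) < 0.25, ]
  flip <- dups[, c("geneB", "geneA", "provenance")]
  names(flip) <- c("geneA", "geneB", "provenance")
  catRows[[1]] <- rbind(catRows[[1]], flip)
  cats <- lapply(catRows, InteractionCatalog)
  merged <- consolidateInteractions(cats)

  # brute-force: normalize every row by hand, unique the triples
  all <- do.call(rbind, c(list(base), list(flip)))
  norm <- t(apply(all[, 1:2], 1, sort))
  oracle <- unique(data.frame(a = norm[, 1], b = norm[, 2],
    p = all$provenance, stringsAsFactors = FALSE))
  expect_equal(nrow(catalogEdges(merged)), nrow(oracle))
})

test_that("self-loops are dropped with a warning at catalogue construction", {
  expect_warning(cat <- InteractionCatalog(data.frame(
    geneA = c("a", "b"), geneB = c("a", "c"), provenance = "P1")),
    "self-loop")
  expect_equal(nrow(catalogEdges(cat)), 1)
})

test_that("an empty catalogue yields an empty network", {
  gc <- mkCellSets("GC", c("g1", "g2"), "g1", "g2")
  sc <- mkCellSets("SC", c("s1", "s2"), "s1", "s2")
  cat <- InteractionCatalog(data.frame(geneA = character(),
    geneB = character(), provenance = character()))
  net <- buildCrosstalk(gc, sc, cat)
  expect_equal(nrow(networkEdges(net)), 0)
  expect_equal(nrow(networkNodes(net)), 0)
  expect_equal(sum(classCounts(net)), 0)
  s <- networkSummary(net)
  expect_equal(s$n_edges, 0)
  expect_equal(s$n_provenance, 0)
})

test_that("a single planted cross edge produces a two-node network", {
  gc <- mkCellSets("GC", c("gcSec1", "gcMem1"), "gcSec1", "gcMem1")
  sc <- mkCellSets("SC", c("scSec1", "scMem1"), "scSec1", "scMem1")
  cat <- InteractionCatalog(data.frame(geneA = "gcSec1", geneB = "scMem1",
    provenance = "P1"))
  net <- buildCrosstalk(gc, sc, cat)
  e <- networkEdges(net)
  expect_equal(nrow(e), 1)
  expect_identical(e$secreted, "gcSec1")
  expect_identical(e$membrane, "scMem1")
  cc <- classCounts(net)
  expect_equal(unname(cc[c("GC_secreted", "SC_membrane")]), c(1L, 1L))
  expect_equal(unname(cc[c("SC_secreted", "GC_membrane")]), c(0L, 0L))
  s <- networkSummary(net)
  expect_equal(s$n_edges, 1)
  expect_equal(s$n_provenance, 1)
})

test_that("crosstalk edges match a quadratic scan on a synthetic world", {
  w <- generateWorld(worldConfig(nGenes = 600, nPlantedGc = 120,
    nPlantedSc = 90, nBackgroundEdges = 400, nPlantedCrossEdges = 10,
    seed = 103))
  gc <- mkCellSets("GC", w$truth$plantedGc,
    w$truth$trueGcSecretome, w$truth$trueGcMembranome)
  sc <- mkCellSets("SC", w$truth$plantedSc,
    w$truth$trueScSecretome, w$truth$trueScMembranome)
  catalog <- consolidateInteractions(lapply(w$tables$interactions,
    InteractionCatalog))
  net <- suppressMessages(buildCrosstalk(gc, sc, catalog))
  e <- networkEdges(net)
  oracle <- scanCrosstalkEdges(catalog, w$truth$trueGcSecretome,
    w$truth$trueScMembranome, w$truth$trueScSecretome,
    w$truth$trueGcMembranome)
  expect_identical(paste(e$secreted, e$membrane),
    paste(oracle$secreted, oracle$membrane))
  # all planted edges are present (their endpoints are eligible by truth)
  pe <- w$truth$plantedEdges
  expect_true(all(paste(pe$secreted, pe$membrane) %in%
    paste(e$secreted, e$membrane)))
})

test_that("the network is bipartite across cell types by construction", {
  for (seed in c(103, 104)) {
    w <- generateWorld(worldConfig(nGenes = 500, nPlantedGc = 100,
      nPlantedSc = 80, nPlantedCrossEdges = 12, seed = seed))
    gc <- mkCellSets("GC", w$truth$plantedGc,
      w$truth$trueGcSecretome, w$truth$trueGcMembranome)
    sc <- mkCellSets("SC", w$truth$plantedSc,
      w$truth$trueScSecretome, w$truth$trueScMembranome)
    catalog <- consolidateInteractions(lapply(w$tables$interactions,
      InteractionCatalog))
    net <- suppressMessages(buildCrosstalk(gc, sc, catalog))
    e <- networkEdges(net)
    gcSide <- e$secreted_class == "GC_secreted"
    expect_true(all(e$membrane_class[gcSide] == "SC_membrane"))
    expect_true(all(e$membrane_class[!gcSide] == "GC_membrane"))
    expect_true(all(e$secreted != e$membrane))
    # node classes partition the node set: one class per (gene, class) node
    nodes <- networkNodes(net)
    expect_false(any(duplicated(nodes$id)))
    # summary equals a direct recount
    s <- networkSummary(net)
    expect_equal(s$n_edges, nrow(e))
    lev <- sort(names(s$class_counts))
    expect_equal(as.integer(s$class_counts[lev]),
      as.integer(table(factor(nodes$class, levels = lev))))
  }
})

test_that("overlapping transcriptomes are refused by the network builder", {
  gc <- mkCellSets("GC", c("g1", "shared"), "g1", character())
  sc <- mkCellSets("SC", c("s1", "shared"), "s1", character())
  cat <- InteractionCatalog(data.frame(geneA = "g1", geneB = "s1",
    provenance = "P1"))
  expect_error(buildCrosstalk(gc, sc, cat), "resolve conflicts")
})

test_that("GraphML round-trip preserves nodes, edges, classes and provenance", {
  gc <- mkCellSets("GC", c("gA", "gB", "gC"), c("gA", "gB"), "gC")
  sc <- mkCellSets("SC", c("sA", "sB", "sC"), "sA", c("sB", "sC"))
  cat <- InteractionCatalog(data.frame(
    geneA = c("gA", "gA", "gB", "sA", "sA"),
    geneB = c("sB", "sC", "sB", "gC", "gC"),
    provenance = c("P1", "P2", "P3", "P4", "P5")))
  net <- buildCrosstalk(gc, sc, cat)
  path <- tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, path)
  back <- readNetworkGraphML(path)
  expect_equal(networkNodes(back), networkNodes(net))
  expect_equal(networkEdges(back), networkEdges(net))
  expect_equal(classCounts(back), classCounts(net))
  expect_equal(back@provenanceCount, net@provenanceCount)

  # SIF and edge-list exports carry one line per edge
  sif <- tempfile(fileext = ".sif")
  writeNetworkSIF(net, sif)
  expect_length(readLines(sif), nrow(networkEdges(net)))
})
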