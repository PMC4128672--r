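# smaller-than-default worlds keep these tests quick; the default study
# conditions are exercised end to end in the acceptance suite
smallConfig <- function(seed = 1, ...) {
  worldConfig(nGenes = 500L, nPlantedGc = 100L, nPlantedSc = 70L,
    nBackgroundEdges = 200L, nPlantedCrossEdges = 10L, seed = seed, ...)
}

test_that("the same seed reproduces the world byte for byte", {
  d1 <- file.path(tempdir(), "world_rep1")
  d2 <- file.path(tempdir(), "world_rep2")
  writeWorld(generateWorld(smallConfig(seed = 5)), d1)
  writeWorld(generateWorld(smallConfig(seed = 5)), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
      readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the draws
  d3 <- file.path(tempdir(), "world_rep3")
  writeWorld(generateWorld(smallConfig(seed = 6)), d3)
  expect_false(identical(readLines(file.path(d1, "expression_matrix.tsv")),
    readLines(file.path(d3, "expression_matrix.tsv"))))
})

test_that("every generated file round-trips through the module readers", {
  w <- generateWorld(smallConfig(seed = 8))
  dir <- file.path(tempdir(), "world_roundtrip")
  writeWorld(w, dir)

  for (sp in w$config$species) {
    prot <- readProteomeList(file.path(dir, sprintf("proteome_%s.txt", sp)))
    expect_identical(prot, w$tables$proteomes[[sp]])
    p2g <- readMappingTable(file.path(dir,
      sprintf("map_protein_to_gene_%s.tsv", sp)))
    expect_identical(p2g, w$chains[[sp]]@proteinToGene)
    g2h <- readMappingTable(file.path(dir,
      sprintf("map_gene_to_group_%s.tsv", sp)))
    expect_identical(g2h, w$chains[[sp]]@geneToGroup)
  }
  h2r <- readMappingTable(file.path(dir, "map_group_to_reference.tsv"))
  expect_identical(h2r, w$chains[[1]]@groupToReference)

  study <- readExpressionStudy(file.path(dir, "expression_matrix.tsv"),
    file.path(dir, "sample_annotation.tsv"),
    file.path(dir, "probeset_to_gene.tsv"))
  expect_equal(SummarizedExperiment::assay(study), w$tables$expression,
    tolerance = 1e-9)
  expect_identical(
    unname(SummarizedExperiment::colData(study)$cell_type),
    unname(w$tables$sampleCells))

  ranks <- readSecretionRanks(file.path(dir, "secretion_ranks.tsv"))
  expect_setequal(referenceSecretome(ranks, 3),
    w$tables$ranks$gene)

  go <- suppressMessages(readGeneGo(file.path(dir, "gene2go.tsv")))
  expect_setequal(referenceMembranome(go), w$truth$membraneGenes)

  for (src in names(w$tables$interactions)) {
    cat <- readInteractionTable(file.path(dir,
      sprintf("interactions_%s.tsv", src)))
    oracle <- InteractionCatalog(w$tables$interactions[[src]])
    expect_identical(catalogEdges(cat), catalogEdges(oracle))
  }

  pla <- readPlaCounts(file.path(dir, "pla_counts.tsv"))
  expect_identical(pla$full_assay@counts, w$pla$full@counts)
})

test_that("truth sets are consistent with the generated tables", {
  w <- generateWorld(smallConfig(seed = 12))
  ranks <- setNames(w$tables$ranks$rank, w$tables$ranks$gene)
  secreted <- names(ranks)[ranks <= 2]
  expect_setequal(w$truth$secretedGenes, secreted)
  expect_setequal(w$truth$trueGcSecretome,
    intersect(intersect(w$truth$plantedGc, secreted), w$truth$detectedUnion))
  expect_setequal(w$truth$trueGcMembranome,
    intersect(w$truth$plantedGc, w$truth$membraneGenes))
  expect_true(all(w$truth$plantedEdges$secreted %in%
    c(w$truth$trueGcSecretome, w$truth$trueScSecretome)))
  # planted classes are disjoint
  expect_length(intersect(w$truth$plantedGc, w$truth$plantedSc), 0)
})

test_that("detection in the fluid is positively associated with secretion", {
  w <- generateWorld(worldConfig(seed = 13))
  secreted <- w$genes %in% w$truth$secretedGenes
  detected <- w$genes %in% w$truth$detectedUnion
  # point-biserial correlation among expressed genes (detection of
  # background genes is essentially impossible either way)
  expressed <- w$genes %in% c(w$truth$plantedGc, w$truth$plantedSc)
  r <- cor(secreted[expressed], detected[expressed])
  expect_gt(r, 0.2)
})

test_that("PLA generation is seeded and respects degenerate means", {
  cfg <- smallConfig(seed = 3, plaMeanFull = 0, plaMeanControl = 0)
  pla <- generatePlaCounts(cfg)
  expect_true(all(pla$full@counts == 0))
  expect_true(all(pla$control@counts == 0))

  cfg2 <- smallConfig(seed = 4)
  expect_identical(generatePlaCounts(cfg2)$full@counts,
    generatePlaCounts(cfg2)$full@counts)

  # sample mean of the full condition tracks the configured density
  set.seed(991)
  means <- replicate(300, mean(rpois(10, 312)))
  se <- sqrt(312 / 10)
  expect_lt(abs(mean(generatePlaCounts(cfg2)$full@counts) - 312), 4 * se)
  expect_lt(abs(mean(means) - 312), 3 * se / sqrt(300))
})

test_that("inconsistent planted counts are refused", {
  expect_error(worldConfig(nGenes = 100, nPlantedGc = 80, nPlantedSc = 30),
    "exceed")
  expect_error(worldConfig(rankProbs = c(0.5, 0.5, 0.2, 0.1)), "sum")
  expect_error(worldConfig(membraneFrac = 1.5), "probabilities")
})
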