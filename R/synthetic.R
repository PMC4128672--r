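#' Configuration for the synthetic crosstalk world
#'
#' Builds the parameter list consumed by [generateWorld()]. The defaults
#' describe a two-species fluid-proteome study over a reference gene space
#' of 2000 genes, with three seminiferous cell populations (Sertoli cells
#' and two germ-cell populations) profiled in triplicate, a planted
#' cell-type expression effect of +2 log2 units on top of an expressed
#' baseline near twice the background median, secretion ranks covering a
#' quarter of the genome, logistic detection-in-fluid tied to expression
#' with a bonus for secreted proteins, homology-chain redundancy and broken
#' links, and an interaction catalogue mixing planted cross-type edges with
#' random background edges.
#'
#' @param nGenes number of reference genes.
#' @param samplesPerType named integer vector of samples per cell type; the
#'   first label is taken as the somatic (Sertoli) class, the remaining
#'   labels as germ-cell populations.
#' @param baselineLog2Mean,noiseSd background log2 intensity mean and the
#'   Gaussian noise sd applied to every measurement.
#' @param expressedLog2Mean log2 intensity of an expressed gene in the cell
#'   type where it is not preferentially expressed.
#' @param effectLog2 planted log2 effect added in the preferential cell
#'   type (0 gives a null world).
#' @param nPlantedGc,nPlantedSc numbers of germ-cell- and
#'   Sertoli-preferential genes.
#' @param rankProbs probabilities of secretion ranks 0..3 (remaining genes
#'   are unranked, i.e. non-secreted).
#' @param membraneFrac probability that a gene carries a plasma-membrane /
#'   cell-surface GO term.
#' @param detectSlope,detectCenter,detectIntercept logistic model for
#'   detection in the fluid: plogis(intercept + slope * (meanExpr - center)
#'   + secretionBonus * secreted).
#' @param secretionBonus logit-scale detection bonus for secreted genes
#'   (0 decouples detection from secretion).
#' @param redundancyRate probability of an extra protein id per species
#'   gene (database redundancy).
#' @param brokenLinkRate probability that a species gene's homology-group
#'   link is missing, so its proteins cannot be mapped.
#' @param probesetExtraProb each gene carries 1 + Binomial(2, p) probesets.
#' @param nUnmappedProbesets decoy probesets with no gene annotation.
#' @param nBackgroundEdges,nPlantedCrossEdges interaction-catalogue
#'   composition.
#' @param nProvenancePool number of distinct study ids provenance is drawn
#'   from.
#' @param plaFields,plaMeanFull,plaMeanControl PLA simulation: number of
#'   fields and Poisson means (signals per 0.25 mm^2) for the full assay
#'   and the single-antibody control.
#' @param species labels of the two fluid-proteome species.
#' @param seed integer seed governing every stochastic draw.
#' @return named list of class `worldConfig`.
#' @export
worldConfig <- function(nGenes = 2000L,
                        samplesPerType = c(SC = 3L, pSpc = 3L, rSpt = 3L),
                        baselineLog2Mean = 5,
                        noiseSd = 0.5,
                        expressedLog2Mean = 10,
                        effectLog2 = 2,
                        nPlantedGc = 300L,
                        nPlantedSc = 200L,
                        rankProbs = c(0.05, 0.07, 0.08, 0.05),
                        membraneFrac = 0.15,
                        detectSlope = 1.5,
                        detectCenter = 12,
                        detectIntercept = 0,
                        secretionBonus = 2,
                        redundancyRate = 0.3,
                        brokenLinkRate = 0.05,
                        probesetExtraProb = 0.15,
                        nUnmappedProbesets = 50L,
                        nBackgroundEdges = 500L,
                        nPlantedCrossEdges = 30L,
                        nProvenancePool = 150L,
                        plaFields = 10L,
                        plaMeanFull = 312,
                        plaMeanControl = 29,
                        species = c("rat", "ram"),
                        seed = 1L) {
  config <- as.list(environment())
  probs <- c(rankProbs, membraneFrac, redundancyRate, brokenLinkRate,
    probesetExtraProb)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (sum(rankProbs) > 1) stop("rank probabilities must sum to at most 1")
  if (nPlantedGc + nPlantedSc > nGenes)
    stop("planted gene counts exceed nGenes")
  if (any(samplesPerType < 2L))
    stop("each cell type needs >= 2 samples")
  structure(config, class = "worldConfig")
}

.drawRanks <- function(nGenes, rankProbs) {
  cut <- cumsum(c(rankProbs, 1 - sum(rankProbs)))
  u <- runif(nGenes)
  rank <- findInterval(u, c(0, cut), rightmost.closed = TRUE)
  rank[rank > 4L] <- 5L
  ifelse(rank <= 4L, rank - 1L, NA_integer_)  # NA = unranked / non-secreted
}

#' Generate a synthetic crosstalk world with planted ground truth
#'
#' Draws, from a single seeded stream, every input the pipeline consumes —
#' per-species proteome lists, the three-step homology mapping tables, a
#' log2 expression matrix with cell-type sample labels and a
#' probeset-to-gene map, a secretion-rank table, a gene2go-style GO
#' annotation table, three overlapping interaction catalogues and PLA field
#' counts — together with the planted truth every set should recover.
#'
#' The generative model: planted germ-cell (Sertoli-cell) genes are
#' expressed at `expressedLog2Mean + effectLog2` in their preferential cell
#' populations and at `expressedLog2Mean` in the other class; all remaining
#' genes sit at the background level. Detection in the fluid is an
#' independent Bernoulli draw per species from a logistic function of mean
#' expression plus a bonus for secreted genes. Homology redundancy is
#' modelled by extra protein ids per species gene, and mapping loss by
#' deleting gene-to-group links at `brokenLinkRate`. Cross-type interaction
#' edges are planted between the true secretomes and the opposite cell
#' type's true membranome, on top of random background edges drawn away
#' from eligible cross pairs.
#'
#' @param config a [worldConfig()] list.
#' @return list with elements `config`, `genes`, `truth` (planted and
#'   derived truth sets), `tables` (all input tables as data frames /
#'   vectors), `chains` (per-species [MappingChain-class]) and `pla`
#'   (a pair of [PlaCounts-class]).
#' @export
generateWorld <- function(config = worldConfig()) {
  stopifnot(inherits(config, "worldConfig"))
  set.seed(config$seed)
  nGenes <- config$nGenes
  genes <- sprintf("MG%05d", seq_len(nGenes))

  ## planted cell-type classes
  planted <- sample(genes, config$nPlantedGc + config$nPlantedSc)
  plantedGc <- sort(planted[seq_len(config$nPlantedGc)])
  plantedSc <- sort(planted[config$nPlantedGc + seq_len(config$nPlantedSc)])

  ## secretion ranks and membrane annotation
  ranks <- .drawRanks(nGenes, config$rankProbs)
  names(ranks) <- genes
  secreted <- !is.na(ranks) & ranks <= 2L
  membrane <- runif(nGenes) < config$membraneFrac
  names(membrane) <- genes

  ## expression matrix
  cellTypes <- names(config$samplesPerType)
  scType <- cellTypes[1L]
  germTypes <- cellTypes[-1L]
  sampleCells <- rep(cellTypes, times = config$samplesPerType)
  sampleIds <- paste0(sampleCells, "_", unlist(lapply(config$samplesPerType,
    seq_len)))
  geneMean <- matrix(config$baselineLog2Mean, nrow = nGenes,
    ncol = length(cellTypes), dimnames = list(genes, cellTypes))
  geneMean[plantedGc, germTypes] <- config$expressedLog2Mean + config$effectLog2
  geneMean[plantedGc, scType] <- config$expressedLog2Mean
  geneMean[plantedSc, scType] <- config$expressedLog2Mean + config$effectLog2
  geneMean[plantedSc, germTypes] <- config$expressedLog2Mean

  nPs <- 1L + rbinom(nGenes, 2L, config$probesetExtraProb)
  psGene <- rep(genes, times = nPs)
  probesets <- sprintf("PS%06d", seq_along(psGene))
  mu <- geneMean[psGene, sampleCells, drop = FALSE]
  mat <- mu + matrix(rnorm(length(mu), sd = config$noiseSd), nrow = nrow(mu))
  ## decoy probesets with no gene annotation
  if (config$nUnmappedProbesets > 0L) {
    decoy <- matrix(rnorm(config$nUnmappedProbesets * length(sampleCells),
      mean = config$baselineLog2Mean, sd = config$noiseSd),
      nrow = config$nUnmappedProbesets)
    mat <- rbind(mat, decoy)
    decoyIds <- sprintf("PSX%05d", seq_len(config$nUnmappedProbesets))
    probesets <- c(probesets, decoyIds)
    psGene <- c(psGene, rep(NA_character_, config$nUnmappedProbesets))
  }
  rownames(mat) <- probesets
  colnames(mat) <- sampleIds

  ## detection in fluid, per species
  meanExpr <- rowMeans(geneMean[, sampleCells, drop = FALSE])
  detectP <- plogis(config$detectIntercept +
    config$detectSlope * (meanExpr - config$detectCenter) +
    config$secretionBonus * secreted)
  detected <- lapply(setNames(config$species, config$species),
    function(sp) genes[runif(nGenes) < detectP])

  ## homology mapping chain per species
  groupIds <- sprintf("HG%05d", seq_len(nGenes))
  groupToReference <- setNames(genes, groupIds)
  chains <- list()
  proteomes <- list()
  mappingTables <- list()
  for (sp in config$species) {
    spGenes <- sprintf("%sG%05d", toupper(sp), seq_len(nGenes))
    nProt <- 1L + rbinom(nGenes, 1L, config$redundancyRate)
    protGene <- rep(spGenes, times = nProt)
    protIds <- sprintf("%sP%06d", toupper(sp), seq_along(protGene))
    proteinToGene <- setNames(protGene, protIds)
    broken <- runif(nGenes) < config$brokenLinkRate
    geneToGroup <- setNames(groupIds[!broken], spGenes[!broken])
    chain <- MappingChain(proteinToGene, geneToGroup, groupToReference,
      referenceSpecies = "mouse")
    chains[[sp]] <- chain
    detectedGenes <- detected[[sp]]
    spGeneOf <- setNames(spGenes, genes)
    proteomes[[sp]] <- protIds[protGene %in% spGeneOf[detectedGenes]]
    mappingTables[[sp]] <- list(
      proteinToGene = data.frame(source_id = protIds, target_id = protGene,
        stringsAsFactors = FALSE),
      geneToGroup = data.frame(source_id = spGenes[!broken],
        target_id = groupIds[!broken], stringsAsFactors = FALSE)
    )
  }
  groupTable <- data.frame(source_id = groupIds, target_id = genes,
    stringsAsFactors = FALSE)

  ## GO annotation (two membrane terms plus decoys)
  membraneTerms <- c("GO:0009986", "GO:0005886")
  decoyTerms <- sprintf("GO:%07d", seq_len(20L))
  goRows <- list()
  memGenes <- genes[membrane]
  if (length(memGenes)) {
    pick <- 1L + rbinom(length(memGenes), 1L, 0.3)  # one or both terms
    goRows[[1L]] <- data.frame(
      gene = rep(memGenes, times = pick),
      go_id = unlist(lapply(pick, function(m) sample(membraneTerms, m))),
      stringsAsFactors = FALSE)
  }
  nDecoy <- rpois(nGenes, 1)
  goRows[[length(goRows) + 1L]] <- data.frame(
    gene = rep(genes, times = nDecoy),
    go_id = sample(decoyTerms, sum(nDecoy), replace = TRUE),
    stringsAsFactors = FALSE)
  goTable <- do.call(rbind, goRows)

  ## truth sets
  detectedUnion <- sort(unique(unlist(detected)))
  secretedGenes <- genes[secreted]
  truth <- list(
    plantedGc = plantedGc,
    plantedSc = plantedSc,
    secretedGenes = sort(secretedGenes),
    membraneGenes = sort(memGenes),
    detected = lapply(detected, sort),
    detectedUnion = detectedUnion,
    trueGcSecretome = sort(intersect(intersect(plantedGc, secretedGenes),
      detectedUnion)),
    trueScSecretome = sort(intersect(intersect(plantedSc, secretedGenes),
      detectedUnion)),
    trueGcMembranome = sort(intersect(plantedGc, memGenes)),
    trueScMembranome = sort(intersect(plantedSc, memGenes))
  )

  ## interaction catalogue: planted cross edges + background
  provenancePool <- sprintf("PMID%06d", sample.int(999999L,
    config$nProvenancePool))
  drawPairs <- function(sSet, mSet, nPairs) {
    if (!length(sSet) || !length(mSet) || nPairs <= 0L)
      return(data.frame(secreted = character(), membrane = character(),
        stringsAsFactors = FALSE))
    all <- expand.grid(secreted = sSet, membrane = mSet,
      stringsAsFactors = FALSE)
    all <- all[all$secreted != all$membrane, , drop = FALSE]
    all[sample.int(nrow(all), min(nPairs, nrow(all))), , drop = FALSE]
  }
  addDirection <- function(df, dir) {
    df$direction <- rep(dir, nrow(df))
    df
  }
  nHalf <- config$nPlantedCrossEdges %/% 2L
  plantedEdges <- rbind(
    addDirection(drawPairs(truth$trueGcSecretome, truth$trueScMembranome,
      nHalf), "GC_to_SC"),
    addDirection(drawPairs(truth$trueScSecretome, truth$trueGcMembranome,
      config$nPlantedCrossEdges - nHalf), "SC_to_GC")
  )
  rownames(plantedEdges) <- NULL
  truth$plantedEdges <- plantedEdges

  isEligible <- function(a, b) {
    (a %in% truth$trueGcSecretome & b %in% truth$trueScMembranome) |
      (b %in% truth$trueGcSecretome & a %in% truth$trueScMembranome) |
      (a %in% truth$trueScSecretome & b %in% truth$trueGcMembranome) |
      (b %in% truth$trueScSecretome & a %in% truth$trueGcMembranome)
  }
  bg <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  while (nrow(bg) < config$nBackgroundEdges) {
    need <- config$nBackgroundEdges - nrow(bg)
    a <- sample(genes, 2L * need + 10L, replace = TRUE)
    b <- sample(genes, 2L * need + 10L, replace = TRUE)
    ok <- a != b & !isEligible(a, b)
    bg <- unique(rbind(bg, data.frame(a = a[ok], b = b[ok],
      stringsAsFactors = FALSE)))
  }
  bg <- bg[seq_len(config$nBackgroundEdges), , drop = FALSE]
  allEdges <- rbind(
    data.frame(geneA = plantedEdges$secreted, geneB = plantedEdges$membrane,
      stringsAsFactors = FALSE),
    data.frame(geneA = bg$a, geneB = bg$b, stringsAsFactors = FALSE)
  )
  allEdges$provenance <- sample(provenancePool, nrow(allEdges),
    replace = TRUE)
  sourcesNames <- c("biogrid", "hprd", "intact")
  primary <- sample(sourcesNames, nrow(allEdges), replace = TRUE)
  interactions <- lapply(setNames(sourcesNames, sourcesNames), function(src) {
    rows <- allEdges[primary == src, , drop = FALSE]
    ## ~25% of rows are duplicated into a second catalogue
    dup <- allEdges[primary != src & runif(nrow(allEdges)) < 0.125, ,
      drop = FALSE]
    out <- rbind(rows, dup)
    rownames(out) <- NULL
    out
  })

  ## PLA counts (continue the world stream; no reseeding here)
  pla <- generatePlaCounts(config, reseed = FALSE)

  list(
    config = config,
    genes = genes,
    truth = truth,
    chains = chains,
    tables = list(
      expression = mat,
      sampleCells = setNames(sampleCells, sampleIds),
      probesetToGene = data.frame(
        source_id = probesets[!is.na(psGene)],
        target_id = psGene[!is.na(psGene)], stringsAsFactors = FALSE),
      ranks = data.frame(gene = genes[!is.na(ranks)],
        rank = ranks[!is.na(ranks)], stringsAsFactors = FALSE),
      gene2go = goTable,
      proteomes = proteomes,
      mappingTables = mappingTables,
      groupToReference = groupTable,
      interactions = interactions
    ),
    pla = pla
  )
}

#' Generate PLA field counts
#'
#' Poisson-distributed signal counts per microscope field for a full assay
#' and a single-antibody control condition.
#'
#' @param config a [worldConfig()] list.
#' @param reseed set the seed from `config$seed` before drawing (TRUE for
#'   standalone use; [generateWorld()] passes FALSE to keep a single
#'   stream).
#' @return list with [PlaCounts-class] elements `full` and `control`.
#' @export
generatePlaCounts <- function(config = worldConfig(), reseed = TRUE) {
  stopifnot(inherits(config, "worldConfig"))
  if (reseed) set.seed(config$seed)
  list(
    full = PlaCounts("full_assay",
      rpois(config$plaFields, config$plaMeanFull)),
    control = PlaCounts("single_antibody",
      rpois(config$plaFields, config$plaMeanControl))
  )
}

#' Write a synthetic world to disk as pipeline-ready input files
#'
#' Writes every generated table in the plain-text formats the package
#' readers consume, plus a ready-to-run pipeline `config.yaml` and a
#' `truth.yaml` manifest of the planted ground truth.
#'
#' @param world output of [generateWorld()].
#' @param dir target directory (created if needed).
#' @return the pipeline config path, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- world$tables
  writeTsv <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  proteomePaths <- list()
  for (sp in names(tab$proteomes)) {
    path <- file.path(dir, sprintf("proteome_%s.txt", sp))
    writeLines(c(sprintf("# fluid proteome, species: %s", sp),
      tab$proteomes[[sp]]), path)
    proteomePaths[[sp]] <- path
    writeTsv(tab$mappingTables[[sp]]$proteinToGene,
      sprintf("map_protein_to_gene_%s.tsv", sp))
    writeTsv(tab$mappingTables[[sp]]$geneToGroup,
      sprintf("map_gene_to_group_%s.tsv", sp))
  }
  writeTsv(tab$groupToReference, "map_group_to_reference.tsv")
  exprDf <- data.frame(probeset = rownames(tab$expression),
    tab$expression, check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(exprDf, "expression_matrix.tsv")
  writeTsv(data.frame(sample = names(tab$sampleCells),
    cell_type = unname(tab$sampleCells)), "sample_annotation.tsv")
  writeTsv(tab$probesetToGene, "probeset_to_gene.tsv")
  writeTsv(tab$ranks, "secretion_ranks.tsv")
  go <- data.frame(
    tax_id = "10090", gene = tab$gene2go$gene, GO_ID = tab$gene2go$go_id,
    evidence = "IEA", qualifier = "-", GO_term = "synthetic",
    PubMed = "-", Category = "Component", stringsAsFactors = FALSE)
  writeTsv(go, "gene2go.tsv")
  interactionPaths <- character()
  for (src in names(tab$interactions)) {
    interactionPaths <- c(interactionPaths,
      writeTsv(tab$interactions[[src]], sprintf("interactions_%s.tsv", src)))
  }
  plaDf <- rbind(
    data.frame(condition = world$pla$full@condition,
      field_id = seq_along(world$pla$full@counts),
      count = world$pla$full@counts),
    data.frame(condition = world$pla$control@condition,
      field_id = seq_along(world$pla$control@counts),
      count = world$pla$control@counts))
  writeTsv(plaDf, "pla_counts.tsv")

  cellTypes <- names(world$config$samplesPerType)
  config <- list(
    seed = world$config$seed,
    reference_species = "mouse",
    proteomes = lapply(names(tab$proteomes), function(sp) list(
      species = sp,
      proteins = sprintf("proteome_%s.txt", sp),
      protein_to_gene = sprintf("map_protein_to_gene_%s.tsv", sp),
      gene_to_group = sprintf("map_gene_to_group_%s.tsv", sp),
      group_to_reference = "map_group_to_reference.tsv")),
    expression = list(
      matrix = "expression_matrix.tsv",
      samples = "sample_annotation.tsv",
      probeset_to_gene = "probeset_to_gene.tsv",
      germ_cells = as.list(cellTypes[-1L]),
      sertoli_cells = as.list(cellTypes[1L])),
    selection = list(bec_multiplier = 2, fold_change_min = 2,
      adj_p_max = 0.01),
    secretome = list(ranks = "secretion_ranks.tsv", max_rank = 2L),
    membranome = list(gene2go = "gene2go.tsv",
      terms = list("GO:0009986", "GO:0005886")),
    interactions = as.list(basename(interactionPaths)),
    pla = list(counts = "pla_counts.tsv", full = "full_assay",
      control = "single_antibody"),
    outdir = "results"
  )
  configPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, configPath)
  yaml::write_yaml(lapply(world$truth, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), file.path(dir, "truth.yaml"))
  invisible(configPath)
}
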