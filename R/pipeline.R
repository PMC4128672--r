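#' Read a pipeline configuration file
#'
#' The configuration is a single YAML file; all relative paths inside it are
#' resolved against its directory.
#'
#' @param path path to a YAML config (see the methods vignette for the
#'   schema; [writeWorld()] writes a valid example).
#' @return a named list with an attribute `dir` used for path resolution.
#' @export
readPipelineConfig <- function(path) {
  config <- yaml::read_yaml(path)
  attr(config, "dir") <- dirname(normalizePath(path))
  config
}

.resolvePath <- function(config, path) {
  base <- attr(config, "dir")
  if (is.null(base) || grepl("^/", path)) path else file.path(base, path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
      call. = FALSE))
}

#' Run the full secretome / crosstalk pipeline
#'
#' Orchestrates the workflow end to end: map each species proteome onto the
#' reference gene space and merge; define the germ-cell and Sertoli-cell
#' reference transcriptomes and discard opposite-pattern genes; classify
#' genes by secretion rank and membrane GO annotation; intersect into
#' cell-specific secretomes and membranomes with overlap enrichment;
#' consolidate the interaction catalogues and assemble the bipartite
#' crosstalk network; optionally compare PLA conditions. All stage counts
#' are collected into a report and, when an output directory is configured,
#' gene sets, statistics tables and network exports are written. The run is
#' fully deterministic: no stage draws random numbers.
#'
#' @param config a config list from [readPipelineConfig()], or a path to a
#'   YAML config file.
#' @return (invisibly) a list with the merged fluid proteome, transcriptome
#'   results, cell gene sets, enrichment results, the network and its
#'   summary, the PLA comparison (if configured) and a `report` data frame
#'   of stage counts.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)

  ## --- proteome mapping -------------------------------------------------
  tf <- .stage("idmap", {
    sets <- lapply(config$proteomes, function(p) {
      chain <- MappingChain(
        proteinToGene = readMappingTable(.resolvePath(config, p$protein_to_gene)),
        geneToGroup = readMappingTable(.resolvePath(config, p$gene_to_group)),
        groupToReference = readMappingTable(.resolvePath(config, p$group_to_reference)),
        referenceSpecies = config$reference_species %||% "reference")
      mapProteinsToReference(
        readProteomeList(.resolvePath(config, p$proteins)), chain,
        species = p$species)
    })
    Reduce(mergeReferenceSets, sets)
  })
  tfGenes <- geneIds(tf)

  ## --- transcriptomes ---------------------------------------------------
  sel <- config$selection %||% list()
  params <- SelectionParams(
    becMultiplier = sel$bec_multiplier %||% 2,
    foldChangeMin = sel$fold_change_min %||% 2,
    adjPMax = sel$adj_p_max %||% 0.01,
    priorDf = sel$prior_df %||% NA_real_)
  transcriptomes <- .stage("transcriptome", {
    ex <- config$expression
    study <- readExpressionStudy(
      .resolvePath(config, ex$matrix),
      .resolvePath(config, ex$samples),
      .resolvePath(config, ex$probeset_to_gene))
    germ <- unlist(ex$germ_cells)
    sertoli <- unlist(ex$sertoli_cells)
    gcT <- selectTranscriptome(study, germ, sertoli, params, cellType = "GC")
    scT <- selectTranscriptome(study, sertoli, germ, params, cellType = "SC")
    resolveConflicts(gcT, scT)
  })
  gcT <- transcriptomes$a
  scT <- transcriptomes$b

  ## --- annotation -------------------------------------------------------
  ann <- .stage("annotate", {
    ranks <- readSecretionRanks(.resolvePath(config, config$secretome$ranks))
    terms <- unlist(config$membranome$terms %||%
      list("GO:0009986", "GO:0005886"))
    go <- suppressMessages(
      readGeneGo(.resolvePath(config, config$membranome$gene2go)))
    list(secretome = referenceSecretome(ranks,
      config$secretome$max_rank %||% 2L),
      membranome = referenceMembranome(go, terms))
  })

  ## --- integration ------------------------------------------------------
  cells <- .stage("integrate", {
    gcSets <- buildCellGeneSets(gcT, tfGenes, ann$secretome, ann$membranome)
    scSets <- buildCellGeneSets(scT, tfGenes, ann$secretome, ann$membranome)
    enrich <- lapply(list(GC = gcSets, SC = scSets), function(cs) {
      sets <- cellGeneSetList(cs)
      hypergeometricEnrichment(
        k = length(sets$cellSecretome),
        n = length(sets$tfOverlap),
        K = length(intersect(sets$transcriptome, ann$secretome)),
        N = length(sets$transcriptome))
    })
    list(gc = gcSets, sc = scSets, enrichment = enrich)
  })

  ## --- network ----------------------------------------------------------
  network <- .stage("network", {
    catalogs <- lapply(unlist(config$interactions), function(p)
      readInteractionTable(.resolvePath(config, p)))
    catalog <- consolidateInteractions(catalogs)
    net <- buildCrosstalk(cells$gc, cells$sc, catalog)
    list(catalog = catalog, net = net, summary = networkSummary(net))
  })

  ## --- PLA (optional) ---------------------------------------------------
  pla <- NULL
  if (!is.null(config$pla)) {
    pla <- .stage("pla", {
      counts <- readPlaCounts(.resolvePath(config, config$pla$counts))
      full <- counts[[config$pla$full]]
      control <- counts[[config$pla$control]]
      c(plaCompare(full, control),
        list(full = full, control = control))
    })
  }

  ## --- report -----------------------------------------------------------
  cc <- classCounts(network$net)
  report <- data.frame(
    stage = c("tf_proteome_genes", "gc_transcriptome", "sc_transcriptome",
      "conflicts_discarded", "reference_secretome", "reference_membranome",
      "gc_tf_overlap", "sc_tf_overlap", "gc_secretome", "sc_secretome",
      "gc_membranome", "sc_membranome", "network_gc_secreted",
      "network_sc_secreted", "network_gc_membrane", "network_sc_membrane",
      "network_edges", "network_provenance"),
    count = c(length(tfGenes), length(geneIds(gcT)), length(geneIds(scT)),
      length(transcriptomes$discarded), length(ann$secretome),
      length(ann$membranome), length(cells$gc@tfOverlap),
      length(cells$sc@tfOverlap), length(cells$gc@cellSecretome),
      length(cells$sc@cellSecretome), length(cells$gc@cellMembranome),
      length(cells$sc@cellMembranome), cc[["GC_secreted"]],
      cc[["SC_secreted"]], cc[["GC_membrane"]], cc[["SC_membrane"]],
      nrow(networkEdges(network$net)), network$net@provenanceCount),
    stringsAsFactors = FALSE
  )
  .checkReportMonotonicity(report)

  result <- list(tf = tf, gcTranscriptome = gcT, scTranscriptome = scT,
    discarded = transcriptomes$discarded, secretome = ann$secretome,
    membranome = ann$membranome, gc = cells$gc, sc = cells$sc,
    enrichment = cells$enrichment, catalog = network$catalog,
    network = network$net, networkSummary = network$summary, pla = pla,
    report = report)

  if (!is.null(config$outdir)) {
    outdir <- .resolvePath(config, config$outdir)
    .stage("report", .writePipelineOutputs(result, outdir))
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## every intersection count must be bounded by its parents
.checkReportMonotonicity <- function(report) {
  count <- setNames(report$count, report$stage)
  stopifnot(
    count["gc_tf_overlap"] <= min(count["gc_transcriptome"],
      count["tf_proteome_genes"]),
    count["sc_tf_overlap"] <= min(count["sc_transcriptome"],
      count["tf_proteome_genes"]),
    count["gc_secretome"] <= min(count["gc_tf_overlap"],
      count["reference_secretome"]),
    count["sc_secretome"] <= min(count["sc_tf_overlap"],
      count["reference_secretome"]),
    count["gc_membranome"] <= min(count["gc_transcriptome"],
      count["reference_membranome"]),
    count["sc_membranome"] <= min(count["sc_transcriptome"],
      count["reference_membranome"]),
    count["network_gc_secreted"] <= count["gc_secretome"],
    count["network_sc_secreted"] <= count["sc_secretome"],
    count["network_gc_membrane"] <= count["gc_membranome"],
    count["network_sc_membrane"] <= count["sc_membranome"])
  invisible(TRUE)
}

.writePipelineOutputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeGeneSet(geneIds(result$tf), file.path(outdir, "tf_proteome_genes.txt"))
  writeGeneSet(geneIds(result$gcTranscriptome),
    file.path(outdir, "gc_transcriptome.txt"))
  writeGeneSet(geneIds(result$scTranscriptome),
    file.path(outdir, "sc_transcriptome.txt"))
  writeSelectionStats(result$gcTranscriptome,
    file.path(outdir, "gc_selection_stats.tsv"))
  writeSelectionStats(result$scTranscriptome,
    file.path(outdir, "sc_selection_stats.tsv"))
  for (cell in c("gc", "sc")) {
    sets <- cellGeneSetList(result[[cell]])
    writeGeneSet(sets$cellSecretome,
      file.path(outdir, sprintf("%s_secretome.txt", cell)))
    writeGeneSet(sets$cellMembranome,
      file.path(outdir, sprintf("%s_membranome.txt", cell)))
  }
  writeEnrichmentTable(result$enrichment,
    file.path(outdir, "enrichment.tsv"))
  writeNetworkGraphML(result$network, file.path(outdir, "network.graphml"))
  writeNetworkSIF(result$network, file.path(outdir, "network.sif"))
  writeNetworkEdgeList(result$network, file.path(outdir, "network_edges.tsv"))
  write.table(result$report, file.path(outdir, "report.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  if (!is.null(result$pla)) {
    plaTab <- data.frame(
      condition = c(result$pla$full@condition, result$pla$control@condition),
      mean_density = c(plaMeanDensity(result$pla$full),
        plaMeanDensity(result$pla$control)),
      t = result$pla$t, p = result$pla$p)
    write.table(plaTab, file.path(outdir, "pla_comparison.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
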