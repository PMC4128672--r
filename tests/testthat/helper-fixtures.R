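# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# a small two-group expression study: nBackground null probesets around
# `baseline`, nSignal probesets elevated by `effect` in group A
makeTwoGroupStudy <- function(nBackground = 270, nSignal = 30, effect = 2,
                              baseline = 5, high = 10, sd = 0.4,
                              nPerGroup = 4, seed = 11) {
  set.seed(seed)
  n <- nBackground + nSignal
  probesets <- sprintf("PS%04d", seq_len(n))
  samples <- c(paste0("A", seq_len(nPerGroup)), paste0("B", seq_len(nPerGroup)))
  meanA <- c(rep(baseline, nBackground), rep(high + effect, nSignal))
  meanB <- c(rep(baseline, nBackground), rep(high, nSignal))
  mat <- cbind(
    matrix(rnorm(n * nPerGroup, meanA, sd), nrow = n),
    matrix(rnorm(n * nPerGroup, meanB, sd), nrow = n)
  )
  rownames(mat) <- probesets
  colnames(mat) <- samples
  genes <- sprintf("G%04d", seq_len(n))
  ExpressionStudy(mat,
    sampleCells = setNames(rep(c("A", "B"), each = nPerGroup), samples),
    probesetToGene = setNames(genes, probesets))
}

# a random mapping chain over nProteins proteins with controlled redundancy
# and broken links; returns the chain plus the raw tables for oracle walks
makeChainFixture <- function(nProteins = 50, nGenes = 38, nBroken = 8,
                             seed = 5) {
  set.seed(seed)
  proteins <- sprintf("P%03d", seq_len(nProteins))
  spGenes <- sprintf("g%03d", seq_len(nGenes))
  groups <- sprintf("h%03d", seq_len(nGenes))
  refGenes <- sprintf("MG%03d", seq_len(nGenes))
  # many-to-one: each protein drawn onto a species gene
  p2g <- setNames(sample(spGenes, nProteins, replace = TRUE), proteins)
  g2h <- setNames(groups, spGenes)
  h2r <- setNames(refGenes, groups)
  # break nBroken chains at a random step
  brokenProteins <- sample(proteins, nBroken)
  for (p in brokenProteins) {
    step <- sample(3, 1)
    if (step == 1 || !p %in% names(p2g)) {
      p2g <- p2g[names(p2g) != p]
    } else if (step == 2 || !p2g[[p]] %in% names(g2h)) {
      g2h <- g2h[names(g2h) != p2g[[p]]]
    } else {
      h2r <- h2r[names(h2r) != g2h[[p2g[[p]]]]]
    }
  }
  list(
    chain = MappingChain(p2g, g2h, h2r, referenceSpecies = "mouse"),
    proteins = proteins, p2g = p2g, g2h = g2h, h2r = h2r
  )
}

# independent one-id-at-a-time walk of the three tables (brute-force oracle)
oracleWalk <- function(proteins, p2g, g2h, h2r) {
  genes <- character()
  unmapped <- character()
  for (p in proteins) {
    g <- if (p %in% names(p2g)) p2g[[p]] else NA
    h <- if (!is.na(g) && g %in% names(g2h)) g2h[[g]] else NA
    r <- if (!is.na(h) && h %in% names(h2r)) h2r[[h]] else NA
    if (is.na(r)) unmapped <- c(unmapped, p) else genes <- c(genes, r)
  }
  list(genes = sort(unique(genes)), unmapped = unmapped)
}

# quadratic brute-force of the BH step-up definition
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank <- which(ord == i)
    vals <- numeric(0)
    for (j in seq_len(m)) {
      rj <- which(ord == j)
      if (rj >= rank) vals <- c(vals, p[j] * m / rj)
    }
    adj[i] <- min(1, min(vals))
  }
  adj
}

# quadratic scan oracle for crosstalk edge eligibility
scanCrosstalkEdges <- function(catalog, gcSec, scMem, scSec, gcMem) {
  e <- catalogEdges(catalog)
  out <- list()
  for (i in seq_len(nrow(e))) {
    for (ori in 1:2) {
      s <- if (ori == 1) e$geneA[i] else e$geneB[i]
      m <- if (ori == 1) e$geneB[i] else e$geneA[i]
      if (s == m) next
      if (s %in% gcSec && m %in% scMem)
        out[[length(out) + 1L]] <- c(s, m, "GC_secreted")
      if (s %in% scSec && m %in% gcMem)
        out[[length(out) + 1L]] <- c(s, m, "SC_secreted")
    }
  }
  if (!length(out)) {
    return(data.frame(secreted = character(), membrane = character(),
      stringsAsFactors = FALSE))
  }
  df <- unique(as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE))
  names(df) <- c("secreted", "membrane", "secreted_class")
  df[order(df$secreted, df$membrane), , drop = FALSE]
}
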