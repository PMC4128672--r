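makeTinyStudy <- function(values, nPerGroup = 2) {
  n <- length(values) / (2 * nPerGroup)
  mat <- matrix(values, nrow = n)
  rownames(mat) <- sprintf("PS%02d", seq_len(n))
  samples <- c(paste0("A", seq_len(nPerGroup)), paste0("B", seq_len(nPerGroup)))
  colnames(mat) <- samples
  ExpressionStudy(mat,
    sampleCells = setNames(rep(c("A", "B"), each = nPerGroup), samples),
    probesetToGene = setNames(sprintf("G%02d", seq_len(n)), rownames(mat)))
}

test_that("the BEC is the pooled median with the mean-of-middle convention", {
  study <- makeTinyStudy(c(1, 2, 3, 4))
  expect_equal(computeBEC(study), 2.5)

  constant <- makeTinyStudy(rep(7.25, 8))
  expect_equal(computeBEC(constant), 7.25)

  # seeded matrix against an independent sort-and-pick computation
  set.seed(3)
  vals <- rnorm(200 * 6, mean = 6, sd = 2)
  mat <- matrix(vals, nrow = 200,
    dimnames = list(sprintf("PS%03d", 1:200),
      c("A1", "A2", "A3", "B1", "B2", "B3")))
  study <- ExpressionStudy(mat,
    setNames(rep(c("A", "B"), each = 3), colnames(mat)))
  sorted <- sort(vals)
  oracle <- (sorted[600] + sorted[601]) / 2
  expect_equal(computeBEC(study), oracle)
})

test_that("BH adjustment matches hand and brute-force step-up computations", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjaminiHochberg(0.4), 0.4)
  expect_error(benjaminiHochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:5) {
    p <- runif(100)^sample(c(1, 3), 1)
    expect_equal(benjaminiHochberg(p), bruteForceBH(p), tolerance = 1e-12)
  }
})

test_that("BH never decreases a p-value and keeps the smallest p first", {
  set.seed(23)
  for (i in 1:10) {
    p <- runif(50)
    adj <- benjaminiHochberg(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # the smallest raw p attains the smallest adjusted value
    expect_equal(adj[which.min(p)], min(adj))
  }
})

test_that("the intensity threshold is a hard boundary regardless of p and FC", {
  # probeset 1: huge effect but max target intensity just below 2 x BEC
  set.seed(31)
  nPerGroup <- 3
  n <- 40
  baseline <- 5
  mat <- matrix(rnorm(n * 6, baseline, 0.1), nrow = n)
  rownames(mat) <- sprintf("PS%02d", seq_len(n))
  colnames(mat) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  study0 <- ExpressionStudy(mat, setNames(rep(c("A", "B"), each = 3),
    colnames(mat)), setNames(sprintf("G%02d", 1:n), rownames(mat)))
  bec <- computeBEC(study0)
  # plant a strong differential signal capped just under the cutoff
  mat[1, 1:3] <- 2 * bec - 0.05
  mat[1, 4:6] <- baseline - 2
  study <- ExpressionStudy(mat, setNames(rep(c("A", "B"), each = 3),
    colnames(mat)), setNames(sprintf("G%02d", 1:n), rownames(mat)))
  res <- selectTranscriptome(study, "A", "B")
  st <- selectionStats(res)
  expect_lt(st$adj_p[1], 0.01)           # significant ...
  expect_gt(st$fold_change[1], 2)        # ... and strongly changed ...
  expect_false(st$selected[1])           # ... but below the intensity cut
})

test_that("planted differential probesets are recovered by the three rules", {
  study <- makeTwoGroupStudy(nBackground = 270, nSignal = 30, effect = 2,
    seed = 11)
  res <- selectTranscriptome(study, "A", "B")
  st <- selectionStats(res)

  # independent re-implementation of the three selection rules
  mat <- SummarizedExperiment::assay(study)
  bec <- (function(v) { s <- sort(v); m <- length(s)
    if (m %% 2) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  })(as.numeric(mat))
  aCols <- 1:4; bCols <- 5:8
  oracleSel <- logical(nrow(mat))
  adjOracle <- bruteForceBH(st$raw_p)
  for (i in seq_len(nrow(mat))) {
    maxT <- max(mat[i, aCols])
    fc <- 2^(mean(mat[i, aCols]) - mean(mat[i, bCols]))
    oracleSel[i] <- maxT >= 2 * bec && fc >= 2 && adjOracle[i] <= 0.01
  }
  expect_identical(st$selected, oracleSel)

  # recovery of the planted block, allowing FDR-consistent errors
  planted <- sprintf("G%04d", 271:300)
  expect_gte(length(intersect(geneIds(res), planted)), 28)
  expect_lte(length(setdiff(geneIds(res), planted)), 3)
})

test_that("an all-background matrix yields an empty transcriptome", {
  study <- makeTwoGroupStudy(nBackground = 100, nSignal = 0, seed = 2)
  res <- selectTranscriptome(study, "A", "B")
  expect_length(geneIds(res), 0)
})

test_that("selection is monotone in the thresholds", {
  study <- makeTwoGroupStudy(nBackground = 150, nSignal = 25, effect = 1.5,
    seed = 13)
  base <- geneIds(selectTranscriptome(study, "A", "B",
    SelectionParams(foldChangeMin = 2, adjPMax = 0.01)))
  stricterFC <- geneIds(selectTranscriptome(study, "A", "B",
    SelectionParams(foldChangeMin = 3, adjPMax = 0.01)))
  stricterP <- geneIds(selectTranscriptome(study, "A", "B",
    SelectionParams(foldChangeMin = 2, adjPMax = 0.001)))
  expect_true(all(stricterFC %in% base))
  expect_true(all(stricterP %in% base))
})

test_that("probesets without a gene mapping contribute statistics but no genes", {
  set.seed(41)
  mat <- matrix(rnorm(20 * 4, 12, 0.3), nrow = 20)
  mat[, 3:4] <- mat[, 3:4] - 4
  rownames(mat) <- sprintf("PS%02d", 1:20)
  colnames(mat) <- c("A1", "A2", "B1", "B2")
  # only the first 10 probesets have a gene
  study <- ExpressionStudy(mat,
    setNames(c("A", "A", "B", "B"), colnames(mat)),
    setNames(sprintf("G%02d", 1:10), rownames(mat)[1:10]))
  res <- selectTranscriptome(study, "A", "B")
  expect_equal(nrow(selectionStats(res)), 20)
  expect_true(all(geneIds(res) %in% sprintf("G%02d", 1:10)))
})

test_that("opposite-pattern genes are discarded from both transcriptomes", {
  mkRes <- function(cellType, genes) new("TranscriptomeResult",
    cellType = cellType, genes = genes,
    stats = data.frame(probeset = character(), gene = character(),
      max_target = numeric(), fold_change = numeric(), raw_p = numeric(),
      adj_p = numeric(), selected = logical()),
    bec = 6)
  a <- mkRes("GC", c("g1", "g2"))
  b <- mkRes("SC", c("g2", "g3"))
  out <- resolveConflicts(a, b)
  expect_identical(geneIds(out$a), "g1")
  expect_identical(geneIds(out$b), "g3")
  expect_identical(out$discarded, "g2")
  expect_length(intersect(geneIds(out$a), geneIds(out$b)), 0)

  # disjoint inputs unchanged
  d <- resolveConflicts(mkRes("GC", c("x1", "x2")), mkRes("SC", "y1"))
  expect_length(d$discarded, 0)
  expect_identical(geneIds(d$a), c("x1", "x2"))

  # seeded fixture with exactly 12 planted conflicts
  set.seed(51)
  pool <- sprintf("MG%04d", 1:300)
  conflicts <- sample(pool, 12)
  aGenes <- sort(c(conflicts, sample(setdiff(pool, conflicts), 80)))
  bGenes <- sort(c(conflicts, sample(setdiff(pool, aGenes), 60)))
  out2 <- resolveConflicts(mkRes("GC", aGenes), mkRes("SC", bGenes))
  expect_setequal(out2$discarded, conflicts)

  expect_error(resolveConflicts(mkRes("GC", "g"), mkRes("GC", "h")),
    "different cell classes")
})
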