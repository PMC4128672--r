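#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma, which is nearly linear; used by the
#' method-of-moments fit of the variance prior.
#'
#' @param y positive numeric vector.
#' @return x such that trigamma(x) = y, elementwise.
#' @keywords internal
trigammaInverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  todo <- is.na(out) & is.finite(y)
  x <- 0.5 + 1 / y[todo]
  if (any(todo)) {
    for (i in seq_len(50L)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[todo] <- x
  }
  out
}

#' Method-of-moments fit of a scaled-F variance prior
#'
#' Models observed residual variances s^2 (each on `df` degrees of freedom)
#' as draws from a scaled F distribution around a prior variance s0^2 with
#' prior degrees of freedom d0, and estimates (s0^2, d0) by matching the
#' mean and variance of log(s^2). When the spread of log variances does not
#' exceed what `df` degrees of freedom alone produce, the prior degrees of
#' freedom are infinite and every probeset shares the prior variance.
#'
#' @param s2 numeric vector of residual variances (zeros allowed; a small
#'   fraction of exact zeros is tolerated by flooring at the smallest
#'   positive value observed).
#' @param df residual degrees of freedom per variance (scalar).
#' @return list with elements `priorVar` (s0^2) and `priorDf` (d0, possibly
#'   Inf).
#' @export
fitVariancePrior <- function(s2, df) {
  stopifnot(length(df) == 1L, df > 0)
  s2 <- as.numeric(s2)
  if (all(s2 == 0))
    stop("all residual variances are zero; variance prior cannot be fitted")
  floorVal <- min(s2[s2 > 0])
  z <- log(pmax(s2, floorVal))
  zmean <- mean(z)
  zvar <- var(z)
  if (!is.finite(zvar)) zvar <- 0
  excess <- zvar - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigammaInverse(excess)
    logS0 <- zmean - digamma(df / 2) + log(df / 2) +
      digamma(d0 / 2) - log(d0 / 2)
  } else {
    d0 <- Inf
    logS0 <- zmean - digamma(df / 2) + log(df / 2)
  }
  list(priorVar = exp(logS0), priorDf = d0)
}

#' Moderated two-group test per probeset
#'
#' For every probeset, compares the mean log2 intensity of a target cell
#' group against a reference cell group with an empirical-Bayes moderated
#' F statistic. The pooled residual variance s^2 of each probeset (on
#' d = n_t + n_r - 2 degrees of freedom) is shrunk toward a prior variance
#' s0^2 with weight `priorDf` (d0):
#'
#'   s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)
#'
#' and the squared standardized mean difference is referred to an F
#' distribution on (1, d0 + d) degrees of freedom. By default s0^2 and d0
#' are estimated from the observed variance distribution by
#' [fitVariancePrior()]; `priorDf = 0` recovers the classical
#' pooled-variance test, `priorDf = Inf` tests every probeset against the
#' common prior variance.
#'
#' @param study an [ExpressionStudy-class].
#' @param targetCells character vector of cell-type labels forming the
#'   target group (e.g. the two germ-cell populations).
#' @param referenceCells labels forming the reference group.
#' @param priorDf NA (default: estimate), 0, a positive number, or Inf.
#' @return data frame with columns probeset, statistic, raw_p; the fitted
#'   prior is attached as attributes `priorVar` and `priorDf`.
#' @export
moderatedGroupTest <- function(study, targetCells, referenceCells,
                               priorDf = NA_real_) {
  stopifnot(is(study, "ExpressionStudy"))
  x <- SummarizedExperiment::assay(study)
  ct <- SummarizedExperiment::colData(study)$cell_type
  tIdx <- which(ct %in% targetCells)
  rIdx <- which(ct %in% referenceCells)
  if (length(intersect(tIdx, rIdx)))
    stop("target and reference cell groups overlap")
  nt <- length(tIdx)
  nr <- length(rIdx)
  if (nt < 2L || nr < 2L)
    stop("both cell groups need at least 2 samples")
  xt <- x[, tIdx, drop = FALSE]
  xr <- x[, rIdx, drop = FALSE]
  mt <- rowMeans(xt)
  mr <- rowMeans(xr)
  d <- nt + nr - 2L
  rss <- rowSums((xt - mt)^2) + rowSums((xr - mr)^2)
  s2 <- rss / d
  if (is.na(priorDf)) {
    prior <- fitVariancePrior(s2, d)
  } else if (priorDf == 0) {
    if (all(s2 == 0))
      stop("all within-group variances are zero; use a positive priorDf")
    prior <- list(priorVar = NA_real_, priorDf = 0)
  } else {
    prior <- fitVariancePrior(s2, d)
    prior$priorDf <- priorDf
  }
  d0 <- prior$priorDf
  s2tilde <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(prior$priorVar, length(s2))
  } else {
    (d0 * prior$priorVar + d * s2) / (d0 + d)
  }
  stat <- (mt - mr)^2 / (s2tilde * (1 / nt + 1 / nr))
  stat[s2tilde == 0 & (mt - mr) == 0] <- 0
  dfTotal <- d0 + d
  rawP <- pf(stat, 1, dfTotal, lower.tail = FALSE)
  out <- data.frame(probeset = rownames(x), statistic = unname(stat),
    raw_p = unname(rawP), stringsAsFactors = FALSE)
  attr(out, "priorVar") <- prior$priorVar
  attr(out, "priorDf") <- prior$priorDf
  out
}
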