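#' Mean PLA signal density
#'
#' Arithmetic mean of the per-field signal counts (signals per 0.25 mm^2).
#'
#' @param x a [PlaCounts-class].
#' @return a single number.
#' @export
plaMeanDensity <- function(x) {
  stopifnot(is(x, "PlaCounts"))
  if (length(x@counts) == 0L) stop("no fields counted")
  mean(x@counts)
}

#' Compare PLA signal densities between two conditions
#'
#' Classical two-sample pooled-variance Student's t-test, two-sided, on raw
#' per-field counts — the standard comparison of a full proximity-ligation
#' assay against its single-antibody control. When the pooled variance is
#' zero and the means are equal the statistic is defined as 0 with p = 1.
#'
#' @param a,b [PlaCounts-class] objects with at least two fields each.
#' @return list with elements `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
plaCompare <- function(a, b) {
  stopifnot(is(a, "PlaCounts"), is(b, "PlaCounts"))
  xa <- as.numeric(a@counts)
  xb <- as.numeric(b@counts)
  na <- length(xa)
  nb <- length(xb)
  if (na < 2L || nb < 2L) stop("each condition needs at least 2 fields")
  df <- na + nb - 2L
  s2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  if (se == 0) {
    if (mean(xa) == mean(xb)) {
      tstat <- 0
      p <- 1
    } else {
      tstat <- sign(mean(xa) - mean(xb)) * Inf
      p <- 0
    }
  } else {
    tstat <- (mean(xa) - mean(xb)) / se
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  }
  list(t = tstat, p = p, df = df, mean_a = mean(xa), mean_b = mean(xb))
}
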