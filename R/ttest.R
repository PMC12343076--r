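#' Cell-level Welch t-test (pseudoreplication baseline)
#'
#' Per gene, a two-sided Welch two-sample t-test between the cells of the
#' two conditions on normalized values. Every cell is treated as an
#' independent observation, so the test ignores the nested structure and
#' serves as the pseudoreplication baseline: on null data with
#' within-sample correlation its p-values are anti-conservative.
#'
#' A gene with zero variance in both groups gets p = 1 when the group
#' means are equal, and p at the numerical floor when they differ.
#'
#' @param m gene x cell count matrix.
#' @param design a [NestedDesign-class].
#' @param normalization `"log1p_cpm"` (default), `"cpm"` or `"raw"`.
#' @return A [DEResult-class]; `effect` is the condition-1 minus
#'   condition-2 difference of cell means on the normalized scale.
#' @export
cellTTest <- function(m, design,
                      normalization = c("log1p_cpm", "cpm", "raw")) {
  normalization <- match.arg(normalization)
  ad <- alignCountsDesign(m, design, strict = TRUE)
  m <- ad$counts; design <- ad$design
  lev <- conditionLevels(design)
  cc <- cellConditions(design)[match(colnames(m), design@cells)]
  g1 <- cc == lev[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("need >= 2 cells per condition")
  vals <- switch(normalization,
                 raw = m, cpm = cpmCells(m), log1p_cpm = log1pCpm(m))
  s1 <- rowStats(vals[, g1, drop = FALSE])
  s2 <- rowStats(vals[, !g1, drop = FALSE])
  d <- s1$mean - s2$mean
  se2 <- s1$var / n1 + s2$var / n2
  t_stat <- ifelse(se2 > 0, d / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((s1$var / n1)^2 / (n1 - 1) +
                          (s2$var / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  # zero variance, unequal means: the statistic degenerates; report the
  # smallest representable p rather than 0 to keep p in (0, 1]
  p[se2 == 0 & d != 0] <- .Machine$double.xmin
  p[se2 == 0 & d == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  DEResult(rownames(m), d, p, "t_test")
}

# row means and unbiased variances of a (possibly sparse) matrix
rowStats <- function(x) {
  n <- ncol(x)
  mu <- as.numeric(Matrix::rowMeans(x))
  ex2 <- as.numeric(Matrix::rowMeans(x^2))
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}
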