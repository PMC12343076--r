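#' Remove rarely expressed genes
#'
#' Drops genes detected (count > 0) in fewer than `minExpressedFraction`
#' of the cells. The boundary is inclusive: a gene expressed in exactly
#' that fraction of cells is retained, i.e. strictly-below-threshold genes
#' are removed. Gene order is preserved, and the operation is idempotent.
#'
#' @param m gene x cell count matrix (sparse or dense, with dimnames).
#' @param minExpressedFraction minimum fraction of cells with nonzero
#'   count, default 0.10.
#' @return The filtered matrix (possibly with zero rows).
#' @examples
#' m <- Matrix::Matrix(c(0, 0, 1, 1, 1, 0), nrow = 2, sparse = TRUE,
#'                     dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' rownames(filterGenes(m, 0.5))
#' @export
filterGenes <- function(m, minExpressedFraction = 0.10) {
  stopifnot(minExpressedFraction >= 0, minExpressedFraction <= 1)
  if (ncol(m) == 0L || nrow(m) == 0L) return(m)
  detected <- Matrix::rowSums(m > 0)
  keep <- detected / ncol(m) >= minExpressedFraction
  m[keep, , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p-values in
#' (0, 1], clipped at 1. A thin, validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
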