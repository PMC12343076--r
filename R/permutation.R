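#' Pseudobulk permutation test for differential expression
#'
#' For each gene the observed statistic is the difference in mean
#' normalized pseudobulk expression between the two conditions. A null
#' distribution is built by reshuffling the sample-level condition
#' labels; the two-sided p-value is the fraction of label assignments
#' whose |difference| reaches the observed one, floored at 1/n (the
#' smallest p-value the test can produce). When the number of distinct
#' label assignments is at most `exhaustiveThreshold` all of them are
#' enumerated (the observed assignment included) and n is their count;
#' otherwise `nPerm` Monte-Carlo shuffles are drawn.
#'
#' @param pb pseudobulk [SummarizedExperiment::SummarizedExperiment] from
#'   [pseudobulk()] (raw counts; normalized internally).
#' @param nPerm Monte-Carlo permutations (default 10000).
#' @param exhaustiveThreshold enumerate exhaustively when the number of
#'   distinct assignments is at most this (default 20000).
#' @param normalization assay normalization before testing, see
#'   [normalizePseudobulk()]. The default `"log1p_cpm"` tests differences
#'   of log expression, so up- and down-regulation are treated
#'   symmetrically; on the linear CPM scale a down-regulated gene's
#'   difference is bounded by its base mean and easily swamped by
#'   multiplicative batch noise.
#' @param seed integer seed for the Monte-Carlo branch.
#' @return A [DEResult-class]; `effect` is the observed difference in
#'   means (condition 1 minus condition 2), `n_resamples_used` the n in
#'   the p-value denominator.
#' @export
permutationTest <- function(pb, nPerm = 10000, exhaustiveThreshold = 20000,
                            normalization = c("log1p_cpm", "cpm", "none"),
                            seed = 1) {
  normalization <- match.arg(normalization)
  pb <- normalizePseudobulk(pb, normalization)
  v <- SummarizedExperiment::assay(pb, "pseudobulk")
  cond <- as.character(SummarizedExperiment::colData(pb)$condition)
  lev <- unique(cond)
  if (length(lev) != 2) stop("need exactly two conditions")
  S <- length(cond)
  n1 <- sum(cond == lev[1])
  if (n1 < 1 || S - n1 < 1) stop("one condition has no samples")
  if (n1 < 2 || S - n1 < 2) {
    warning("fewer than 2 samples in a condition; the test has little power")
  }
  obs <- diffMeansByLabel(v, cond == lev[1])
  nAssign <- choose(S, n1)
  if (nAssign <= exhaustiveThreshold) {
    combos <- utils::combn(S, n1)
    b <- integer(nrow(v))
    for (start in seq(1, ncol(combos), by = 2000)) {
      idx <- start:min(start + 1999, ncol(combos))
      W <- matrix(-1 / (S - n1), nrow = S, ncol = length(idx))
      for (j in seq_along(idx)) W[combos[, idx[j]], j] <- 1 / n1
      b <- b + rowSums(abs(v %*% W) >= abs(obs) - 1e-12)
    }
    n_used <- ncol(combos)
  } else {
    null_ge <- withr::with_seed(seed, {
      acc <- integer(nrow(v))
      done <- 0L
      while (done < nPerm) {
        B <- min(2000L, nPerm - done)
        W <- vapply(seq_len(B), function(j) {
          w <- rep(-1 / (S - n1), S)
          w[sample.int(S, n1)] <- 1 / n1
          w
        }, numeric(S))
        acc <- acc + rowSums(abs(v %*% W) >= abs(obs) - 1e-12)
        done <- done + B
      }
      acc
    })
    b <- null_ge
    n_used <- nPerm
  }
  p <- pmax(b, 1) / n_used
  p <- pmin(p, 1)
  DEResult(rownames(v), obs, p, "permutation",
           rep.int(as.integer(n_used), nrow(v)))
}

diffMeansByLabel <- function(v, isFirst) {
  rowMeans(v[, isFirst, drop = FALSE]) - rowMeans(v[, !isFirst, drop = FALSE])
}
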