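#' Mixed-effect framework for pseudoreplication
#'
#' For gene expression in a two-stage design, cell-level observations
#' decompose as Y = mu_c + b_i + e_ij with a sample-level random effect
#' b_i ~ N(0, sigma2_b) and cell-level noise e_ij ~ N(0, nu2_eps). Cells
#' from the same sample are then correlated with intraclass correlation
#' rho = sigma2_b / (sigma2_b + nu2_eps), and the variance of the mean of
#' n such cells is inflated by 1 + (n - 1) * rho relative to independence.
#' These helpers evaluate the closed forms.
#'
#' @param sigma2_b sample-level variance component (>= 0).
#' @param nu2_eps cell-level residual variance (>= 0); not both zero.
#' @return `icc`: the intraclass correlation rho in [0, 1], with the total
#'   variance sigma2_b + nu2_eps attached as attribute
#'   `"total_variance"`.
#' @examples
#' icc(0.05, 0.95)              # 0.05
#' varianceInflation(1000, 0.05) # 50.95
#' degreesOfFreedom(5, 1000)     # naive 9998, correct 8
#' @export
icc <- function(sigma2_b, nu2_eps) {
  if (sigma2_b < 0 || nu2_eps < 0) stop("variance components must be nonnegative")
  tot <- sigma2_b + nu2_eps
  if (tot == 0) stop("intraclass correlation undefined when both variances are zero")
  structure(sigma2_b / tot, total_variance = tot)
}

#' Variance-inflation multiplier for correlated cells
#'
#' The factor 1 + (n - 1) * rho by which within-sample correlation rho
#' inflates the variance of a mean over n cells (equals 1 under
#' independence and n under perfect correlation).
#'
#' @param n cells per sample (>= 1).
#' @param rho intraclass correlation in [0, 1].
#' @return The multiplier, >= 1.
#' @export
varianceInflation <- function(n, rho) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  1 + (n - 1) * rho
}

#' Specification of the two-stage mixed model
#'
#' @param mu fixed condition means (length 2, expression units); only
#'   carried along, the variance formulas do not use it.
#' @param sigma2_b sample-level variance component.
#' @param nu2_eps cell-level residual variance.
#' @param N samples per condition.
#' @param n cells per sample.
#' @return A list of class `MixedModelSpec`.
#' @export
mixedModelSpec <- function(mu = c(0, 0), sigma2_b, nu2_eps, N, n) {
  stopifnot(sigma2_b >= 0, nu2_eps >= 0, N >= 1, n >= 1)
  structure(list(mu = mu, sigma2_b = sigma2_b, nu2_eps = nu2_eps,
                 N = N, n = n),
            class = "MixedModelSpec")
}

#' Variance of the difference-in-means estimator
#'
#' For N samples per condition and n cells per sample, the difference in
#' condition means of cell-level values has variance
#' (2 / (N n)) * (sigma2_b + nu2_eps) * (1 + (n - 1) rho). With rho taken
#' from the same variance components this equals (2 / N) * Var(sample
#' mean).
#'
#' @param spec a [mixedModelSpec()].
#' @param rho intraclass correlation; defaults to [icc()] of the spec's
#'   components.
#' @return The variance of the difference-in-means estimator.
#' @export
varDiffMeans <- function(spec, rho = NULL) {
  stopifnot(inherits(spec, "MixedModelSpec"))
  if (is.null(rho)) rho <- as.numeric(icc(spec$sigma2_b, spec$nu2_eps))
  tot <- spec$sigma2_b + spec$nu2_eps
  2 / (spec$N * spec$n) * tot * varianceInflation(spec$n, rho)
}

#' Naive versus correct degrees of freedom
#'
#' A cell-level two-sample t-test on N samples per condition with n cells
#' each claims 2 N n - 2 degrees of freedom; the number of independent
#' experimental units supports only 2 N - 2.
#'
#' @param N samples per condition; @param n cells per sample.
#' @return Named numeric vector `c(naive = 2 N n - 2, correct = 2 N - 2)`.
#' @export
degreesOfFreedom <- function(N, n) {
  stopifnot(N >= 1, n >= 1)
  c(naive = 2 * N * n - 2, correct = 2 * N - 2)
}

#' Empirical intraclass correlation from nested expression data
#'
#' Per-gene one-way ANOVA ICC(1) estimates with samples as groups,
#' computed on log1p-CPM transformed counts by default (or on the values
#' as given with `transform = "none"`, for data already on a linear
#' scale). When the design has more than one batch the estimate is
#' batch-stratified: ICC(1) is computed within each batch and the
#' per-gene estimates are combined as a cell-count-weighted mean, so the
#' coefficient reflects sample-level heterogeneity rather than the
#' (separately modelled) batch shifts. With a single batch this is
#' plain one-way ICC(1). Unbalanced group sizes use the standard n0
#' correction n0 = (N - sum n_i^2 / N) / (a - 1). Estimates are clipped
#' to [-1/(n0 - 1), 1]; the pooled estimate is the median across genes.
#'
#' Samples with a single cell cannot contribute a within-sample variance
#' and are excluded with a warning.
#'
#' @param m gene x cell matrix (counts, or arbitrary values with
#'   `transform = "none"`).
#' @param design a [NestedDesign-class] covering the matrix's cells.
#' @param transform `"log1p_cpm"` (default) or `"none"`.
#' @return list with `per_gene` (named numeric vector of ICC(1)
#'   estimates) and `pooled` (their median).
#' @export
empiricalICC <- function(m, design, transform = c("log1p_cpm", "none")) {
  transform <- match.arg(transform)
  ad <- alignCountsDesign(m, design, strict = FALSE)
  m <- ad$counts; design <- ad$design
  if (transform == "log1p_cpm") {
    m <- log1pCpm(m)
    transform <- "none"
  }
  batches <- unique(cellBatches(design))
  if (length(batches) > 1L) {
    cb <- cellBatches(design)
    ests <- matrix(NA_real_, nrow(m), length(batches))
    wts <- numeric(length(batches))
    for (b in seq_along(batches)) {
      cells <- design@cells[cb == batches[b]]
      sub <- subsetDesign(design, cells)
      ests[, b] <- iccOneWay(m[, cells, drop = FALSE], sub)
      wts[b] <- length(cells)
    }
    est <- as.numeric(ests %*% wts) / sum(wts)
    names(est) <- rownames(m)
    return(list(per_gene = est, pooled = stats::median(est, na.rm = TRUE)))
  }
  est <- iccOneWay(m, design)
  list(per_gene = est, pooled = stats::median(est, na.rm = TRUE))
}

# per-gene one-way ANOVA ICC(1), samples as groups
iccOneWay <- function(m, design) {
  grp <- cellSamples(design)[colnames(m)]
  sizes <- table(grp)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding sample(s) with a single cell: ",
            paste(drop, collapse = ", "))
    keep <- !(grp %in% drop)
    m <- m[, keep, drop = FALSE]
    grp <- grp[keep]
    sizes <- table(grp)
  }
  a <- length(sizes)
  if (a < 2) stop("need >= 2 samples with >= 2 cells each")
  m <- as.matrix(m)
  Ntot <- ncol(m)
  n_i <- as.numeric(sizes)[match(unique(grp), names(sizes))]
  groups <- unique(grp)
  # group means per gene: G x a
  ind <- Matrix::sparseMatrix(i = seq_along(grp),
                              j = match(grp, groups),
                              x = 1, dims = c(Ntot, a))
  gm <- as.matrix(m %*% ind) / rep(n_i, each = nrow(m))
  grand <- Matrix::rowSums(m) / Ntot
  ssb <- as.numeric(gm^2 %*% n_i) - Ntot * grand^2
  sst <- rowSums(m^2) - Ntot * grand^2
  ssw <- sst - ssb
  msb <- ssb / (a - 1)
  msw <- ssw / (Ntot - a)
  n0 <- (Ntot - sum(n_i^2) / Ntot) / (a - 1)
  est <- (msb - msw) / (msb + (n0 - 1) * msw)
  est[msb + (n0 - 1) * msw <= 0] <- 0  # constant gene: no variance at all
  est <- pmin(pmax(est, -1 / (n0 - 1)), 1)
  names(est) <- rownames(m)
  est
}

# counts-per-million per cell followed by log(1 + x); keeps zeros zero,
# so sparsity is preserved
log1pCpm <- function(m) {
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) stop("cell(s) with zero total count")
  scaled <- m %*% Matrix::Diagonal(x = 1e6 / cs)
  dimnames(scaled) <- dimnames(m)
  log1p(scaled)
}

cpmCells <- function(m) {
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) stop("cell(s) with zero total count")
  scaled <- m %*% Matrix::Diagonal(x = 1e6 / cs)
  dimnames(scaled) <- dimnames(m)
  scaled
}
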