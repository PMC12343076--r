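#' Precision-recall curve and AUPRC against ground truth
#'
#' Genes are ranked by the result's `rank_score` (ascending p-value, ties
#' broken by decreasing |effect|, then gene id) and the precision-recall
#' curve is swept over all rank cutoffs. The area is the step-wise
#' average precision (the mean of the precision at every true positive's
#' rank), without interpolation. The random-ranking baseline of this
#' area equals the prevalence of positives.
#'
#' @param result a [DEResult-class].
#' @param truth named logical vector of true DE status; names must match
#'   the result's gene set exactly and at least one gene must be
#'   positive.
#' @return list with `curve` (data.frame `rank`, `recall`, `precision`),
#'   `auprc`, and `prevalence`.
#' @examples
#' res <- DEResult(paste0("g", 1:4), c(4, 3, 2, 1),
#'                 c(0.01, 0.02, 0.03, 0.04), "toy")
#' truth <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = FALSE)
#' prCurve(res, truth)$auprc  # 0.8333...
#' @export
prCurve <- function(result, truth) {
  tab <- resultTable(result)
  if (!setequal(tab$gene, names(truth))) {
    stop("gene sets of result and truth must be identical")
  }
  pos <- truth[tab$gene[order(tab$rank_score)]]
  P <- sum(pos)
  if (P == 0) stop("no positives in truth; precision-recall undefined")
  tp <- cumsum(pos)
  k <- seq_along(pos)
  precision <- tp / k
  recall <- tp / P
  auprc <- sum(precision[pos]) / P
  list(curve = data.frame(rank = k, recall = recall, precision = precision),
       auprc = auprc,
       prevalence = P / length(pos))
}

#' @rdname prCurve
#' @export
auprc <- function(result, truth) prCurve(result, truth)$auprc

#' False-positive-rate calibration curve on null data
#'
#' For a result computed on data with no true differential expression,
#' reports the observed false positive rate (the fraction of genes with
#' p <= alpha) across a grid of p-value cutoffs — by default 2000
#' equidistant cutoffs spanning (0, 1]. A well-calibrated test tracks
#' the diagonal; values above it flag anti-conservative behaviour.
#'
#' @param result a [DEResult-class] with p-values on null data.
#' @param cutoffs numeric cutoff grid, or a single integer n for n
#'   equidistant cutoffs in (0, 1].
#' @return data.frame with columns `cutoff` and `observed_fpr`
#'   (non-decreasing in `cutoff`).
#' @export
calibrationCurve <- function(result, cutoffs = 2000) {
  p <- resultTable(result)$p_value
  if (any(is.na(p))) stop("calibration needs p-values for every gene")
  if (length(cutoffs) == 1 && cutoffs >= 1 && cutoffs == floor(cutoffs)) {
    cutoffs <- seq_len(cutoffs) / cutoffs
  }
  stopifnot(all(cutoffs > 0 & cutoffs <= 1), !is.unsorted(cutoffs))
  sp <- sort(p)
  fpr <- findInterval(cutoffs, sp) / length(p)
  data.frame(cutoff = cutoffs, observed_fpr = fpr)
}

#' Split a dataset into sample-balanced subsets
#'
#' Partitions the cells into disjoint subsets of at most `maxCells` cells
#' each, such that every subset retains at least `minCellsPerSample`
#' cells from every sample (preserving the design's balance for
#' reproducibility analyses). Each sample's cells are shuffled and dealt
#' round-robin across the subsets. If some sample is too small to give
#' every subset its minimum, the subset count is reduced with a warning;
#' if no subset count satisfies both constraints, the split is rejected.
#'
#' @param m gene x cell count matrix.
#' @param design a [NestedDesign-class].
#' @param maxCells maximum cells per subset (default 4000).
#' @param minCellsPerSample minimum cells from each sample in each subset
#'   (default 20).
#' @param seed integer seed for the shuffles.
#' @return list of `list(counts =, design =)` pairs.
#' @export
splitDataset <- function(m, design, maxCells = 4000,
                         minCellsPerSample = 20, seed = 1) {
  ad <- alignCountsDesign(m, design, strict = TRUE)
  m <- ad$counts; design <- ad$design
  grp <- cellSamples(design)[colnames(m)]
  sizes <- table(grp)
  if (any(sizes < minCellsPerSample)) {
    stop("sample(s) below the per-subset minimum of ", minCellsPerSample,
         " cells: ", paste(names(sizes)[sizes < minCellsPerSample],
                           collapse = ", "))
  }
  total <- ncol(m)
  K <- ceiling(total / maxCells)
  Kmax <- min(floor(sizes / minCellsPerSample))
  if (K > Kmax) {
    warning("reducing subset count from ", K, " to ", Kmax,
            " so every subset keeps >= ", minCellsPerSample,
            " cells per sample")
    K <- Kmax
  }
  if (K < 1 || ceiling(total / K) > maxCells) {
    stop("cannot satisfy both the ", maxCells, "-cell cap and the ",
         minCellsPerSample, "-cells-per-sample minimum")
  }
  assign <- withr::with_seed(seed, {
    out <- integer(total)
    offset <- 0L
    for (s in names(sizes)) {
      idx <- which(grp == s)
      idx <- idx[sample.int(length(idx))]
      # rotate the round-robin start so subset sizes stay balanced
      out[idx] <- ((seq_along(idx) - 1L + offset) %% K) + 1L
      offset <- (offset + length(idx)) %% K
    }
    out
  })
  lapply(seq_len(K), function(k) {
    cells <- colnames(m)[assign == k]
    list(counts = m[, cells, drop = FALSE],
         design = subsetDesign(design, cells))
  })
}

#' Top-N Jaccard overlap between two results
#'
#' The Jaccard index |A intersect B| / |A union B| of the top `n` genes of
#' two DE results, each ranked by its `rank_score`. Used to quantify
#' method reproducibility across dataset subsets.
#'
#' @param a,b [DEResult-class] objects ranking at least `n` genes.
#' @param n number of top genes (default 100).
#' @return A number in [0, 1].
#' @export
jaccardTopN <- function(a, b, n = 100) {
  ta <- topGenes(a, n)
  tb <- topGenes(b, n)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Run the simulation benchmark
#'
#' For every scenario and replicate: simulate with a replicate-specific
#' seed, apply the 10 percent gene filter, run each requested method, and
#' score the AUPRC against the simulated truth restricted to the retained
#' genes. Method failures on a replicate are recorded as missing and the
#' run continues.
#'
#' @param scenarios character vector of preset names (see
#'   [scenarioConfig()]).
#' @param methods subset of `c("permutation", "hierboot", "ttest")`.
#' @param nReplicates independent simulations per scenario (default 20).
#' @param baseSeed integer; replicate r of scenario s uses seed
#'   `baseSeed + 1000 * s + r`.
#' @param simArgs list of overrides for [scenarioConfig()] (e.g.
#'   `n_genes`).
#' @param methodArgs named list of per-method argument lists (e.g.
#'   `list(hierboot = list(nBootInitial = 1000))`).
#' @return Tidy data.frame with columns `scenario`, `method`,
#'   `replicate_seed`, `metric_name`, `value` (one `auprc` row per
#'   scenario x method x replicate).
#' @export
runBenchmark <- function(scenarios = "dataset",
                         methods = c("permutation", "ttest"),
                         nReplicates = 20, baseSeed = 1,
                         simArgs = list(), methodArgs = list()) {
  methods <- match.arg(methods, c("permutation", "hierboot", "ttest"),
                       several.ok = TRUE)
  rows <- list()
  for (si in seq_along(scenarios)) {
    for (r in seq_len(nReplicates)) {
      seed <- baseSeed + 1000L * si + r
      sim <- do.call(simulateScenario,
                     c(list(preset = scenarios[si], seed = seed), simArgs))
      counts <- filterGenes(simCounts(sim))
      truth <- isDE(sim)[rownames(counts)]
      for (meth in methods) {
        val <- tryCatch({
          res <- runMethod(meth, counts, simDesign(sim), seed,
                           methodArgs[[meth]])
          auprc(res, truth)
        }, error = function(e) {
          warning(sprintf("%s failed on %s replicate %d: %s",
                          meth, scenarios[si], r, conditionMessage(e)))
          NA_real_
        })
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scenarios[si], method = meth,
          replicate_seed = seed, metric_name = "auprc", value = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

runMethod <- function(method, counts, design, seed, args = NULL) {
  args <- args %||% list()
  switch(method,
    permutation = do.call(permutationTest,
                          c(list(pb = pseudobulk(counts, design),
                                 seed = seed), args)),
    hierboot = do.call(hierarchicalBootstrap,
                       c(list(m = counts, design = design, seed = seed),
                         args)),
    ttest = do.call(cellTTest, c(list(m = counts, design = design), args)))
}
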