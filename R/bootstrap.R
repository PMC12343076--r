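#' Hierarchical bootstrap test for nested single-cell data
#'
#' Resampling respects the nesting: within each condition and each batch
#' stratum, samples are drawn with replacement (as many as the stratum
#' contains), then `cellsPerDraw` cells are drawn with replacement from
#' every drawn sample. Batch representation is equalized by truncating
#' each batch's pooled draw to the smallest pool within the condition, so
#' every batch contributes the same number of cells. Each iteration
#' yields a per-gene mean for both conditions; with c1 iterations where
#' condition 1 exceeds condition 2 and c2 the reverse (exact ties count
#' toward neither), the p-value is max(min(c1, c2), 1) / n, floored at
#' 1/n. Genes hitting the floor after `nBootInitial` iterations are
#' re-run at `nBootEscalated` iterations (adaptive sampling);
#' `n_resamples_used` records the final n per gene. Batches present in
#' only one condition cannot support a within-batch comparison and are
#' excluded from both conditions' draws with a warning.
#'
#' @param m gene x cell count matrix.
#' @param design a [NestedDesign-class].
#' @param nBootInitial first-stage iterations (default 10000).
#' @param nBootEscalated iterations for genes at the first-stage floor
#'   (default 100000).
#' @param cellsPerDraw cells drawn per sampled sample (default 100).
#' @param normalization `"log1p_cpm"` (default), `"cpm"` or `"raw"`
#'   transformation of the cell-level values before averaging; the
#'   default matches the other tests' symmetric log-scale statistic.
#' @param seed integer seed.
#' @return A [DEResult-class]; `effect` is the mean over iterations of
#'   the condition-1 minus condition-2 per-gene means.
#' @export
hierarchicalBootstrap <- function(m, design,
                                  nBootInitial = 10000,
                                  nBootEscalated = 100000,
                                  cellsPerDraw = 100,
                                  normalization = c("log1p_cpm", "cpm", "raw"),
                                  seed = 1) {
  normalization <- match.arg(normalization)
  stopifnot(nBootInitial >= 1, nBootEscalated > nBootInitial,
            cellsPerDraw >= 1)
  ad <- alignCountsDesign(m, design, strict = TRUE)
  m <- ad$counts; design <- ad$design
  lev <- conditionLevels(design)
  st <- design@sampleTable
  shared <- intersect(unique(st$batch[st$condition == lev[1]]),
                      unique(st$batch[st$condition == lev[2]]))
  if (!length(shared)) {
    stop("no batch contains samples from both conditions")
  }
  if (length(setdiff(unique(st$batch), shared))) {
    warning("excluding batch(es) present in only one condition: ",
            paste(setdiff(unique(st$batch), shared), collapse = ", "))
  }
  keep_samples <- st$sample[st$batch %in% shared]
  keep_cells <- design@cells[design@cellSample %in% keep_samples]
  m <- m[, keep_cells, drop = FALSE]
  design <- subsetDesign(design, keep_cells)
  st <- design@sampleTable

  vals <- switch(normalization,
                 raw = m,
                 cpm = cpmCells(m),
                 log1p_cpm = log1pCpm(m))
  vals <- as.matrix(vals)

  # cell indices grouped by sample, plus stratum bookkeeping
  cs <- cellSamples(design)[colnames(m)]
  cellIdxBySample <- split(seq_len(ncol(m)), cs)
  strata <- lapply(lev, function(cc) {
    sub <- st[st$condition == cc, , drop = FALSE]
    split(sub$sample, sub$batch)
  })
  names(strata) <- lev

  withr::with_seed(seed, {
    stage1 <- bootstrapStage(vals, cellIdxBySample, strata, lev,
                             nBootInitial, cellsPerDraw)
    p <- stage1$p
    effect <- stage1$effect
    n_used <- rep.int(as.integer(nBootInitial), nrow(vals))
    floor_hit <- which(p <= 1 / nBootInitial + 1e-15 &
                         stage1$decided)
    if (length(floor_hit)) {
      stage2 <- bootstrapStage(vals[floor_hit, , drop = FALSE],
                               cellIdxBySample, strata, lev,
                               nBootEscalated, cellsPerDraw)
      p[floor_hit] <- stage2$p
      effect[floor_hit] <- stage2$effect
      n_used[floor_hit] <- as.integer(nBootEscalated)
    }
  })
  DEResult(rownames(vals), effect, p, "hierarchical_bootstrap", n_used)
}

# one full run of n_iter hierarchical bootstrap iterations
bootstrapStage <- function(vals, cellIdxBySample, strata, lev,
                           n_iter, cellsPerDraw, chunk = 250L) {
  G <- nrow(vals)
  c1 <- integer(G); c2 <- integer(G)
  eff_sum <- numeric(G)
  done <- 0L
  while (done < n_iter) {
    B <- min(chunk, n_iter - done)
    m1 <- conditionMeans(vals, cellIdxBySample, strata[[lev[1]]], B,
                         cellsPerDraw)
    m2 <- conditionMeans(vals, cellIdxBySample, strata[[lev[2]]], B,
                         cellsPerDraw)
    c1 <- c1 + rowSums(m1 > m2)
    c2 <- c2 + rowSums(m2 > m1)
    eff_sum <- eff_sum + rowSums(m1 - m2)
    done <- done + B
  }
  decided <- (c1 + c2) > 0
  p <- ifelse(decided, pmax(pmin(c1, c2), 1) / n_iter, 1)
  p <- pmin(p, 1)
  list(p = p, effect = eff_sum / n_iter, decided = decided)
}

# per-gene means of B pooled hierarchical draws for one condition:
# per batch stratum, draw (with replacement) as many samples as the
# stratum holds, then cellsPerDraw cells per drawn sample; truncate every
# batch pool to the smallest pool so batches are equally represented.
conditionMeans <- function(vals, cellIdxBySample, batchSamples, B,
                           cellsPerDraw) {
  pool_sizes <- vapply(batchSamples, function(s) length(s) * cellsPerDraw,
                       numeric(1))
  L <- as.integer(min(pool_sizes))        # cells kept per batch
  idx_all <- integer(0)
  for (samples in batchSamples) {
    sN <- length(samples)
    drawn <- samples[sample.int(sN, B * sN, replace = TRUE)]
    lens <- lengths(cellIdxBySample)[drawn]
    within <- floor(stats::runif(length(drawn) * cellsPerDraw) *
                      rep(lens, each = cellsPerDraw)) + 1
    starts <- rep(cumsum(c(0, lens[-length(lens)])), each = cellsPerDraw)
    flat <- unlist(cellIdxBySample[drawn], use.names = FALSE)
    cells <- flat[starts + within]
    # reshape to B x (sN * cellsPerDraw), keep the first L per iteration
    dim(cells) <- c(sN * cellsPerDraw, B)
    idx_all <- c(idx_all, as.integer(cells[seq_len(L), , drop = FALSE]))
  }
  nb <- length(batchSamples)
  iter <- rep(rep(seq_len(B), each = L), times = nb)
  S <- Matrix::sparseMatrix(i = idx_all, j = iter, x = 1 / (L * nb),
                            dims = c(ncol(vals), B))
  as.matrix(vals %*% S)
}
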