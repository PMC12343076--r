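#' Moment-matched log-normal parameters
#'
#' Given the desired natural-scale mean and standard deviation of a
#' log-normal distribution, returns the `(meanlog, sdlog)` pair such that
#' draws have exactly those moments: sdlog^2 = log(1 + sd^2/mean^2),
#' meanlog = log(mean) - sdlog^2 / 2.
#'
#' @param mean natural-scale mean (> 0).
#' @param sd natural-scale standard deviation (>= 0).
#' @return Named numeric vector `c(meanlog =, sdlog =)`.
#' @examples
#' lognormalParamsFromMoments(13.2, 5.5)
#' @export
lognormalParamsFromMoments <- function(mean, sd) {
  if (mean <= 0) stop("mean must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  s2 <- log(1 + sd^2 / mean^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw differential-expression fold changes
#'
#' Fold changes for DE genes are drawn i.i.d. from the log-normal
#' distribution moment-matched to a natural-scale mean of 13.2 and
#' standard deviation of 5.5 (5 percent quantile about 6.3, 95 percent
#' quantile about 23.5), so most DE genes carry a strong signal.
#' Magnitudes only; direction is assigned separately by the simulator.
#'
#' @param k number of draws.
#' @param fcMean,fcSd natural-scale moments of the distribution.
#' @return Numeric vector of k factors (> 0, in practice > 1).
#' @export
drawFoldChanges <- function(k, fcMean = 13.2, fcSd = 5.5) {
  stopifnot(k >= 0)
  if (k == 0) return(numeric(0))
  p <- lognormalParamsFromMoments(fcMean, fcSd)
  stats::rlnorm(k, meanlog = p["meanlog"], sdlog = p["sdlog"])
}

#' Draw variable cells-per-sample counts
#'
#' Cell numbers per sample are gamma-distributed (shape 0.8, rate 0.0035;
#' mean about 228, sd about 255), rounded to integers, and floored at
#' `floor` so every sample keeps at least a handful of cells.
#'
#' @param nSamples number of samples to draw for.
#' @param shape,rate gamma parameters.
#' @param floor minimum cells per sample after rounding (default 10).
#' @return Integer vector of length `nSamples`.
#' @export
drawCellCounts <- function(nSamples, shape = 0.8, rate = 0.0035, floor = 10) {
  stopifnot(shape > 0, rate > 0, nSamples >= 0)
  pmax(as.integer(round(stats::rgamma(nSamples, shape = shape, rate = rate))),
       as.integer(floor))
}

#' Scenario configuration for the simulator
#'
#' Resolves a named preset plus overrides into the full parameter list
#' consumed by [simulateScenario()]. Presets:
#' \describe{
#'   \item{dataset}{single batch, 2 conditions x 5 samples x 250 cells.}
#'   \item{atlas}{3 batches x 5 samples x 250 cells; within each batch the
#'     conditions split 3/2 with the majority condition alternating, so
#'     every batch holds both conditions.}
#'   \item{varying_cells}{dataset layout with gamma-distributed cells per
#'     sample ([drawCellCounts()]).}
#'   \item{unbalanced_atlas}{two batches of ten samples, split 9:1 and
#'     1:9 between the conditions, 250 cells per sample.}
#'   \item{negative_control}{the atlas layout with `de_fraction = 0`.}
#' }
#'
#' @param preset one of the five preset names.
#' @param n_genes number of genes (default 5000).
#' @param de_fraction fraction of DE genes (default 0.05; the sparse
#'   variant in the benchmark uses 0.005).
#' @param fc_mean,fc_sd natural-scale moments of the fold-change
#'   log-normal.
#' @param cells_per_sample fixed cells per sample (ignored when
#'   `vary_cells`).
#' @param vary_cells draw cells per sample from the gamma distribution.
#' @param cell_count_gamma `c(shape, rate)` for [drawCellCounts()].
#' @param batch_effect_params list of `c(location, scale)` pairs, one per
#'   batch, parameterising the log-normal batch-factor magnitudes.
#' @param sample_effect_sd log-scale sd of the per-gene x sample
#'   multiplicative random effect; the default is calibrated so the
#'   pooled empirical ICC of null data sits near 0.05.
#' @param base_mean_gamma `c(shape, rate)` of the gene base-mean gamma.
#' @param libsize_lognormal `c(location, scale)` of the per-cell library
#'   size.
#' @param bcv_common common biological coefficient of variation; the
#'   negative binomial uses variance mu + bcv^2 mu^2.
#' @return A list of class `ScenarioConfig`.
#' @export
scenarioConfig <- function(preset = c("dataset", "atlas", "varying_cells",
                                      "unbalanced_atlas", "negative_control"),
                           n_genes = 5000,
                           de_fraction = 0.05,
                           fc_mean = 13.2, fc_sd = 5.5,
                           cells_per_sample = 250,
                           vary_cells = FALSE,
                           cell_count_gamma = c(shape = 0.8, rate = 0.0035),
                           batch_effect_params = NULL,
                           sample_effect_sd = 0.13,
                           base_mean_gamma = c(shape = 0.6, rate = 0.3),
                           libsize_lognormal = c(location = 11, scale = 0.2),
                           bcv_common = 0.1) {
  preset <- match.arg(preset)
  atlas_params <- list(c(0.05, 0.1), c(0.8, 0.1), c(1.45, 0.05))
  layout <- switch(preset,
    dataset = data.frame(batch = "b1", n1 = 5, n2 = 5),
    varying_cells = data.frame(batch = "b1", n1 = 5, n2 = 5),
    atlas = data.frame(batch = c("b1", "b2", "b3"),
                       n1 = c(3, 2, 3), n2 = c(2, 3, 2)),
    negative_control = data.frame(batch = c("b1", "b2", "b3"),
                                  n1 = c(3, 2, 3), n2 = c(2, 3, 2)),
    unbalanced_atlas = data.frame(batch = c("b1", "b2"),
                                  n1 = c(9, 1), n2 = c(1, 9)))
  if (is.null(batch_effect_params)) {
    batch_effect_params <- switch(preset,
      dataset = list(),
      varying_cells = list(),
      atlas = atlas_params,
      negative_control = atlas_params,
      unbalanced_atlas = atlas_params[1:2])
  }
  if (preset == "negative_control") de_fraction <- 0
  if (preset == "varying_cells") vary_cells <- TRUE
  if (nrow(layout) > 1 && length(batch_effect_params) != nrow(layout)) {
    stop("need one (location, scale) pair per batch")
  }
  if (any(layout$n1 < 1 | layout$n2 < 1)) {
    stop("every batch must contain at least one sample from each condition")
  }
  stopifnot(de_fraction >= 0, de_fraction <= 1, fc_mean > 0, fc_sd >= 0,
            n_genes >= 1, cells_per_sample >= 1)
  structure(list(preset = preset, n_genes = n_genes,
                 de_fraction = de_fraction,
                 fc_mean = fc_mean, fc_sd = fc_sd,
                 layout = layout,
                 cells_per_sample = cells_per_sample,
                 vary_cells = vary_cells,
                 cell_count_gamma = cell_count_gamma,
                 batch_effect_params = batch_effect_params,
                 sample_effect_sd = sample_effect_sd,
                 base_mean_gamma = base_mean_gamma,
                 libsize_lognormal = libsize_lognormal,
                 bcv_common = bcv_common),
            class = "ScenarioConfig")
}

#' Simulate a nested single-cell benchmark scenario
#'
#' Generates hierarchically structured negative-binomial counts with
#' ground-truth DE labels. The generative pipeline:
#' \enumerate{
#'   \item gene base means from a gamma distribution;
#'   \item a `de_fraction` subset of genes receives a log-normal fold
#'     change on the condition-2 mean, up- or down-regulated with equal
#'     probability (down = reciprocal factor);
#'   \item a per-gene x sample multiplicative log-normal random effect
#'     (log-scale sd `sample_effect_sd`) induces within-sample
#'     correlation;
#'   \item a per-gene x batch multiplicative factor whose magnitude is
#'     log-normal with the batch's `(location, scale)` and whose
#'     direction (factor vs reciprocal) is random per gene and batch;
#'   \item per-cell expected counts: the sample's gene means normalised
#'     to proportions times a log-normal cell library size;
#'   \item counts drawn negative-binomially with variance
#'     mu + bcv^2 mu^2.
#' }
#'
#' @param preset preset name passed to [scenarioConfig()], or an already
#'   resolved `ScenarioConfig` list.
#' @param ... overrides forwarded to [scenarioConfig()].
#' @param seed integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @return A [SimulatedDataset-class].
#' @examples
#' sim <- simulateScenario("dataset", n_genes = 50, cells_per_sample = 20,
#'                         seed = 1)
#' sim
#' @export
simulateScenario <- function(preset = "dataset", ..., seed = 1) {
  cfg <- if (inherits(preset, "ScenarioConfig")) preset
         else scenarioConfig(preset, ...)
  withr::with_seed(seed, simulateFromConfig(cfg))
}

simulateFromConfig <- function(cfg) {
  G <- cfg$n_genes
  genes <- sprintf("gene%04d", seq_len(G))
  lay <- cfg$layout
  # sample table
  st <- do.call(rbind, lapply(seq_len(nrow(lay)), function(b) {
    data.frame(
      batch = lay$batch[b],
      condition = rep(c("1", "2"), times = c(lay$n1[b], lay$n2[b])),
      stringsAsFactors = FALSE)
  }))
  st$sample <- sprintf("s%02d", seq_len(nrow(st)))
  S <- nrow(st)
  nbatch <- length(unique(st$batch))

  # (1) base means
  lambda <- stats::rgamma(G, shape = cfg$base_mean_gamma[[1]],
                          rate = cfg$base_mean_gamma[[2]])
  lambda <- pmax(lambda, 1e-8)

  # (2) DE genes and condition-2 factors
  nDE <- round(cfg$de_fraction * G)
  is_de <- rep(FALSE, G)
  fc_applied <- rep(1, G)
  if (nDE > 0) {
    de_idx <- sample.int(G, nDE)
    is_de[de_idx] <- TRUE
    fc <- drawFoldChanges(nDE, cfg$fc_mean, cfg$fc_sd)
    up <- stats::runif(nDE) < 0.5
    fc_applied[de_idx] <- ifelse(up, fc, 1 / fc)
  }
  mu_cond <- cbind(`1` = lambda, `2` = lambda * fc_applied)

  # (3) per-gene x sample random effect
  sampEff <- matrix(stats::rlnorm(G * S, meanlog = 0,
                                  sdlog = cfg$sample_effect_sd),
                    nrow = G, ncol = S)

  # (4) per-gene x batch factors
  batches <- unique(st$batch)
  bf <- matrix(1, nrow = G, ncol = nbatch,
               dimnames = list(genes, batches))
  if (length(cfg$batch_effect_params)) {
    for (b in seq_len(nbatch)) {
      pars <- cfg$batch_effect_params[[b]]
      mag <- stats::rlnorm(G, meanlog = pars[[1]], sdlog = pars[[2]])
      flip <- stats::runif(G) < 0.5
      bf[, b] <- ifelse(flip, 1 / mag, mag)
    }
  }

  # cells per sample
  ncells <- if (cfg$vary_cells) {
    drawCellCounts(S, cfg$cell_count_gamma[[1]], cfg$cell_count_gamma[[2]])
  } else rep.int(as.integer(cfg$cells_per_sample), S)

  # (5)-(6) per-sample expected values and NB counts
  lp <- cfg$libsize_lognormal
  blocks <- vector("list", S)
  cell_ids <- vector("list", S)
  offset <- 0L
  for (s in seq_len(S)) {
    mu_s <- mu_cond[, st$condition[s]] * sampEff[, s] *
      bf[, match(st$batch[s], batches)]
    prop <- mu_s / sum(mu_s)
    lib <- stats::rlnorm(ncells[s], meanlog = lp[[1]], sdlog = lp[[2]])
    mu_cells <- outer(prop, lib)  # G x ncells[s]
    cnt <- matrix(stats::rnbinom(length(mu_cells), mu = mu_cells,
                                 size = 1 / cfg$bcv_common^2),
                  nrow = G)
    blocks[[s]] <- as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
    cell_ids[[s]] <- sprintf("cell%05d", offset + seq_len(ncells[s]))
    offset <- offset + ncells[s]
  }
  counts <- do.call(cbind, blocks)
  dimnames(counts) <- list(genes, unlist(cell_ids))

  design <- NestedDesign(
    cell = colnames(counts),
    sample = rep(st$sample, times = ncells),
    batch = rep(st$batch, times = ncells),
    condition = rep(st$condition, times = ncells))

  new("SimulatedDataset", counts = counts, design = design,
      isDE = is_de, foldChange = fc_applied, batchFactors = bf,
      config = unclass(cfg))
}

#' Permute sample-level condition labels
#'
#' Reassigns the condition labels uniformly at random across samples
#' (preserving the label multiset) while leaving the cell -> sample and
#' sample -> batch structure untouched. Used to build negative controls
#' from real or simulated data.
#'
#' @param design a [NestedDesign-class] with >= 2 samples.
#' @param seed integer seed.
#' @return A new [NestedDesign-class].
#' @export
permuteConditionLabels <- function(design, seed = 1) {
  st <- design@sampleTable
  if (nrow(st) < 2) stop("need >= 2 samples to permute")
  st$condition <- withr::with_seed(seed, sample(st$condition))
  new("NestedDesign", cells = design@cells, cellSample = design@cellSample,
      sampleTable = st)
}
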