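test_that("pseudobulk aggregation sums each sample's cells and conserves mass", {
  # one cell per sample: pseudobulk equals the count matrix
  m <- toyCounts(6, 4)
  nd <- NestedDesign(colnames(m), paste0("s", 1:4), "b1",
                     c("1", "1", "2", "2"))
  pb <- pseudobulk(m, nd)
  expect_equal(unname(SummarizedExperiment::assay(pb)), unname(as.matrix(m)))
  # 2 samples x 2 cells toy, hand-aggregated
  m2 <- Matrix::Matrix(matrix(c(1, 2, 3, 4,
                                5, 6, 7, 8), nrow = 2, byrow = TRUE),
                       sparse = TRUE,
                       dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  nd2 <- NestedDesign(paste0("c", 1:4), c("s1", "s1", "s2", "s2"),
                      "b1", c("1", "1", "2", "2"))
  v <- SummarizedExperiment::assay(pseudobulk(m2, nd2))
  expect_equal(unname(v), matrix(c(3, 11, 7, 15), nrow = 2))
  # conservation on an arbitrary fixture
  m3 <- toyCounts(30, 12, seed = 8)
  nd3 <- toyDesign(ns = 2, nc = 3)
  expect_equal(sum(SummarizedExperiment::assay(pseudobulk(m3, nd3))), sum(m3))
  # mean aggregation
  vm <- SummarizedExperiment::assay(pseudobulk(m2, nd2, agg = "mean"))
  expect_equal(unname(vm), matrix(c(1.5, 5.5, 3.5, 7.5), nrow = 2))
})

test_that("pseudobulk normalization scales columns to a million and logs", {
  m <- Matrix::Matrix(matrix(c(1, 3, 2, 6), nrow = 2), sparse = TRUE,
                      dimnames = list(c("g1", "g2"), c("c1", "c2")))
  nd <- NestedDesign(c("c1", "c2"), c("s1", "s2"), "b1", c("1", "2"))
  pb <- pseudobulk(m, nd)
  cpm <- SummarizedExperiment::assay(normalizePseudobulk(pb, "cpm"))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(unname(cpm[, 1]), c(0.25e6, 0.75e6))
  lg <- SummarizedExperiment::assay(normalizePseudobulk(pb, "log1p_cpm"))
  expect_equal(unname(lg[, 1]), log1p(c(0.25e6, 0.75e6)))
  same <- SummarizedExperiment::assay(normalizePseudobulk(pb, "none"))
  expect_equal(same, SummarizedExperiment::assay(pb))
})

test_that("exhaustive permutation p matches full enumeration on a 3-vs-3 toy", {
  vals <- matrix(c(10, 11, 12, 20, 21, 22), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  nd <- NestedDesign(paste0("s", 1:6), paste0("s", 1:6), "b1",
                     rep(c("1", "2"), each = 3))
  pb <- pseudobulk(Matrix::Matrix(vals, sparse = TRUE), nd)
  res <- permutationTest(pb, normalization = "none")
  # independent oracle: enumerate all 20 assignments by brute force
  combos <- utils::combn(6, 3)
  deltas <- apply(combos, 2, function(idx) {
    abs(mean(vals[1, idx]) - mean(vals[1, -idx]))
  })
  obs <- abs(mean(vals[1, 1:3]) - mean(vals[1, 4:6]))
  p_oracle <- sum(deltas >= obs) / ncol(combos)
  expect_equal(p_oracle, 2 / 20)
  expect_equal(resultTable(res)$p_value, p_oracle)
  expect_equal(unique(nResamplesUsed(res)), 20L)
  # Monte-Carlo branch agrees within 3 binomial standard errors
  resMC <- permutationTest(pb, normalization = "none",
                           exhaustiveThreshold = 1, nPerm = 4000, seed = 2)
  pmc <- resultTable(resMC)$p_value
  se <- sqrt(p_oracle * (1 - p_oracle) / 4000)
  expect_lt(abs(pmc - p_oracle), 3 * se)
})

test_that("constant genes get p = 1 and p never falls below 1/n", {
  m <- Matrix::Matrix(matrix(c(rep(5, 6), 1, 1, 1, 50, 50, 50),
                             nrow = 2, byrow = TRUE), sparse = TRUE,
                      dimnames = list(c("flat", "de"), paste0("s", 1:6)))
  nd <- NestedDesign(paste0("s", 1:6), paste0("s", 1:6), "b1",
                     rep(c("1", "2"), each = 3))
  res <- permutationTest(pseudobulk(m, nd), normalization = "none")
  tab <- resultTable(res)
  expect_equal(tab$p_value[tab$gene == "flat"], 1)
  expect_equal(tab$p_value[tab$gene == "de"], 2 / 20)  # floor of the
  # exhaustive two-sided enumeration (observed + mirror)
  expect_true(all(tab$p_value >= 1 / unique(nResamplesUsed(res))))
})

test_that("null permutation p-values are uniform on the attainable grid", {
  # Gaussian null pseudobulk, no DE, no batch structure
  S <- 10
  v <- withr::with_seed(21, matrix(stats::rnorm(2000 * S), ncol = S,
                                   dimnames = list(sprintf("g%04d", 1:2000),
                                                   paste0("s", 1:S))))
  pb <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pseudobulk = v),
    colData = S4Vectors::DataFrame(condition = rep(c("1", "2"), each = S / 2),
                                   batch = "b1",
                                   row.names = paste0("s", 1:S)))
  res <- permutationTest(pb, normalization = "none")
  p <- resultTable(res)$p_value
  # ties are expected: exhaustive p-values live on a discrete grid
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("hierarchical bootstrap escalates floor genes and respects the floor", {
  withr::local_seed(31)
  G <- 30; ncell <- 40
  m <- matrix(stats::rpois(G * 4 * ncell, 5), nrow = G)
  # gene 1: expressed only in condition 1
  m[1, (2 * ncell + 1):(4 * ncell)] <- 0
  dimnames(m) <- list(paste0("g", 1:G), paste0("c", seq_len(4 * ncell)))
  nd <- NestedDesign(colnames(m), rep(paste0("s", 1:4), each = ncell),
                     "b1", rep(c("1", "2"), each = 2 * ncell))
  res <- hierarchicalBootstrap(Matrix::Matrix(m, sparse = TRUE), nd,
                               nBootInitial = 200, nBootEscalated = 1000,
                               cellsPerDraw = 20, seed = 1)
  tab <- resultTable(res)
  nr <- nResamplesUsed(res)
  # the all-condition-1 gene hits the stage-1 floor and is escalated
  expect_equal(unname(nr["g1"]), 1000L)
  expect_equal(tab$p_value[tab$gene == "g1"], 1 / 1000)
  expect_gt(tab$effect[tab$gene == "g1"], 0)
  # floor respected everywhere
  expect_true(all(tab$p_value >= 1 / nr))
  expect_true(all(tab$p_value <= 1))
})

test_that("bootstrap on duplicated conditions is symmetric", {
  withr::local_seed(32)
  G <- 60; ncell <- 30
  half <- matrix(stats::rpois(G * 2 * ncell, 4), nrow = G)
  m <- cbind(half, half)  # identical cells copied into both conditions
  dimnames(m) <- list(paste0("g", 1:G), paste0("c", seq_len(4 * ncell)))
  nd <- NestedDesign(colnames(m), rep(paste0("s", 1:4), each = ncell),
                     "b1", rep(c("1", "2"), each = 2 * ncell))
  res <- hierarchicalBootstrap(Matrix::Matrix(m, sparse = TRUE), nd,
                               nBootInitial = 400, nBootEscalated = 2000,
                               cellsPerDraw = 25, seed = 2)
  expect_gte(stats::median(resultTable(res)$p_value), 0.2)
})

test_that("bootstrap excludes single-condition batches and is deterministic", {
  sim <- simulateScenario("dataset", n_genes = 80, cells_per_sample = 15,
                          seed = 33)
  nd <- simDesign(sim)
  # relabel one condition-1 sample into a batch that has no condition-2
  st <- sampleConditions(nd)
  lone <- names(st)[st == "1"][1]
  nd_odd <- NestedDesign(cellIds(nd), unname(cellSamples(nd)),
                         ifelse(unname(cellSamples(nd)) == lone, "bX",
                                unname(sampleBatches(nd)[cellSamples(nd)])),
                         unname(sampleConditions(nd)[cellSamples(nd)]))
  expect_warning(
    res <- hierarchicalBootstrap(simCounts(sim), nd_odd,
                                 nBootInitial = 50, nBootEscalated = 100,
                                 cellsPerDraw = 10, seed = 3),
    "only one condition")
  expect_s4_class(res, "DEResult")
  r1 <- hierarchicalBootstrap(simCounts(sim), nd, nBootInitial = 100,
                              nBootEscalated = 300, cellsPerDraw = 10,
                              seed = 7)
  r2 <- hierarchicalBootstrap(simCounts(sim), nd, nBootInitial = 100,
                              nBootEscalated = 300, cellsPerDraw = 10,
                              seed = 7)
  expect_identical(resultTable(r1), resultTable(r2))
})

test_that("median bootstrap p over DE genes drops as fold changes grow", {
  p_med <- vapply(c(2.0, 13.2), function(fm) {
    sim <- simulateScenario("dataset", n_genes = 300, cells_per_sample = 40,
                            fc_mean = fm, fc_sd = fm / 2.4, seed = 34)
    res <- hierarchicalBootstrap(simCounts(sim), simDesign(sim),
                                 nBootInitial = 300, nBootEscalated = 900,
                                 cellsPerDraw = 30, seed = 4)
    tab <- resultTable(res)
    stats::median(tab$p_value[isDE(sim)[tab$gene]])
  }, numeric(1))
  expect_lte(p_med[2], p_med[1])
})

test_that("Welch t-test matches stats::t.test on toys", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g1", paste0("c", 1:6)))
  nd <- NestedDesign(paste0("c", 1:6), paste0("s", 1:6), "b1",
                     rep(c("1", "2"), each = 3))
  res <- cellTTest(Matrix::Matrix(m, sparse = TRUE), nd,
                   normalization = "raw")
  ref <- stats::t.test(m[1, 1:3], m[1, 4:6])
  expect_equal(resultTable(res)$p_value, ref$p.value)
  expect_equal(resultTable(res)$effect, -3)
  # several random toys against the reference implementation
  withr::local_seed(35)
  for (i in 1:5) {
    x <- matrix(stats::rpois(20, 6), nrow = 2,
                dimnames = list(c("a", "b"), paste0("c", 1:10)))
    ndr <- NestedDesign(paste0("c", 1:10), paste0("s", 1:10), "b1",
                        rep(c("1", "2"), each = 5))
    got <- resultTable(cellTTest(Matrix::Matrix(x, sparse = TRUE), ndr,
                                 normalization = "raw"))
    for (g in c("a", "b")) {
      if (stats::sd(x[g, 1:5]) == 0 && stats::sd(x[g, 6:10]) == 0) next
      ref <- stats::t.test(x[g, 1:5], x[g, 6:10])
      expect_equal(got$p_value[got$gene == g], ref$p.value, tolerance = 1e-10)
    }
  }
  # identical groups: t = 0, p = 1
  mm <- matrix(rep(c(1, 2, 7), 2), nrow = 1,
               dimnames = list("g", paste0("c", 1:6)))
  same <- cellTTest(Matrix::Matrix(mm, sparse = TRUE), nd,
                    normalization = "raw")
  expect_equal(resultTable(same)$p_value, 1)
  # zero variance in both groups, equal means
  flat <- matrix(5, nrow = 1, ncol = 6,
                 dimnames = list("g", paste0("c", 1:6)))
  expect_equal(resultTable(cellTTest(Matrix::Matrix(flat, sparse = TRUE), nd,
                                     normalization = "raw"))$p_value, 1)
})

test_that("cell t-test is anti-conservative on correlated null data", {
  ncs <- simulateScenario("negative_control", n_genes = 500,
                          cells_per_sample = 60, seed = 36,
                          sample_effect_sd = 0.25)
  res <- cellTTest(filterGenes(simCounts(ncs)), simDesign(ncs))
  fpr <- mean(resultTable(res)$p_value <= 0.05)
  expect_gt(fpr, 0.05)
})
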