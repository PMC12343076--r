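# shared fixture builders; everything is generated in code at test time

# tiny valid design: ns samples per condition, nc cells per sample
toyDesign <- function(ns = 2, nc = 2, batches = 1) {
  S <- 2 * ns
  batch <- rep_len(paste0("b", seq_len(batches)), S)
  NestedDesign(
    cell = paste0("c", seq_len(S * nc)),
    sample = rep(paste0("s", seq_len(S)), each = nc),
    batch = rep(batch, each = nc),
    condition = rep(rep(c("1", "2"), each = ns), each = nc))
}

# random sparse count matrix with dimnames
toyCounts <- function(G = 20, C = 8, lambda = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(G * C, lambda), nrow = G,
                dimnames = list(paste0("g", seq_len(G)),
                                paste0("c", seq_len(C))))
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
}

# Gaussian nested generator: y_gij = b_gi + e_gij on a plain matrix,
# used as the independent oracle for ICC recovery
gaussianNested <- function(G, S, n, sigma2_b, nu2_eps, seed = 1) {
  withr::with_seed(seed, {
    b <- matrix(stats::rnorm(G * S, sd = sqrt(sigma2_b)), G, S)
    y <- b[, rep(seq_len(S), each = n)] +
      matrix(stats::rnorm(G * S * n, sd = sqrt(nu2_eps)), G, S * n)
    dimnames(y) <- list(paste0("g", seq_len(G)),
                        paste0("c", seq_len(S * n)))
    y
  })
}

# restrict a design to a subset of cells (test-side re-derivation)
subset_design_for_test <- function(d, cells) {
  cs <- cellSamples(d)[cells]
  NestedDesign(cells, cs, sampleBatches(d)[cs], sampleConditions(d)[cs])
}

gaussianNestedDesign <- function(S, n) {
  NestedDesign(cell = paste0("c", seq_len(S * n)),
               sample = rep(paste0("s", seq_len(S)), each = n),
               batch = "b1",
               condition = rep(rep(c("1", "2"), length.out = S), each = n))
}
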