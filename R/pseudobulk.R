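#' Aggregate single cells into pseudobulk samples
#'
#' Collapses a gene x cell count matrix to a gene x sample matrix by
#' summing (default) or averaging the counts of each sample's cells,
#' making the biological sample the unit of analysis. With `agg = "sum"`
#' total mass is conserved: the pseudobulk matrix sums to the same total
#' as the cell-level counts of the retained samples.
#'
#' @param m gene x cell count matrix.
#' @param design a [NestedDesign-class]; samples with zero cells in `m`
#'   are dropped with a warning.
#' @param agg `"sum"` or `"mean"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"pseudobulk"` and colData columns `condition` and `batch`.
#' @examples
#' sim <- simulateScenario("dataset", n_genes = 40, cells_per_sample = 10,
#'                         seed = 1)
#' pb <- pseudobulk(simCounts(sim), simDesign(sim))
#' dim(pb)
#' @export
pseudobulk <- function(m, design, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  ad <- alignCountsDesign(m, design, strict = TRUE)
  m <- ad$counts; design <- ad$design
  grp <- cellSamples(design)[colnames(m)]
  samples <- sampleIds(design)
  present <- samples %in% grp
  if (!all(present)) {
    warning("dropping sample(s) with zero cells: ",
            paste(samples[!present], collapse = ", "))
    samples <- samples[present]
  }
  ind <- Matrix::sparseMatrix(i = seq_along(grp),
                              j = match(grp, samples),
                              x = 1, dims = c(length(grp), length(samples)))
  vals <- m %*% ind
  if (agg == "mean") {
    vals <- vals %*% Matrix::Diagonal(x = 1 / as.numeric(table(grp)[samples]))
  }
  vals <- as.matrix(vals)
  dimnames(vals) <- list(rownames(m), samples)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(pseudobulk = vals),
    colData = S4Vectors::DataFrame(
      condition = unname(sampleConditions(design)[samples]),
      batch = unname(sampleBatches(design)[samples]),
      row.names = samples))
}

#' Normalize a pseudobulk matrix
#'
#' `"cpm"` scales every column (sample) to a total of one million;
#' `"log1p_cpm"` additionally applies log(1 + x); `"none"` is the
#' identity. Columns with zero total are rejected.
#'
#' @param pb a pseudobulk [SummarizedExperiment::SummarizedExperiment]
#'   from [pseudobulk()].
#' @param mode `"cpm"`, `"log1p_cpm"` or `"none"`.
#' @return The SummarizedExperiment with the assay transformed.
#' @export
normalizePseudobulk <- function(pb, mode = c("cpm", "log1p_cpm", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(pb)
  v <- SummarizedExperiment::assay(pb, "pseudobulk")
  tot <- colSums(v)
  if (any(tot == 0)) stop("pseudobulk column(s) with zero total")
  v <- sweep(v, 2, tot / 1e6, "/")
  if (mode == "log1p_cpm") v <- log1p(v)
  SummarizedExperiment::assay(pb, "pseudobulk") <- v
  pb
}
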