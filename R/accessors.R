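#' @name NestedDesign-accessors
#' @title Accessors for NestedDesign objects
#' @param x a [NestedDesign-class].
#' @description `cellIds` returns the cell identifiers; `cellSamples` the
#'   sample of each cell (named by cell); `sampleIds`, `sampleBatches`,
#'   `sampleConditions` the per-sample attributes (the latter two named by
#'   sample); `conditionLevels` the two condition labels in order of first
#'   appearance; `nSamples`/`nCells` the sizes.
NULL

#' @rdname NestedDesign-accessors
#' @export
cellIds <- function(x) x@cells

#' @rdname NestedDesign-accessors
#' @export
cellSamples <- function(x) stats::setNames(x@cellSample, x@cells)

#' @rdname NestedDesign-accessors
#' @export
sampleIds <- function(x) x@sampleTable$sample

#' @rdname NestedDesign-accessors
#' @export
sampleBatches <- function(x) {
  stats::setNames(as.character(x@sampleTable$batch), x@sampleTable$sample)
}

#' @rdname NestedDesign-accessors
#' @export
sampleConditions <- function(x) {
  stats::setNames(as.character(x@sampleTable$condition), x@sampleTable$sample)
}

#' @rdname NestedDesign-accessors
#' @export
conditionLevels <- function(x) unique(as.character(x@sampleTable$condition))

#' @rdname NestedDesign-accessors
#' @export
nSamples <- function(x) nrow(x@sampleTable)

#' @rdname NestedDesign-accessors
#' @export
nCells <- function(x) length(x@cells)

# per-cell batch / condition, following the cell -> sample mapping
cellBatches <- function(x) unname(sampleBatches(x)[x@cellSample])
cellConditions <- function(x) unname(sampleConditions(x)[x@cellSample])

# subset a design to a set of cells (keeps samples that retain >= 1 cell)
subsetDesign <- function(x, cells) {
  keep <- x@cells %in% cells
  cs <- x@cellSample[keep]
  st <- x@sampleTable[x@sampleTable$sample %in% unique(cs), , drop = FALSE]
  rownames(st) <- NULL
  new("NestedDesign", cells = x@cells[keep], cellSample = cs, sampleTable = st)
}

setMethod("show", "NestedDesign", function(object) {
  st <- object@sampleTable
  cat("NestedDesign with", length(object@cells), "cells,",
      nrow(st), "samples,", length(unique(st$batch)), "batch(es)\n")
  tab <- table(condition = st$condition)
  cat("samples per condition:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", nrow(object@counts), "genes x",
      ncol(object@counts), "cells\n")
  cat("  preset:", object@config$preset %||% "custom",
      "| DE genes:", sum(object@isDE), "\n")
  show(object@design)
})

setMethod("show", "DEResult", function(object) {
  cat("DEResult (", object@method, "): ", nrow(object@table),
      " genes\n", sep = "")
  cat("  genes with p <= 0.05:",
      sum(object@table$p_value <= 0.05, na.rm = TRUE), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @name SimulatedDataset-accessors
#' @title Accessors for SimulatedDataset objects
#' @param x a [SimulatedDataset-class].
#' @description `simCounts` returns the sparse count matrix, `simDesign`
#'   the [NestedDesign-class], `isDE` the logical ground-truth vector
#'   (named by gene), `foldChanges` the applied condition-2 factors
#'   (named by gene), and `batchFactors` the gene x batch factor matrix.
NULL

#' @rdname SimulatedDataset-accessors
#' @export
simCounts <- function(x) x@counts

#' @rdname SimulatedDataset-accessors
#' @export
simDesign <- function(x) x@design

#' @rdname SimulatedDataset-accessors
#' @export
isDE <- function(x) stats::setNames(x@isDE, rownames(x@counts))

#' @rdname SimulatedDataset-accessors
#' @export
foldChanges <- function(x) stats::setNames(x@foldChange, rownames(x@counts))

#' @rdname SimulatedDataset-accessors
#' @export
batchFactors <- function(x) x@batchFactors

#' @name DEResult-accessors
#' @title Accessors for DEResult objects
#' @param x a [DEResult-class].
#' @description `resultTable` returns the per-gene data.frame, `deMethod`
#'   the method label, `nResamplesUsed` the per-gene resampling iteration
#'   counts, and `topGenes` the first `n` gene ids in rank order.
NULL

#' @rdname DEResult-accessors
#' @export
resultTable <- function(x) x@table

#' @rdname DEResult-accessors
#' @export
deMethod <- function(x) x@method

#' @rdname DEResult-accessors
#' @export
nResamplesUsed <- function(x) {
  stats::setNames(x@nResamplesUsed, x@table$gene)
}

#' @rdname DEResult-accessors
#' @param n number of top-ranked genes to return.
#' @export
topGenes <- function(x, n = 100) {
  if (n > nrow(x@table)) {
    stop("n exceeds the number of ranked genes (", nrow(x@table), ")")
  }
  x@table$gene[order(x@table$rank_score)][seq_len(n)]
}
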