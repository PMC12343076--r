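#' @import methods
#' @importFrom Matrix Matrix t rowSums colSums rowMeans colMeans sparseMatrix readMM writeMM
#' @importFrom stats p.adjust rnorm rlnorm rgamma rnbinom runif quantile median sd var
#'   ks.test qlnorm
NULL

#' NestedDesign: the cell -> sample -> (batch, condition) hierarchy
#'
#' A `NestedDesign` records the two-stage sampling structure of a nested
#' single-cell experiment: every cell belongs to exactly one biological
#' sample, and every sample belongs to exactly one batch and one of two
#' condition groups. The class is the design companion of a gene x cell
#' count matrix and is what makes the sample, not the cell, the unit of
#' replication in downstream tests.
#'
#' @slot cells character vector of unique cell identifiers.
#' @slot cellSample character vector parallel to `cells`: the sample each
#'   cell belongs to.
#' @slot sampleTable data.frame with columns `sample`, `batch`, `condition`
#'   (one row per sample; `condition` has exactly two levels).
#'
#' @section Validity:
#' Cell identifiers must be unique; every cell must map to a sample present
#' in `sampleTable`; every sample maps to exactly one batch and one
#' condition; exactly two condition labels are present and each has at
#' least one sample.
#'
#' @seealso [NestedDesign()] for the user-facing constructor,
#'   [readDesign()] for file input.
#' @export
setClass("NestedDesign",
  representation(
    cells = "character",
    cellSample = "character",
    sampleTable = "data.frame"
  )
)

setValidity("NestedDesign", function(object) {
  msg <- character()
  if (anyDuplicated(object@cells)) {
    msg <- c(msg, "cell identifiers must be unique")
  }
  if (length(object@cells) != length(object@cellSample)) {
    msg <- c(msg, "cells and cellSample must have equal length")
  }
  st <- object@sampleTable
  if (!all(c("sample", "batch", "condition") %in% colnames(st))) {
    msg <- c(msg, "sampleTable needs columns sample, batch, condition")
  } else {
    if (anyDuplicated(st$sample)) {
      msg <- c(msg, "each sample must appear once in sampleTable (one batch, one condition)")
    }
    if (!all(object@cellSample %in% st$sample)) {
      msg <- c(msg, "every cell must map to a sample present in sampleTable")
    }
    conds <- unique(as.character(st$condition))
    if (length(conds) != 2L) {
      msg <- c(msg, sprintf("exactly two condition labels required, found %d", length(conds)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a NestedDesign
#'
#' @param cell character vector of cell identifiers (one entry per cell).
#' @param sample character vector, parallel to `cell`: sample of each cell.
#' @param batch character vector, parallel to `cell` (constant within each
#'   sample): batch of the cell's sample.
#' @param condition character vector, parallel to `cell` (constant within
#'   each sample): condition group of the cell's sample.
#'
#' @return A [NestedDesign-class] object.
#'
#' @details A sample listed with two different batches or two different
#'   conditions is a design error and is rejected.
#'
#' @examples
#' nd <- NestedDesign(
#'   cell = paste0("c", 1:4),
#'   sample = c("s1", "s1", "s2", "s2"),
#'   batch = "b1",
#'   condition = c("1", "1", "2", "2")
#' )
#' nSamples(nd)
#' @export
NestedDesign <- function(cell, sample, batch, condition) {
  cell <- as.character(cell)
  sample <- as.character(sample)
  n <- length(cell)
  batch <- rep_len(as.character(batch), n)
  condition <- rep_len(as.character(condition), n)
  if (length(sample) != n) {
    stop("cell and sample must have equal length")
  }
  per <- unique(data.frame(sample = sample, batch = batch,
                           condition = condition,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(per$sample)) {
    bad <- unique(per$sample[duplicated(per$sample)])
    stop("sample(s) mapped to more than one batch or condition: ",
         paste(bad, collapse = ", "))
  }
  per <- per[order(match(per$sample, sample)), , drop = FALSE]
  rownames(per) <- NULL
  new("NestedDesign", cells = cell, cellSample = sample, sampleTable = per)
}

#' SimulatedDataset: counts, design and ground truth from the simulator
#'
#' Bundles the output of [simulateScenario()]: the simulated count matrix,
#' the nested design it was generated under, the per-gene differential
#' expression ground truth (which genes are DE and the multiplicative
#' condition-2 fold change actually applied), the per-batch multiplicative
#' factors, and the configuration used.
#'
#' @slot counts sparse gene x cell integer count matrix (`dgCMatrix`).
#' @slot design [NestedDesign-class] for the simulated cells.
#' @slot isDE logical per gene: true differential expression status.
#' @slot foldChange numeric per gene: multiplicative factor applied to the
#'   condition-2 mean (1 for non-DE genes; < 1 for down-regulated genes).
#' @slot batchFactors numeric gene x batch matrix of multiplicative batch
#'   factors (all 1 in single-batch scenarios).
#' @slot config list: the resolved [scenarioConfig()] used.
#' @export
setClass("SimulatedDataset",
  representation(
    counts = "Matrix",
    design = "NestedDesign",
    isDE = "logical",
    foldChange = "numeric",
    batchFactors = "matrix",
    config = "list"
  )
)

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  G <- nrow(object@counts)
  if (length(object@isDE) != G || length(object@foldChange) != G) {
    msg <- c(msg, "isDE and foldChange must have one entry per gene")
  }
  if (ncol(object@counts) != length(object@design@cells)) {
    msg <- c(msg, "counts columns must match design cells")
  }
  if (any(object@foldChange[!object@isDE] != 1)) {
    msg <- c(msg, "non-DE genes must have fold change exactly 1")
  }
  if (any(object@isDE & object@foldChange == 1)) {
    msg <- c(msg, "DE genes must have fold change different from 1")
  }
  if (length(msg)) msg else TRUE
})

#' DEResult: per-gene differential expression test output
#'
#' One row per tested gene with the signed effect, the p-value (NA for
#' rank-only methods), the Benjamini-Hochberg adjusted p-value, and a
#' `rank_score` defining a deterministic total order for top-N selection
#' (ascending p, ties broken by decreasing |effect|, then gene id).
#'
#' @slot table data.frame with columns `gene`, `effect`, `p_value`,
#'   `p_adjusted`, `rank_score`.
#' @slot method character scalar naming the test.
#' @slot nResamplesUsed integer per gene: resampling iterations behind each
#'   p-value (0 for analytic tests).
#' @export
setClass("DEResult",
  representation(
    table = "data.frame",
    method = "character",
    nResamplesUsed = "integer"
  )
)

setValidity("DEResult", function(object) {
  msg <- character()
  need <- c("gene", "effect", "p_value", "p_adjusted", "rank_score")
  if (!all(need %in% colnames(object@table))) {
    msg <- c(msg, paste("table needs columns", paste(need, collapse = ", ")))
  } else {
    p <- object@table$p_value
    ok <- !is.na(p)
    if (any(p[ok] <= 0 | p[ok] > 1)) {
      msg <- c(msg, "p_value must lie in (0, 1]")
    }
    pa <- object@table$p_adjusted
    if (any(!is.na(p) & !is.na(pa) & pa < p - 1e-12)) {
      msg <- c(msg, "p_adjusted must be >= p_value")
    }
    if (anyDuplicated(object@table$rank_score)) {
      msg <- c(msg, "rank_score must define a total order (no ties)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DEResult-class internal constructor used by the test methods.
#' @param gene,effect,p_value,method,n_resamples vectors/scalars assembled
#'   into the result (BH adjustment and rank scores are derived here).
#' @export
DEResult <- function(gene, effect, p_value, method,
                     n_resamples = rep.int(0L, length(gene))) {
  gene <- as.character(gene)
  stopifnot(length(effect) == length(gene), length(p_value) == length(gene))
  p_adj <- rep(NA_real_, length(gene))
  ok <- !is.na(p_value)
  if (any(ok)) p_adj[ok] <- bhAdjust(p_value[ok])
  rank_score <- rankScore(gene, effect, p_value)
  tab <- data.frame(gene = gene, effect = as.numeric(effect),
                    p_value = as.numeric(p_value), p_adjusted = p_adj,
                    rank_score = rank_score, stringsAsFactors = FALSE)
  new("DEResult", table = tab, method = as.character(method)[1],
      nResamplesUsed = as.integer(rep_len(n_resamples, length(gene))))
}

# Deterministic total order: ascending p (NA p means effect-only ranking),
# ties broken by |effect| descending, then lexicographic gene id.
rankScore <- function(gene, effect, p_value) {
  key_p <- if (all(is.na(p_value))) -abs(effect) else p_value
  ord <- order(key_p, -abs(effect), gene, na.last = TRUE)
  score <- integer(length(gene))
  score[ord] <- seq_along(gene)
  score
}
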