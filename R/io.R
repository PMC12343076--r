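#' Read a gene x cell count matrix
#'
#' Reads either a 10x-style Matrix-Market triple (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, optionally gzipped) or a
#' dense CSV with gene rows and cell columns. Entries must be nonnegative
#' integers (UMI counts); gene and cell identifiers must be unique.
#'
#' @param path directory containing the MTX triple, a `.mtx` file, or a
#'   `.csv` file.
#' @param format `"auto"` (infer from `path`), `"mtx"` or `"csv"`.
#' @return A sparse `dgCMatrix` with gene rownames and cell colnames.
#' @seealso [writeCounts()] for the inverse; the pair round-trips values
#'   exactly.
#' @export
readCounts <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "csv"
  }
  m <- if (format == "mtx") readCountsMtx(path) else readCountsCsv(path)
  validateCounts(m)
  m
}

readCountsMtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- firstExisting(path, c("matrix.mtx", "matrix.mtx.gz"))
    feat <- firstExisting(path, c("features.tsv", "features.tsv.gz",
                                  "genes.tsv", "genes.tsv.gz"))
    bc <- firstExisting(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  } else {
    mtx <- path
    d <- dirname(path)
    feat <- firstExisting(d, c("features.tsv", "features.tsv.gz",
                               "genes.tsv", "genes.tsv.gz"))
    bc <- firstExisting(d, c("barcodes.tsv", "barcodes.tsv.gz"))
  }
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- utils::read.table(feat, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(bc, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m)) {
    stop("feature file has ", length(genes), " entries but matrix has ",
         nrow(m), " rows; refusing a silent index shift")
  }
  if (length(cells) != ncol(m)) {
    stop("barcode file has ", length(cells), " entries but matrix has ",
         ncol(m), " columns; refusing a silent index shift")
  }
  dimnames(m) <- list(genes, cells)
  m
}

firstExisting <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = "/"), " found in ", dir)
}

readCountsCsv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as(as.matrix(df), "CsparseMatrix")
}

validateCounts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix needs gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (any(x < 0) || any(x != floor(x)))) {
    stop("counts must be nonnegative integers")
  }
  invisible(m)
}

#' Write a count matrix
#'
#' Writes the 10x-style Matrix-Market triple (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, uncompressed) into a directory, or a dense CSV.
#'
#' @param m gene x cell count matrix (sparse or dense, with dimnames).
#' @param path output directory (`mtx`) or file (`csv`).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(m, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(as(as(m, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    utils::write.csv(as.data.frame(as.matrix(m)), path)
  }
  invisible(path)
}

#' Read a nested design table
#'
#' Reads a CSV/TSV with header columns `cell`, `sample`, `batch`,
#' `condition` into a [NestedDesign-class]. A sample listed under two
#' batches or two conditions is rejected.
#'
#' @param path CSV or TSV file (separator inferred from the extension,
#'   `.tsv`/`.txt` taken as tab).
#' @return A [NestedDesign-class].
#' @export
readDesign <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("cell", "sample", "batch", "condition")
  if (!all(need %in% colnames(df))) {
    stop("design file needs columns ", paste(need, collapse = ", "))
  }
  NestedDesign(df$cell, df$sample, df$batch, df$condition)
}

#' Write a nested design table
#'
#' @param design a [NestedDesign-class].
#' @param path output CSV (or TSV if the extension says so).
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- data.frame(cell = design@cells,
                   sample = design@cellSample,
                   batch = cellBatches(design),
                   condition = cellConditions(design),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that counts and design describe the same cells
#'
#' In strict mode (default) any cell present in only one of the two is an
#' error; in permissive mode the two are intersected with a warning and
#' the subsetted pair is returned.
#'
#' @param m count matrix; @param design [NestedDesign-class].
#' @param strict logical.
#' @return list(counts, design) restricted to the common cells, in the
#'   matrix's column order.
#' @export
alignCountsDesign <- function(m, design, strict = TRUE) {
  mc <- colnames(m)
  dc <- design@cells
  common <- intersect(mc, dc)
  if (length(common) < length(mc) || length(common) < length(dc)) {
    msg <- sprintf("counts and design disagree: %d cells only in counts, %d only in design",
                   length(setdiff(mc, dc)), length(setdiff(dc, mc)))
    if (strict) stop(msg) else warning(msg, "; intersecting")
  }
  if (!length(common)) stop("no cells shared between counts and design")
  keep <- mc[mc %in% common]
  list(counts = m[, keep, drop = FALSE],
       design = subsetDesign(design, keep))
}

#' Read / write DEResult tables
#'
#' TSV with columns `gene`, `effect`, `p_value`, `p_adjusted`,
#' `rank_score`, `method`, `n_resamples_used` — the interchange format
#' that also accepts result tables produced by external methods.
#'
#' @param x a [DEResult-class] (for writing).
#' @param path TSV file.
#' @return `writeDEResult`: `path` invisibly; `readDEResult`: a
#'   [DEResult-class].
#' @export
writeDEResult <- function(x, path) {
  df <- x@table
  df$method <- x@method
  df$n_resamples_used <- x@nResamplesUsed
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResult
#' @export
readDEResult <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "effect", "p_value")
  if (!all(need %in% colnames(df))) {
    stop("result file needs at least columns ", paste(need, collapse = ", "))
  }
  nr <- if ("n_resamples_used" %in% colnames(df)) df$n_resamples_used else 0L
  method <- if ("method" %in% colnames(df)) df$method[1] else "external"
  DEResult(df$gene, df$effect, df$p_value, method, nr)
}
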