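# A count matrix is a plain numeric matrix: genes in rows, cells in columns,
# rownames = gene ids, colnames = cell ids.  validate_counts() enforces the
# invariants every operation in this file assumes.

#' Validate a genes x cells count matrix
#'
#' Checks the container invariants used throughout the package: a numeric
#' matrix with gene identifiers as rownames and unique cell identifiers as
#' colnames, and no negative entries.
#'
#' @param m numeric matrix, genes in rows, cells in columns.
#' @param what label used in error messages.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_counts <- function(m, what = "count matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(colnames(m))) {
    stop(what, " has duplicated cell identifiers")
  }
  if (any(m < 0)) {
    stop(what, " contains negative entries; counts must be non-negative")
  }
  invisible(m)
}

#' Read a genes x cells count matrix
#'
#' Reads either a dense CSV/TSV (first column gene ids, header row cell ids)
#' or a MatrixMarket sparse triplet file with 10x-style sibling files
#' `genes.tsv` (row names) and `barcodes.tsv` (column names) in the same
#' directory.
#'
#' @param path path to the `.csv`/`.tsv` or `.mtx` file.
#' @param format `"csv"` or `"mtx"`.  For `"csv"` the separator is sniffed
#'   from the extension (`.tsv` uses tab).
#' @param transposed logical; set `TRUE` when a dense file stores cells in
#'   rows and genes in columns.
#' @return numeric matrix, genes x cells, with dimnames.
#' @export
read_counts <- function(path, format = c("csv", "mtx"), transposed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "csv") {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (transposed) m <- t(m)
  } else {
    dir <- dirname(path)
    genes_f <- file.path(dir, "genes.tsv")
    cells_f <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_f) || !file.exists(cells_f)) {
      stop("mtx input needs sibling genes.tsv and barcodes.tsv in ", dir)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.table(genes_f, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cells_f, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("dimension mismatch between matrix (", nrow(m), " x ", ncol(m),
           ") and identifier files (", length(genes), " genes, ",
           length(cells), " cells)")
    }
    dimnames(m) <- list(genes, cells)
    if (transposed) m <- t(m)
  }
  validate_counts(m, "input matrix")
  m
}

#' Write a count matrix as CSV
#'
#' @param m genes x cells matrix.
#' @param path output file.
#' @export
write_counts <- function(m, path) {
  validate_counts(m)
  utils::write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}

#' Filter low-quality cells by library size (IQR rule)
#'
#' Computes each cell's library size (total counts) and keeps cells whose
#' library size lies within `[Q25 - IQR, Q75 + IQR]`, where Q25/Q75 are the
#' 25th/75th percentiles (linear-interpolation convention, `stats::quantile`
#' type 7) and IQR = Q75 - Q25.  Cells outside the band are treated as
#' low-quality outliers.
#'
#' @param m genes x cells count matrix.
#' @param verbose print before/after dimensions.
#' @return the matrix restricted to kept cells (column order preserved).
#' @export
filter_cells_iqr <- function(m, verbose = FALSE) {
  validate_counts(m)
  if (ncol(m) < 4) stop("need at least 4 cells for the IQR filter")
  lib <- colSums(m)
  q <- stats::quantile(lib, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- lib >= q[1] - iqr & lib <= q[2] + iqr
  if (!any(keep)) {
    stop("IQR cell filter removed every cell (bounds [",
         q[1] - iqr, ", ", q[2] + iqr, "])")
  }
  if (verbose) {
    message(sprintf(
      "filter_cells_iqr: kept %d/%d cells (library size in [%.1f, %.1f], Q25/Q75 linear interpolation)",
      sum(keep), ncol(m), q[1] - iqr, q[2] + iqr))
  }
  m[, keep, drop = FALSE]
}

#' Remove genes detected in too few cells
#'
#' Drops genes with nonzero expression in at most `min_cells` cells
#' (default 3, i.e. genes expressed in <= 3 cells are removed).
#'
#' @param m genes x cells count matrix.
#' @param min_cells genes expressed in `<= min_cells` cells are removed.
#' @param verbose print before/after dimensions.
#' @return matrix restricted to kept genes.
#' @export
filter_genes <- function(m, min_cells = 3, verbose = FALSE) {
  validate_counts(m)
  ncells <- rowSums(m > 0)
  keep <- ncells > min_cells
  if (!any(keep)) stop("gene filter removed every gene")
  if (verbose) {
    message(sprintf("filter_genes: kept %d/%d genes (expressed in > %d cells)",
                    sum(keep), nrow(m), min_cells))
  }
  m[keep, , drop = FALSE]
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts so that its total equals the median library
#' size across cells, then applies `log1p`.  Identifiers and column order
#' are preserved.
#'
#' @param m filtered genes x cells count matrix.
#' @return normalized matrix, same shape and dimnames.
#' @export
normalize_counts <- function(m) {
  validate_counts(m)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("cell(s) with zero library size: ",
         paste(colnames(m)[lib == 0], collapse = ", "),
         " (should have been filtered)")
  }
  med <- stats::median(lib)
  out <- sweep(m, 2, med / lib, `*`)
  log1p(out)
}

#' Reduce a normalized matrix to the D x n model input
#'
#' Projects cells onto the top `D` principal components when the data are
#' large enough (`n > D` and more than `D` genes); for smaller data sets
#' (where dimensionality exceeds the number of cells) the `D` most variable
#' genes are selected instead.  The `D` retained features are then z-scored
#' across cells; constant features are left at zero.
#'
#' @param m normalized genes x cells matrix.
#' @param D target number of features (default 512, matching the first
#'   autoencoder layer).
#' @param verbose log the path taken.
#' @return list with `values` (D x n matrix, rows z-scored),
#'   `method` (`"pca"` or `"hvg"`), and `cell_ids`.
#' @export
reduce_dims <- function(m, D = 512L, verbose = FALSE) {
  validate_counts(m)
  if (ncol(m) < 2) stop("need at least 2 cells")
  if (D < 2) stop("D must be >= 2")
  n <- ncol(m)
  use_pca <- n > D && nrow(m) > D
  if (use_pca) {
    # PCA on cells-as-observations, per-gene centering only; z-score after.
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = D)
    y <- t(pc$x)                       # D x n
    rownames(y) <- paste0("PC", seq_len(nrow(y)))
    method <- "pca"
  } else {
    if (nrow(m) < D && verbose) {
      message("reduce_dims: fewer than D genes available; using all ",
              nrow(m), " genes")
    }
    v <- apply(m, 1, stats::var)
    top <- order(-v, seq_len(nrow(m)))[seq_len(min(D, nrow(m)))]
    y <- m[sort(top), , drop = FALSE]
    method <- "hvg"
  }
  if (verbose) {
    message(sprintf("reduce_dims: %s path, %d x %d output", method,
                    nrow(y), ncol(y)))
  }
  y <- zscore_rows(y)
  list(values = y, method = method, cell_ids = colnames(m))
}

# z-score each row across columns; constant rows stay 0
zscore_rows <- function(y) {
  mu <- rowMeans(y)
  sdv <- apply(y, 1, stats::sd)
  y <- y - mu
  nz <- sdv > 0
  y[nz, ] <- y[nz, , drop = FALSE] / sdv[nz]
  y[!nz, ] <- 0
  y
}

#' Run the full preprocessing chain
#'
#' IQR cell filter, low-expression gene filter, median library-size
#' normalization with log transform, and reduction to `D` features.
#'
#' @inheritParams reduce_dims
#' @param min_cells passed to [filter_genes()].
#' @param normalize logical; set `FALSE` to skip normalization (the QC
#'   filters always run).
#' @return as [reduce_dims()], plus `counts_filtered` (the filtered,
#'   normalized matrix).
#' @export
preprocess_counts <- function(m, D = 512L, min_cells = 3, normalize = TRUE,
                              verbose = FALSE) {
  m <- filter_cells_iqr(m, verbose = verbose)
  m <- filter_genes(m, min_cells = min_cells, verbose = verbose)
  if (normalize) m <- normalize_counts(m)
  red <- reduce_dims(m, D = D, verbose = verbose)
  red$counts_filtered <- m
  red
}
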