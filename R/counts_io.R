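#' Read a UMI count matrix
#'
#' Reads a gene x cell UMI count matrix either from a 10x-style Matrix Market
#' directory (\code{matrix.mtx} plus \code{genes.tsv}/\code{features.tsv} and
#' \code{barcodes.tsv} sidecars, cellranger v2 or v3 naming) or from a dense
#' tab-delimited file with a header row of cell identifiers and gene
#' identifiers in the first column. Genes are rows and cells are columns
#' throughout the package, matching the indexing \eqn{x_{ij}} (gene i,
#' cell j).
#'
#' Duplicate gene identifiers are disambiguated deterministically with
#' suffixes \code{.1}, \code{.2}, ... in order of appearance.
#'
#' @param path Directory (for \code{mtx_dir}) or file (for \code{dense_tsv}).
#' @param format One of \code{"auto"}, \code{"mtx_dir"}, \code{"dense_tsv"}.
#'   \code{"auto"} picks \code{mtx_dir} when \code{path} is a directory.
#' @return A sparse \code{dgCMatrix} of non-negative integer counts with
#'   unique \code{rownames} (genes) and \code{colnames} (cells).
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input path does not exist: ", path)
  }
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir" else "dense_tsv"
  }
  counts <- if (format == "mtx_dir") read_counts_mtx(path) else read_counts_tsv(path)
  validate_counts(counts)
  counts
}

find_sidecar <- function(path, candidates, what) {
  for (f in candidates) {
    full <- file.path(path, f)
    if (file.exists(full)) return(full)
  }
  stop("missing ", what, " file in ", path,
       " (looked for ", paste(candidates, collapse = ", "), ")")
}

read_counts_mtx <- function(path) {
  mtx_file <- find_sidecar(path, c("matrix.mtx", "matrix.mtx.gz"), "matrix")
  gene_file <- find_sidecar(path, c("genes.tsv", "features.tsv",
                                    "genes.tsv.gz", "features.tsv.gz"), "gene")
  bc_file <- find_sidecar(path, c("barcodes.tsv", "barcodes.tsv.gz"), "barcode")
  m <- Matrix::readMM(mtx_file)
  genes <- utils::read.delim(gene_file, header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc_file, header = FALSE,
                                stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m)) {
    stop("gene file has ", nrow(genes), " rows but matrix has ",
         nrow(m), " rows")
  }
  if (nrow(barcodes) != ncol(m)) {
    stop("barcode file has ", nrow(barcodes), " rows but matrix has ",
         ncol(m), " columns")
  }
  # cellranger features.tsv carries id<TAB>symbol; prefer the symbol column
  gene_ids <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  rownames(m) <- make.unique(as.character(gene_ids), sep = ".")
  colnames(m) <- make.unique(as.character(barcodes[[1]]), sep = ".")
  methods::as(m, "CsparseMatrix")
}

read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("dense count file is empty or has no cell columns: ", path)
  }
  gene_ids <- make.unique(as.character(df[[1]]), sep = ".")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Validate a count matrix
#'
#' Checks the invariants every entry point relies on: non-negative integer
#' entries, and unique gene/cell identifiers matching the dimensions.
#'
#' @param counts Matrix-like object of counts (genes x cells).
#' @return The validated matrix as a \code{dgCMatrix}, invisibly usable.
#' @export
validate_counts <- function(counts) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (any(dim(counts) == 0L)) {
    stop("count matrix is empty (", nrow(counts), " genes x ",
         ncol(counts), " cells)")
  }
  v <- counts@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))) {
    stop("count matrix contains negative, non-integer or non-finite entries")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell identifiers")
  counts
}

#' Write a count matrix as a Matrix Market directory
#'
#' Writes \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv} in the
#' cellranger v2 layout.
#'
#' @param counts Gene x cell count matrix.
#' @param path Output directory, created if needed.
#' @return \code{path}, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  counts <- validate_counts(counts)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(counts), name = rownames(counts)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Filter genes by detection
#'
#' Keeps genes with a nonzero count in at least \code{min_cells} cells. The
#' default of 5 matches the common practice of modeling only genes detected
#' in at least 5 cells.
#'
#' @param counts Gene x cell count matrix.
#' @param min_cells Minimum number of cells with nonzero count (>= 1).
#' @return The filtered count matrix (cell set unchanged).
#' @export
filter_genes <- function(counts, min_cells = 5) {
  counts <- validate_counts(counts)
  if (min_cells < 1) stop("min_cells must be >= 1")
  n_det <- Matrix::rowSums(counts > 0)
  keep <- n_det >= min_cells
  if (!any(keep)) {
    stop("no genes detected in at least ", min_cells,
         " cells; lower min_cells")
  }
  counts[keep, , drop = FALSE]
}

#' Per-cell sequencing depths
#'
#' The depth of cell j is \eqn{m_j = \sum_i x_{ij}}, the total number of UMIs
#' assigned to the cell; it is the sole default covariate of the regression
#' model.
#'
#' @param counts Gene x cell count matrix.
#' @return Named numeric vector of column sums. Cells with zero depth are
#'   reported via a warning; remove them with \code{\link{drop_empty_cells}}
#'   before modeling (log10 of 0 is undefined).
#' @export
compute_depths <- function(counts) {
  m <- Matrix::colSums(counts)
  names(m) <- colnames(counts)
  if (any(m == 0)) {
    warning(sum(m == 0), " cell(s) have zero total UMI and must be removed ",
            "before model fitting")
  }
  m
}

#' Drop cells with zero total UMI
#'
#' @param counts Gene x cell count matrix.
#' @return The matrix restricted to cells with positive depth; warns when
#'   cells are dropped.
#' @export
drop_empty_cells <- function(counts) {
  m <- Matrix::colSums(counts)
  if (any(m == 0)) {
    warning("dropping ", sum(m == 0), " cell(s) with zero total UMI")
    counts <- counts[, m > 0, drop = FALSE]
  }
  counts
}

#' Geometric mean of a count vector
#'
#' Computed as \code{exp(mean(log(x + eps))) - eps}. The pseudo-offset
#' \code{eps} avoids log(0); the default is 1. Relative to the arithmetic
#' mean, the geometric mean damps the influence of outlier cells and respects
#' the exponential character of count distributions; it is the abscissa for
#' all parameter regularization and gene binning in this package.
#'
#' @param x Non-negative count vector.
#' @param eps Positive pseudo-offset added before the log.
#' @return Scalar geometric mean; 0 exactly when \code{x} is all zero.
#' @export
geometric_mean <- function(x, eps = 1) {
  if (length(x) == 0L) stop("geometric_mean of an empty vector")
  if (eps <= 0) stop("eps must be > 0")
  if (any(x < 0)) stop("counts must be non-negative")
  exp(mean(log(x + eps))) - eps
}

#' Per-gene summary: geometric mean and detection count
#'
#' Computes, for every gene, the geometric mean abundance
#' (\code{\link{geometric_mean}}) and the number of cells with nonzero UMI.
#' Exploits sparsity: for the zero entries \code{log(0 + eps) = log(eps)} is
#' a constant, so only the stored entries are touched.
#'
#' @param counts Gene x cell count matrix.
#' @param eps Pseudo-offset for the geometric mean.
#' @return \code{data.frame} with columns \code{gene_id}, \code{gmean},
#'   \code{n_cells_detected}.
#' @export
gene_summary <- function(counts, eps = 1) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  n <- ncol(counts)
  logx <- counts
  logx@x <- log(counts@x + eps)
  sum_log <- Matrix::rowSums(logx)
  nnz <- Matrix::rowSums(counts != 0)
  gmean <- exp((sum_log + (n - nnz) * log(eps)) / n) - eps
  # all-zero genes are exactly 0 by construction; guard rounding
  gmean[nnz == 0] <- 0
  data.frame(gene_id = rownames(counts),
             gmean = as.numeric(gmean),
             n_cells_detected = as.integer(nnz),
             stringsAsFactors = FALSE)
}

#' Log-normalization baseline
#'
#' The size-factor transformation \code{log(scale_factor * x / m + 1)} that
#' regularized-residual normalization is routinely compared against.
#'
#' @param counts Gene x cell count matrix.
#' @param depths Optional per-cell depths; recomputed when missing.
#' @param scale_factor Library-size scale factor (default 1e4).
#' @return Sparse matrix of log-normalized values, same dimensions.
#' @export
log_normalize <- function(counts, depths = NULL, scale_factor = 1e4) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(depths)) depths <- Matrix::colSums(counts)
  if (any(depths == 0)) stop("cells with zero depth cannot be log-normalized")
  out <- counts %*% Matrix::Diagonal(x = scale_factor / depths)
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}
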