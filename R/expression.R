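#' Construct an expression matrix container
#'
#' The package's basic data container: a dense cells x genes matrix of
#' non-negative counts (or normalized counts) with unique gene and cell
#' identifiers and optional per-cell class labels.
#'
#' @param values numeric matrix, cells in rows, genes in columns; no
#'   negative entries
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column (defaults to `colnames(values)`)
#' @param cell_ids character vector of unique cell identifiers, one per
#'   row (defaults to `rownames(values)`)
#' @param labels optional character vector of per-cell class labels
#' @return an object of class `ExpressionMatrix`: the values matrix with
#'   ids as dimnames and labels attached as an attribute
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values), labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) {
    gene_ids <- paste0("gene_", seq_len(ncol(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell_", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("gene_ids length (", length(gene_ids), ") != number of gene columns (",
         ncol(values), ")")
  }
  if (length(cell_ids) != nrow(values)) {
    stop("cell_ids length (", length(cell_ids), ") != number of cell rows (",
         nrow(values), ")")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup)) {
    stop("duplicate cell ids: ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  if (anyNA(values)) stop("expression values contain NA")
  if (min(values) < 0) stop("expression values contain negative entries")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      stop("labels length (", length(labels),
           ") != number of cells (", nrow(values), ")")
    }
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(values, labels = labels, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("ExpressionMatrix: %d cells x %d genes%s\n", nrow(x), ncol(x),
              if (is.null(lab)) "" else
                sprintf(", %d label classes", length(unique(lab)))))
  invisible(x)
}

gene_ids <- function(x) colnames(x)
cell_ids <- function(x) rownames(x)

#' Per-cell class labels of an expression matrix
#' @param x an `ExpressionMatrix`
#' @return character vector of labels, or `NULL` if unlabeled
#' @export
cell_labels <- function(x) attr(x, "labels")

#' Attach per-cell labels
#' @param x an `ExpressionMatrix`
#' @param value character vector, one label per cell
#' @return the labeled `ExpressionMatrix`
#' @export
`cell_labels<-` <- function(x, value) {
  expression_matrix(unclass(x), labels = value)
}

# Subset rows/columns preserving class and labels.
subset_expression <- function(x, cells = NULL, genes = NULL) {
  lab <- attr(x, "labels")
  m <- unclass(x)
  attr(m, "labels") <- NULL
  if (!is.null(cells)) {
    m <- m[cells, , drop = FALSE]
    if (!is.null(lab)) {
      idx <- if (is.character(cells)) match(cells, rownames(x)) else cells
      lab <- lab[idx]
    }
  }
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  expression_matrix(m, labels = lab)
}

#' Read an expression matrix from disk
#'
#' Supported formats: `csv` / `tsv` (dense, cells x genes, header row of
#' gene ids, first column of cell ids), `mtx_dir` (a directory holding
#' `matrix.mtx`, `genes.tsv`, `barcodes.tsv`; the common genes-as-rows
#' dialect is detected from the companion file lengths and transposed),
#' and `h5ad` (converted through the `anndata` Python library, which must
#' be on the PATH as `python`).
#'
#' @param path file (csv/tsv/h5ad) or directory (mtx_dir)
#' @param format one of `"csv"`, `"tsv"`, `"mtx_dir"`, `"h5ad"`
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx_dir", "h5ad")) {
  format <- match.arg(format)
  switch(format,
    csv = read_expression_delim(path, ","),
    tsv = read_expression_delim(path, "\t"),
    mtx_dir = read_expression_mtx(path),
    h5ad = read_expression_h5ad(path)
  )
}

read_expression_delim <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop("malformed delimited file '", path, "': ",
                             conditionMessage(e))
  )
  expression_matrix(as.matrix(df))
}

read_expression_mtx <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  mtx <- file.path(path, "matrix.mtx")
  gf <- file.path(path, "genes.tsv")
  bf <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, gf, bf)) {
    if (!file.exists(f)) stop("missing companion file: ", f)
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed Matrix Market file '", mtx,
                                         "': ", conditionMessage(e)))
  genes <- utils::read.table(gf, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(bf, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  genes_as_rows <- nrow(m) == length(genes) && ncol(m) == length(cells)
  cells_as_rows <- nrow(m) == length(cells) && ncol(m) == length(genes)
  if (genes_as_rows && cells_as_rows && length(genes) != length(cells)) {
    stop("internal orientation detection error")  # unreachable
  }
  if (genes_as_rows && cells_as_rows) {
    # square matrix with equally long companions: ambiguous by construction
    if (!identical(genes, cells)) {
      stop("ambiguous MTX orientation: matrix is ", nrow(m), " x ", ncol(m),
           " and both companion files have matching lengths")
    }
  }
  if (!genes_as_rows && !cells_as_rows) {
    stop("MTX dimensions ", nrow(m), " x ", ncol(m),
         " match neither genes.tsv (", length(genes),
         ") x barcodes.tsv (", length(cells), ") orientation")
  }
  dense <- as.matrix(m)
  if (genes_as_rows) dense <- t(dense)
  expression_matrix(dense, gene_ids = genes, cell_ids = cells)
}

read_expression_h5ad <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("reading h5ad requires a `python` interpreter with the anndata ",
         "library on the PATH")
  }
  out <- tempfile("h5ad_mtx_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE))
  script <- paste(
    "import sys, anndata, scipy.io, scipy.sparse, numpy as np",
    "ad = anndata.read_h5ad(sys.argv[1])",
    "X = ad.X if scipy.sparse.issparse(ad.X) else scipy.sparse.csr_matrix(np.asarray(ad.X))",
    "scipy.io.mmwrite(sys.argv[2] + '/matrix.mtx', X.T)",
    "open(sys.argv[2] + '/genes.tsv', 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')",
    "open(sys.argv[2] + '/barcodes.tsv', 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop("h5ad conversion failed: ", paste(status, collapse = "\n"))
  }
  read_expression_mtx(out)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()] for the text formats; round trips are
#' entrywise exact for integer counts.
#'
#' @param x an `ExpressionMatrix`
#' @param path output file (csv/tsv) or directory (mtx_dir)
#' @param format one of `"csv"`, `"tsv"`, `"mtx_dir"`
#' @return `path`, invisibly
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = rownames(x), unclass(x),
                     check.names = FALSE, row.names = NULL)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    m <- Matrix::Matrix(t(unclass(x)), sparse = TRUE)  # genes-as-rows dialect
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(colnames(x), file.path(path, "genes.tsv"))
    writeLines(rownames(x), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read a two-column cell label file
#'
#' @param path TSV with columns `cell_id` and `label` (no header required;
#'   a header line is detected and skipped)
#' @return named character vector of labels, names = cell ids
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("label file must have two tab-separated columns")
  if (identical(tolower(df[1L, 1L]), "cell_id")) df <- df[-1L, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
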