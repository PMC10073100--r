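# Reading expression matrices and per-cell metadata; writing embeddings.
# Internal convention: cells are rows, genes are columns.

#' Construct an expression matrix
#'
#' A thin validated container: a nonnegative `n x d` numeric matrix (cells by
#' genes) with unique cell and gene identifiers. Sparse input
#' (`Matrix::dgCMatrix`) is kept sparse.
#'
#' @param values Numeric matrix or `Matrix` sparse matrix, cells in rows.
#' @param gene_ids Character vector of `d` unique gene identifiers.
#' @param cell_ids Character vector of `n` unique cell identifiers.
#' @param check_counts If `TRUE`, reject negative entries.
#' @return An `expression_matrix` object (list with `values`, `gene_ids`,
#'   `cell_ids`).
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values),
                              check_counts = TRUE) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one cell and one gene")
  if (length(gene_ids) != ncol(values))
    stop(sprintf("%d gene ids for %d gene columns", length(gene_ids), ncol(values)))
  if (length(cell_ids) != nrow(values))
    stop(sprintf("%d cell ids for %d cell rows", length(cell_ids), nrow(values)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (check_counts && min(values) < 0) stop("negative entries in count input")
  rownames(values) <- cell_ids; colnames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (inherits(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports MatrixMarket triplet files (`format = "mtx"`, 1-based indices per
#' the standard) accompanied by plain-text gene and cell name files (one id
#' per line), and dense CSV/TSV with a header row of gene names and cell ids
#' in the first column. On-disk genes-as-rows layouts are handled with
#' `transpose = TRUE`; the returned object always has cells as rows.
#'
#' @param path File path. For MTX, `gene_file`/`cell_file` default to
#'   `<path-dir>/genes.txt` and `<path-dir>/cells.txt`.
#' @param format `"mtx"`, `"csv"` or `"tsv"`; guessed from the extension when
#'   missing.
#' @param transpose Set `TRUE` when the file stores genes as rows.
#' @param gene_file,cell_file Name files for MTX input.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            transpose = FALSE,
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx") {
    M <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e)))
    if (is.null(gene_file)) gene_file <- file.path(dirname(path), "genes.txt")
    if (is.null(cell_file)) cell_file <- file.path(dirname(path), "cells.txt")
    if (!file.exists(gene_file)) stop("gene name file not found: ", gene_file)
    if (!file.exists(cell_file)) stop("cell name file not found: ", cell_file)
    genes <- readLines(gene_file); cells <- readLines(cell_file)
    if (transpose) M <- Matrix::t(M)
    if (length(genes) != ncol(M))
      stop(sprintf("matrix declares %d genes but name file lists %d",
                   ncol(M), length(genes)))
    if (length(cells) != nrow(M))
      stop(sprintf("matrix declares %d cells but name file lists %d",
                   nrow(M), length(cells)))
    expression_matrix(methods::as(M, "CsparseMatrix"), genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    M <- as.matrix(df)
    if (!is.numeric(M)) stop("non-numeric entries in ", path)
    if (transpose) M <- t(M)
    expression_matrix(M)
  }
}

#' Construct a multi-hot batch design
#'
#' One one-hot block per categorical factor, concatenated in the given order,
#' so each cell's row carries exactly one 1 per factor ("multi-hot").
#'
#' @param factors Named list of factor vectors (or a data.frame), one entry
#'   per cell each.
#' @param cell_ids Optional cell identifiers.
#' @return A `batch_design`: list with `encoding` (`n x m` 0/1 matrix),
#'   `factors` (names), `levels` (per-factor level names), `cell_ids`.
#' @export
batch_design <- function(factors, cell_ids = NULL) {
  factors <- as.list(factors)
  if (length(factors) == 0L) stop("at least one batch factor is required")
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop("batch factors must be named")
  n <- length(factors[[1]])
  blocks <- list(); levels_out <- list()
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (length(f) != n) stop("factor lengths differ")
    if (anyNA(f)) stop("missing value in batch factor '", nm, "'")
    f <- factor(f)
    B <- matrix(0, n, nlevels(f),
                dimnames = list(NULL, paste(nm, levels(f), sep = ":")))
    B[cbind(seq_len(n), as.integer(f))] <- 1
    blocks[[nm]] <- B
    levels_out[[nm]] <- levels(f)
  }
  enc <- do.call(cbind, blocks)
  if (!is.null(cell_ids)) rownames(enc) <- cell_ids
  structure(list(encoding = enc, factors = names(factors),
                 levels = levels_out, cell_ids = cell_ids),
            class = "batch_design")
}

#' @export
print.batch_design <- function(x, ...) {
  cat(sprintf("<batch_design> %d cells, factors: %s\n", nrow(x$encoding),
              paste(sprintf("%s(%d)", x$factors,
                            vapply(x$levels, length, 1L)), collapse = ", ")))
  invisible(x)
}

#' Read per-cell metadata into a batch design
#'
#' @param path CSV/TSV file with a header row.
#' @param factor_columns Character vector of batch factor columns, in the
#'   order their one-hot blocks should be concatenated.
#' @param label_column Optional cell-type label column.
#' @param id_column Optional column of cell ids used to match (and reorder
#'   to) `cell_ids`; when absent, row order must already match.
#' @param cell_ids Optional expected cell identifiers.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return List with `batch` (a [batch_design()]) and `labels` (factor or
#'   `NULL`).
#' @export
read_metadata <- function(path, factor_columns, label_column = NULL,
                          id_column = NULL, cell_ids = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(factor_columns, label_column, id_column), names(df))
  if (length(missing_cols))
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(id_column) && !is.null(cell_ids)) {
    idx <- match(cell_ids, df[[id_column]])
    if (anyNA(idx))
      stop("cell ids not found in metadata: ",
           paste(utils::head(cell_ids[is.na(idx)], 5), collapse = ", "))
    df <- df[idx, , drop = FALSE]
  } else if (!is.null(cell_ids) && nrow(df) != length(cell_ids)) {
    stop("metadata has ", nrow(df), " rows for ", length(cell_ids), " cells")
  }
  bd <- batch_design(df[factor_columns], cell_ids = cell_ids)
  labels <- if (!is.null(label_column)) factor(df[[label_column]]) else NULL
  list(batch = bd, labels = labels)
}

#' Construct an embedding table
#'
#' Coordinates of `n` cells on a latent manifold, with the manifold recorded
#' alongside. Validates the manifold constraints: Poincare rows must lie
#' strictly inside the ball of radius `1/sqrt(K)`; Lorentz rows must satisfy
#' `<x, x>_L = -1` (tolerance `1e-6`) with positive first coordinate.
#'
#' @param coords `n x p` numeric matrix (ambient coordinates).
#' @param manifold A [manifold_spec()].
#' @param cell_ids Cell identifiers.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(coords, manifold, cell_ids = rownames(coords)) {
  coords <- as.matrix(coords)
  stopifnot(inherits(manifold, "manifold_spec"))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(coords)))
  if (length(cell_ids) != nrow(coords)) stop("cell_ids length mismatch")
  if (ncol(coords) != manifold$ambient_dim)
    stop("coordinate dimension does not match the manifold ambient dimension")
  if (manifold$kind == "poincare") {
    if (any(manifold$K * rowSums(coords^2) >= 1))
      stop("Poincare coordinates outside the open ball")
  } else if (manifold$kind == "lorentz") {
    q <- -coords[, 1]^2 + rowSums(coords[, -1, drop = FALSE]^2)
    if (any(abs(q + 1) > 1e-6) || any(coords[, 1] <= 0))
      stop("Lorentz coordinates off the hyperboloid")
  }
  rownames(coords) <- cell_ids
  structure(list(coords = coords, manifold = manifold,
                 cell_ids = as.character(cell_ids)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d cells, %d coords, %s\n",
              nrow(x$coords), ncol(x$coords), x$manifold$kind))
  invisible(x)
}

#' Write an embedding to CSV
#'
#' The manifold kind, curvature and dimension are recorded in `#`-prefixed
#' header comments so that [read_embedding()] round-trips the table exactly.
#' Coordinates are written with full double precision.
#'
#' @param table An [embedding_table()].
#' @param path Output file.
#' @export
write_embedding <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  m <- table$manifold
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# manifold=%s K=%.17g dim=%d", m$kind, m$K, m$dim), con)
  coords <- table$coords
  colnames(coords) <- paste0("z", seq_len(ncol(coords)))
  writeLines(paste(c("cell_id", colnames(coords)), collapse = ","), con)
  body <- apply(coords, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(paste(table$cell_ids, body, sep = ","), con)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path CSV file with the manifold header comment.
#' @return An [embedding_table()].
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
    regexec("^# manifold=(\\w+) K=([0-9.eE+-]+) dim=(\\d+)", first))[[1]]
  if (length(m) != 4L) stop("missing manifold header in ", path)
  spec <- manifold_spec(m[2], K = as.numeric(m[3]), dim = as.integer(m[4]))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  colnames(coords) <- NULL   # plain coordinates, as constructed
  embedding_table(coords, spec, cell_ids = as.character(df[[1]]))
}

#' Write an expression matrix as MatrixMarket triplets
#'
#' Writes `matrix.mtx` (cells as rows) plus `genes.txt` and `cells.txt` next
#' to it.
#'
#' @param X An [expression_matrix()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_expression_mtx <- function(X, dir) {
  stopifnot(inherits(X, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(X$values, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(X$gene_ids, file.path(dir, "genes.txt"))
  writeLines(X$cell_ids, file.path(dir, "cells.txt"))
  invisible(dir)
}
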