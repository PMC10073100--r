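# Preprocessing pipeline: library-size normalization -> log1p -> per-gene
# standardization -> PCA. Statistics are learned once on training data and
# re-applied verbatim to queries, so a frozen model can map new datasets.

#' Fit the preprocessing model
#'
#' Learns, in the order applied: the library-size normalization constant, the
#' log transform flag, per-gene mean/standard deviation (zero deviations are
#' recorded as 1 so constant genes standardize to zero), and a PCA basis of
#' `min(n_pcs, n - 1, d)` components. Every stage can be disabled; with
#' `use_pca = FALSE` the d genes feed the encoder directly.
#'
#' @param X An [expression_matrix()] or bare matrix (cells in rows).
#' @param target_sum Library-size target (default `1e4` counts per cell).
#' @param use_log Apply `log1p` after normalization.
#' @param use_scale Standardize genes with training mean/sd.
#' @param use_pca Project onto principal components.
#' @param n_pcs Number of components requested (default 50).
#' @return A `preprocess_model` storing the reference gene order and all
#'   training statistics.
#' @export
fit_preprocess <- function(X, target_sum = 1e4, use_log = TRUE,
                           use_scale = TRUE, use_pca = TRUE, n_pcs = 50L) {
  M <- .as_dense_values(X)
  if (nrow(M) < 2L) stop("need at least 2 cells to fit preprocessing")
  model <- structure(list(
    reference_genes = colnames(M),
    target_sum = if (is.null(target_sum)) NULL else as.numeric(target_sum),
    use_log = isTRUE(use_log), use_scale = isTRUE(use_scale),
    use_pca = isTRUE(use_pca), n_pcs = as.integer(n_pcs)),
    class = "preprocess_model")
  M <- .pp_normalize(model, M)
  if (model$use_scale) {
    mu <- colMeans(M)
    sd <- apply(M, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    model$gene_mean <- mu; model$gene_sd <- sd
    M <- sweep(sweep(M, 2, mu, "-"), 2, sd, "/")
  }
  if (model$use_pca) {
    k <- min(model$n_pcs, nrow(M) - 1L, ncol(M))
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = k)
    model$pca_center <- pc$center
    model$pca_rotation <- pc$rotation[, seq_len(k), drop = FALSE]
  }
  model
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf(
    "<preprocess_model> %d genes | normalize:%s log:%s scale:%s pca:%s\n",
    length(x$reference_genes),
    if (is.null(x$target_sum)) "off" else format(x$target_sum),
    x$use_log, x$use_scale,
    if (x$use_pca) ncol(x$pca_rotation) else "off"))
  invisible(x)
}

#' Apply a fitted preprocessing model
#'
#' Transforms `X` with the training statistics only; nothing is refit. The
#' gene set must already match `model$reference_genes` (use [align_genes()]
#' first for heterogeneous queries).
#'
#' @param model A [fit_preprocess()] result.
#' @param X An [expression_matrix()] or matrix with the reference genes.
#' @return Dense numeric matrix, `n x n_pcs` (or `n x d` without PCA).
#' @export
apply_preprocess <- function(model, X) {
  stopifnot(inherits(model, "preprocess_model"))
  M <- .as_dense_values(X, allow_vector = TRUE)
  if (ncol(M) != length(model$reference_genes))
    stop("query has ", ncol(M), " genes; model expects ",
         length(model$reference_genes), " (run align_genes first)")
  if (!is.null(colnames(M)) &&
      !identical(colnames(M), model$reference_genes))
    stop("query gene order differs from the reference (run align_genes)")
  M <- .pp_normalize(model, M)
  if (model$use_scale)
    M <- sweep(sweep(M, 2, model$gene_mean, "-"), 2, model$gene_sd, "/")
  if (model$use_pca)
    M <- sweep(M, 2, model$pca_center, "-") %*% model$pca_rotation
  M
}

.pp_normalize <- function(model, M) {
  if (!is.null(model$target_sum)) {
    rs <- rowSums(M)
    rs[rs == 0] <- 1
    M <- M * (model$target_sum / rs)
  }
  if (model$use_log) M <- log1p(M)
  M
}

.as_dense_values <- function(X, allow_vector = FALSE) {
  if (inherits(X, "expression_matrix")) X <- X$values
  if (allow_vector && is.null(dim(X))) X <- matrix(X, nrow = 1)
  as.matrix(X)
}

#' Align a query to a reference gene set
#'
#' Shared genes keep their original values, genes missing from the query are
#' zero-filled, extra query genes are dropped, and the output columns follow
#' the reference order exactly. Zero overlap is an error rather than a silent
#' all-zero mapping.
#'
#' @param reference_genes Character vector of reference gene ids.
#' @param X_query An [expression_matrix()].
#' @return An [expression_matrix()] over `reference_genes`, with attribute
#'   `overlap` giving the number of shared genes.
#' @export
align_genes <- function(reference_genes, X_query) {
  stopifnot(inherits(X_query, "expression_matrix"))
  reference_genes <- as.character(reference_genes)
  idx <- match(reference_genes, X_query$gene_ids)
  overlap <- sum(!is.na(idx))
  if (overlap == 0L)
    stop("no overlap between query genes and the reference gene set")
  Q <- .as_dense_values(X_query)
  out <- matrix(0, nrow(Q), length(reference_genes),
                dimnames = list(rownames(Q), reference_genes))
  keep <- !is.na(idx)
  out[, keep] <- Q[, idx[keep], drop = FALSE]
  res <- expression_matrix(out, reference_genes, X_query$cell_ids,
                           check_counts = FALSE)
  attr(res, "overlap") <- overlap
  res
}
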