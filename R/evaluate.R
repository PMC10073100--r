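# Embedding quality criteria: co-ranking-based Q_local / Q_global
# (scale-independent criteria of Lee & Verleysen), per-batch structure
# preservation, k-NN label transfer and a batch-mixing score.

#' Co-ranking matrix of two distance matrices
#'
#' Ranks are computed per row with the point itself excluded and ties broken
#' by lower index; entry `(k, l)` counts pairs whose high-dimensional rank is
#' `k` and low-dimensional rank is `l`. Every row and column of the result
#' sums to `n`, for a total mass of `n * (n - 1)`.
#'
#' @param D_high,D_low `n x n` distance matrices.
#' @return `(n-1) x (n-1)` integer matrix of class `coranking_matrix`.
#' @export
coranking <- function(D_high, D_low) {
  if (!all(dim(D_high) == dim(D_low))) stop("shape mismatch")
  n <- nrow(D_high)
  if (n < 3L) stop("need at least 3 points")
  C <- matrix(0L, n - 1L, n - 1L)
  for (i in seq_len(n)) {
    rh <- .nn_ranks(D_high[i, ], i)
    rl <- .nn_ranks(D_low[i, ], i)
    C[cbind(rh, rl)] <- C[cbind(rh, rl)] + 1L
  }
  structure(C, class = c("coranking_matrix", "matrix"))
}

# rank of every other point as neighbour of i (1 = nearest), ties by index
.nn_ranks <- function(drow, i) {
  ord <- order(drow[-i])  # stable sort: ties resolved by lower index
  r <- integer(length(ord)); r[ord] <- seq_along(ord)
  r
}

# Q_NX(K) curve from a co-ranking matrix: fraction of each point's K
# high-dimensional neighbours retained among its K low-dimensional ones.
.qnx_curve <- function(C) {
  n <- nrow(C) + 1L
  cs <- apply(apply(C, 1L, cumsum), 1L, cumsum)  # cs[K,K] = sum_{k,l<=K}
  diag(cs) / (seq_len(n - 1L) * n)
}

#' Structure-preservation quality scores
#'
#' Computes the `Q_NX(K)` curve from the co-ranking matrix of
#' high-dimensional (Euclidean) against low-dimensional (manifold metric)
#' distances, splits the neighbourhood scale at
#' `argmax_K [Q_NX(K) - K/(n-1)]`, and averages the curve on each side:
#' `Q_local` is the mean over `K <= split_K`, `Q_global` the mean over
#' `K > split_K`. Both lie in `[0, 1]`; an isometric embedding scores 1/1.
#' Inputs larger than `max_n` cells are subsampled reproducibly.
#'
#' @param X_high High-dimensional coordinates (matrix, cells in rows) —
#'   typically the model's preprocessed input.
#' @param Z_low An [embedding_table()], or a bare matrix (then `manifold`
#'   gives the metric).
#' @param manifold Metric for a bare-matrix `Z_low`; default Euclidean.
#' @param max_n Subsampling cap for the O(n^2) co-ranking (default 3000).
#' @param subsample_seed Seed for the cap.
#' @return List with `Q_local`, `Q_global`, `split_K`, `n`, and the
#'   `Q_NX` curve.
#' @export
quality_scores <- function(X_high, Z_low, manifold = NULL, max_n = 3000L,
                           subsample_seed = 1L) {
  if (inherits(Z_low, "embedding_table")) {
    manifold <- Z_low$manifold
    Z <- Z_low$coords
  } else {
    Z <- as.matrix(Z_low)
    if (is.null(manifold))
      manifold <- manifold_spec("euclidean", dim = ncol(Z))
  }
  X_high <- as.matrix(X_high)
  if (nrow(X_high) != nrow(Z)) stop("cell counts differ")
  n <- nrow(Z)
  if (n < 10L) stop("need at least 10 cells for a meaningful curve")
  if (n > max_n) {
    set.seed(subsample_seed)
    keep <- sort(sample.int(n, max_n))
    X_high <- X_high[keep, , drop = FALSE]
    Z <- Z[keep, , drop = FALSE]
    n <- max_n
  }
  D_high <- sqrt(.pdist2(X_high))
  D_low <- pairwise_distance(manifold, Z)
  C <- coranking(D_high, D_low)
  q <- .qnx_curve(C)
  Ks <- seq_len(n - 1L)
  split_K <- which.max(q - Ks / (n - 1L))
  list(Q_local = mean(q[Ks <= split_K]),
       Q_global = mean(q[Ks > split_K]),
       split_K = split_K, n = n, Q_NX = q)
}

#' Per-batch structure preservation
#'
#' Runs [quality_scores()] within each batch's cells only, comparing the
#' uncorrected high-dimensional input against the final embedding — the
#' protocol for judging whether batch correction preserved each batch's own
#' geometry. Batches smaller than `min_cells` are skipped with a warning.
#'
#' @param X_high High-dimensional input (cells in rows).
#' @param Z_low [embedding_table()] or matrix.
#' @param batch_labels Per-cell batch labels.
#' @param manifold Metric for bare-matrix `Z_low`.
#' @param min_cells Minimum batch size evaluated (default 10).
#' @param ... Passed to [quality_scores()].
#' @return Data frame with one row per evaluated batch: `batch`, `n`,
#'   `Q_local`, `Q_global`, `split_K`; skipped batches appear with `NA`.
#' @export
per_batch_quality <- function(X_high, Z_low, batch_labels, manifold = NULL,
                              min_cells = 10L, ...) {
  Z <- if (inherits(Z_low, "embedding_table")) Z_low$coords else
    as.matrix(Z_low)
  if (inherits(Z_low, "embedding_table") && is.null(manifold))
    manifold <- Z_low$manifold
  batch_labels <- as.factor(batch_labels)
  if (length(batch_labels) != nrow(Z)) stop("label length mismatch")
  res <- lapply(levels(batch_labels), function(lv) {
    sel <- batch_labels == lv
    if (sum(sel) < min_cells) {
      warning("batch '", lv, "' has fewer than ", min_cells,
              " cells; skipped")
      return(data.frame(batch = lv, n = sum(sel), Q_local = NA_real_,
                        Q_global = NA_real_, split_K = NA_integer_))
    }
    qs <- quality_scores(X_high[sel, , drop = FALSE],
                         Z[sel, , drop = FALSE], manifold = manifold, ...)
    data.frame(batch = lv, n = qs$n, Q_local = qs$Q_local,
               Q_global = qs$Q_global, split_K = qs$split_K)
  })
  out <- do.call(rbind, res)
  if (all(is.na(out$Q_local))) stop("all batches below the size threshold")
  out
}

#' k-NN label-transfer accuracy
#'
#' Classifies each test embedding by majority vote over its `k` nearest
#' training embeddings under the manifold metric, breaking vote ties by the
#' smallest mean distance to the tied classes. Test labels never seen in
#' training count as errors unless `drop_unseen = TRUE`.
#'
#' @param Z_train,Z_test Embedding coordinates (matrices or
#'   [embedding_table()]s sharing a manifold).
#' @param labels_train,labels_test Class labels.
#' @param k Neighbour count (default 5).
#' @param manifold Metric; taken from an embedding table when available.
#' @param drop_unseen Drop test cells whose label is absent from training.
#' @return Fraction of correctly classified test cells.
#' @export
knn_transfer_accuracy <- function(Z_train, labels_train, Z_test, labels_test,
                                  k = 5L, manifold = NULL,
                                  drop_unseen = FALSE) {
  if (inherits(Z_train, "embedding_table")) {
    if (is.null(manifold)) manifold <- Z_train$manifold
    Z_train <- Z_train$coords
  }
  if (inherits(Z_test, "embedding_table")) Z_test <- Z_test$coords
  Z_train <- as.matrix(Z_train); Z_test <- as.matrix(Z_test)
  if (is.null(manifold)) manifold <- manifold_spec("euclidean",
                                                   dim = ncol(Z_train))
  labels_train <- as.character(labels_train)
  labels_test <- as.character(labels_test)
  stopifnot(length(labels_train) == nrow(Z_train),
            length(labels_test) == nrow(Z_test), k <= nrow(Z_train))
  if (drop_unseen) {
    keep <- labels_test %in% labels_train
    Z_test <- Z_test[keep, , drop = FALSE]
    labels_test <- labels_test[keep]
  }
  D <- pairwise_distance(manifold, Z_test, Z_train)
  pred <- character(nrow(Z_test))
  for (i in seq_len(nrow(Z_test))) {
    nb <- order(D[i, ])[seq_len(k)]
    votes <- table(labels_train[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      md <- vapply(top, function(cl)
        mean(D[i, nb[labels_train[nb] == cl]]), numeric(1))
      top <- top[which.min(md)]
    }
    pred[i] <- top
  }
  mean(pred == labels_test)
}

#' Leave-one-group-out k-NN accuracy
#'
#' For each group (e.g., patient), trains the k-NN classifier on all other
#' groups' embeddings and tests on the held-out group — the protocol behind
#' the mean leave-one-group-out accuracy used to score batch-invariant
#' models.
#'
#' @param Z Embedding ([embedding_table()] or matrix).
#' @param labels Cell-type labels.
#' @param groups Group assignment (batch factor) per cell.
#' @inheritParams knn_transfer_accuracy
#' @return Named vector of per-group accuracies; the mean is the summary
#'   score.
#' @export
leave_one_group_out_accuracy <- function(Z, labels, groups, k = 5L,
                                         manifold = NULL) {
  if (inherits(Z, "embedding_table")) {
    if (is.null(manifold)) manifold <- Z$manifold
    Z <- Z$coords
  }
  groups <- as.factor(groups)
  vapply(levels(groups), function(g) {
    te <- groups == g
    knn_transfer_accuracy(Z[!te, , drop = FALSE], labels[!te],
                          Z[te, , drop = FALSE], labels[te],
                          k = k, manifold = manifold)
  }, numeric(1))
}

#' Batch-mixing score of an embedding
#'
#' For every cell, the fraction of its `k` nearest neighbours (manifold
#' metric) belonging to a different batch, normalized by the fraction
#' expected under perfect mixing (`(n - n_batch)/(n - 1)`). Near 1 when
#' batches are ideally mixed, near 0 when fully separated; invariant to
#' batch relabeling.
#'
#' @param Z Embedding ([embedding_table()] or matrix).
#' @param batch_labels Batch label per cell (>= 2 distinct values).
#' @param k Neighbour count (default 10).
#' @param manifold Metric for a bare matrix.
#' @return Scalar mixing score.
#' @export
batch_mixing <- function(Z, batch_labels, k = 10L, manifold = NULL) {
  if (inherits(Z, "embedding_table")) {
    if (is.null(manifold)) manifold <- Z$manifold
    Z <- Z$coords
  }
  Z <- as.matrix(Z)
  if (is.null(manifold)) manifold <- manifold_spec("euclidean",
                                                   dim = ncol(Z))
  batch_labels <- as.factor(batch_labels)
  if (nlevels(batch_labels) < 2L) stop("need at least 2 batches")
  n <- nrow(Z)
  stopifnot(length(batch_labels) == n, k < n)
  D <- pairwise_distance(manifold, Z)
  diag(D) <- Inf
  tab <- table(batch_labels)
  ratio <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    obs <- mean(batch_labels[nb] != batch_labels[i])
    expct <- (n - tab[[as.character(batch_labels[i])]]) / (n - 1)
    ratio[i] <- obs / expct
  }
  mean(ratio)
}
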