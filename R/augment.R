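# k-NN input graph and mixup-style augmentation. Training minibatches are
# the sampled cells followed by `a` interpolated copies of each, so row
# `b + (u-1)*b + i` is the u-th augmentation of row `i`.

#' Build an exact k-nearest-neighbour graph
#'
#' Exact Euclidean k-NN per row with the point itself excluded and ties
#' broken deterministically by lower index.
#'
#' @param X Numeric matrix, points in rows (typically preprocessed input).
#' @param k Neighbour count, `1 <= k < nrow(X)`.
#' @return A `neighbor_graph`: list with `k` and the `n x k` integer matrix
#'   `neighbor_indices`.
#' @export
build_knn_graph <- function(X, k = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of points")
  D2 <- .pdist2(X)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])           # stable: ties broken by lower index
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  structure(list(k = k, neighbor_indices = idx, n = n),
            class = "neighbor_graph")
}

#' Mixup augmentation over a neighbour graph
#'
#' For each sampled cell and each of `a` repetitions, draws a neighbour `j`
#' uniformly from its k-NN list and a mixing ratio `r ~ U(0, p_u)`, and emits
#' the convex combinations `(1 - r) x_i + r x_j` and `(1 - r) y_i + r y_j`.
#' The returned block stacks the `b` originals first, then the `a * b`
#' interpolants.
#'
#' @param X Numeric matrix the graph was built on (n x d').
#' @param Y Optional batch-encoding matrix (n x m), interpolated alongside.
#' @param graph A [build_knn_graph()] result on the same `X`.
#' @param batch_indices Row indices of the sampled minibatch.
#' @param a Augmentations per cell (>= 1).
#' @param p_u Upper end of the mixing-ratio distribution, in (0, 1].
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (the trainer seeds once per run).
#' @return An `augmented_batch`: list with `X_aug`, `Y_aug` (or `NULL`),
#'   `source` (for every augmented row, the row of `X_aug` it interpolates
#'   from; originals point to themselves), `r_values`, `b`, `a`.
#' @export
mixup_augment <- function(X, Y = NULL, graph, batch_indices, a = 1L,
                          p_u = 1, seed = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (length(batch_indices) == 0L) stop("empty minibatch")
  if (!(p_u > 0 && p_u <= 1)) stop("p_u must be in (0, 1]")
  a <- as.integer(a)
  if (a < 1L) stop("a must be >= 1")
  if (graph$n != nrow(X)) stop("graph was built on a different matrix")
  if (!is.null(seed)) set.seed(seed)
  b <- length(batch_indices)
  Xb <- X[batch_indices, , drop = FALSE]
  Yb <- if (!is.null(Y)) Y[batch_indices, , drop = FALSE]
  blocksX <- vector("list", a + 1L); blocksX[[1L]] <- Xb
  blocksY <- vector("list", a + 1L); blocksY[[1L]] <- Yb
  r_all <- numeric(0); src <- integer(0)
  for (u in seq_len(a)) {
    nb_col <- sample.int(graph$k, b, replace = TRUE)
    j <- graph$neighbor_indices[cbind(batch_indices, nb_col)]
    r <- stats::runif(b, 0, p_u)
    Xj <- X[j, , drop = FALSE]
    blocksX[[u + 1L]] <- (1 - r) * Xb + r * Xj
    if (!is.null(Y)) blocksY[[u + 1L]] <- (1 - r) * Yb + r * Y[j, , drop = FALSE]
    r_all <- c(r_all, r)
    src <- c(src, seq_len(b))
  }
  structure(list(
    X_aug = do.call(rbind, blocksX),
    Y_aug = if (!is.null(Y)) do.call(rbind, blocksY),
    source = c(seq_len(b), src),
    r_values = r_all, b = b, a = a), class = "augmented_batch")
}

# index pairs (cell, its own augmentation) within an augmented block:
# rows i and b + (u-1)*b + i for u = 1..a
.own_aug_pairs <- function(b, a) {
  i <- rep(seq_len(b), a)
  cbind(i, b + seq_len(a * b))
}
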