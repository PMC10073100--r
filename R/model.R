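# The embedding model: a structure module (d' -> 500 -> 300 -> 100, LeakyReLU
# + batch norm on hidden layers) feeding a visualization module
# (100 -> 300 -> 100 -> latent_dim). Raw latent outputs are mapped onto the
# chosen manifold by the exponential map at the origin, so ordinary Adam
# optimizes all weights. The batch vector enters the loss only, never the
# network input ("batch-invariant" encoder).

#' Model and training configuration
#'
#' Defaults follow the method's typical search-space midpoints: learning rate
#' `1e-3`, batch size 1000, 300 epochs, `nu_vi = 5e-3`, `gamma = 1000`,
#' `beta = 1`, `nu_st = 100`, `p_u = 1`. A good embedding is usually reached
#' well before 300 epochs (around 50-100 on the synthetic fixtures).
#'
#' @param manifold A [manifold_spec()], or a kind string.
#' @param latent_dim Latent dimension (2 or 3) when `manifold` is a string.
#' @param K Curvature magnitude when `manifold` is a string.
#' @param structure_dims Hidden widths of the structure module.
#' @param vis_dims Hidden widths of the visualization module (its input is
#'   the structure embedding).
#' @param learning_rate,batch_size,epochs,seed Optimization controls.
#' @param k_neighbors k for the input k-NN graph.
#' @param n_augment Augmentations per cell (`a`).
#' @param p_u Upper end of the mixing-ratio distribution.
#' @param sim A [similarity_config()].
#' @param target_sum,use_log,use_scale,use_pca,n_pcs Preprocessing options,
#'   passed to [fit_preprocess()] by [dv_fit()].
#' @return A `dv_config` list.
#' @export
dv_config <- function(manifold = "euclidean", latent_dim = 2L, K = 1,
                      structure_dims = c(500L, 300L, 100L),
                      vis_dims = c(300L, 100L),
                      learning_rate = 1e-3, batch_size = 1000L,
                      epochs = 300L, seed = 1L, k_neighbors = 10L,
                      n_augment = 1L, p_u = 1, sim = similarity_config(),
                      target_sum = 1e4, use_log = TRUE, use_scale = TRUE,
                      use_pca = TRUE, n_pcs = 50L) {
  if (!inherits(manifold, "manifold_spec"))
    manifold <- manifold_spec(manifold, K = K, dim = as.integer(latent_dim))
  if (!manifold$dim %in% c(2L, 3L))
    stop("latent dimension must be 2 or 3 for visualization")
  stopifnot(inherits(sim, "similarity_config"), epochs >= 0, batch_size >= 2)
  structure(list(
    manifold = manifold, structure_dims = as.integer(structure_dims),
    vis_dims = as.integer(vis_dims),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), seed = as.integer(seed),
    k_neighbors = as.integer(k_neighbors), n_augment = as.integer(n_augment),
    p_u = p_u, sim = sim,
    target_sum = target_sum, use_log = use_log, use_scale = use_scale,
    use_pca = use_pca, n_pcs = as.integer(n_pcs)), class = "dv_config")
}

#' @export
print.dv_config <- function(x, ...) {
  cat(sprintf(
    "<dv_config> %s dim %d | lr %g, batch %d, %d epochs, seed %d\n",
    x$manifold$kind, x$manifold$dim, x$learning_rate, x$batch_size,
    x$epochs, x$seed))
  cat(sprintf("  nu_st %g, nu_vi %g, gamma %g, beta %g, k %d, a %d, p_u %g\n",
              x$sim$nu_st, x$sim$nu_vi, x$sim$gamma, x$sim$beta,
              x$k_neighbors, x$n_augment, x$p_u))
  invisible(x)
}

#' Build an untrained model
#'
#' Initializes both modules deterministically from the seed. Hidden layers
#' are linear + batch norm + LeakyReLU; the final layer of each module is a
#' bare linear map. The visualization module's last layer is scaled by 0.1
#' at initialization so hyperbolic runs start near the disk centre.
#'
#' @param input_dim Width of the (preprocessed) encoder input.
#' @param config A [dv_config()].
#' @param seed Overrides `config$seed` when given.
#' @return An untrained `dv_model`.
#' @export
build_model <- function(input_dim, config = dv_config(), seed = NULL) {
  stopifnot(inherits(config, "dv_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  sdims <- c(as.integer(input_dim), config$structure_dims)
  vdims <- c(sdims[length(sdims)], config$vis_dims, config$manifold$dim)
  structure(list(
    snet = .make_mlp(sdims),
    vnet = .make_mlp(vdims, final_init_scale = 0.1),
    config = config, manifold = config$manifold,
    input_dim = as.integer(input_dim), preprocess = NULL,
    loss_history = numeric(0), trained = FALSE), class = "dv_model")
}

#' @export
print.dv_model <- function(x, ...) {
  cat(sprintf("<dv_model> %s, input %d, %s; layers %s + %s\n",
              if (x$trained) sprintf("trained (%d epochs)",
                                     length(x$loss_history)) else "untrained",
              x$input_dim, x$manifold$kind,
              paste(x$snet$dims, collapse = "-"),
              paste(x$vnet$dims, collapse = "-")))
  invisible(x)
}

#' Structure and visualization embeddings of input rows
#'
#' Runs both modules in evaluation mode (batch norm uses running statistics,
#' so single rows work) and applies the exponential map at the origin to the
#' raw visualization output.
#'
#' @param model A `dv_model`.
#' @param X_rows Preprocessed input rows (`input_dim` columns).
#' @return List with `Z_st` (structure embedding), `Z_vi` (manifold
#'   coordinates) and `raw` (pre-exponential-map output).
#' @export
forward_embed <- function(model, X_rows) {
  X_rows <- as.matrix(X_rows)
  if (ncol(X_rows) != model$input_dim)
    stop("input has ", ncol(X_rows), " columns; model expects ",
         model$input_dim)
  Z_st <- .mlp_forward(model$snet, X_rows, training = FALSE)$out
  Tt <- .mlp_forward(model$vnet, Z_st, training = FALSE)$out
  list(Z_st = Z_st, Z_vi = .exp_map0_rows(model$manifold, Tt), raw = Tt)
}

# ---- training ----------------------------------------------------------

#' Train the embedding network
#'
#' Per epoch: shuffle cells; per minibatch, draw mixup augmentations over the
#' input k-NN graph, run both modules, build the structure and visualization
#' similarity graphs and take one Adam step on the fuzzy cross-entropy
#' between them. All randomness flows from `config$seed`.
#'
#' @param X Preprocessed input matrix (`n x input_dim`).
#' @param Y Optional multi-hot batch encoding (`n x m` matrix or a
#'   [batch_design()]); used only inside the loss.
#' @param config A [dv_config()].
#' @return A trained `dv_model` with `loss_history` (mean loss per epoch,
#'   scaled by the squared block size so epochs are comparable).
#' @export
dv_train <- function(X, Y = NULL, config = dv_config()) {
  X <- as.matrix(X)
  if (inherits(Y, "batch_design")) Y <- Y$encoding
  n <- nrow(X)
  set.seed(config$seed)
  model <- build_model(ncol(X), config, seed = config$seed)
  if (config$epochs == 0L) return(model)
  graph <- build_knn_graph(X, min(config$k_neighbors, n - 1L))
  # calibrate the structure module's output scale: rescale its final linear
  # layer so the initial structure embedding inherits the input's median
  # pairwise distance. The t-kernel at nu_st then grades neighbourhoods over
  # the data's own distance range from the first step (see the vignette).
  sub <- X[sample.int(n, min(512L, n)), , drop = FALSE]
  fs0 <- .mlp_forward(model$snet, sub, training = TRUE, update_stats = FALSE)
  ut <- upper.tri(diag(nrow(sub)))
  med_st <- stats::median(sqrt(.pdist2(fs0$out))[ut])
  med_in <- stats::median(sqrt(.pdist2(sub))[ut])
  if (med_st > 0 && is.finite(med_in / med_st)) {
    k_fin <- length(model$snet$layers)
    model$snet$layers[[k_fin]]$W <- model$snet$layers[[k_fin]]$W *
      (med_in / med_st)
    model$snet$layers[[k_fin]]$b <- model$snet$layers[[k_fin]]$b *
      (med_in / med_st)
  }
  nets <- list(model$snet, model$vnet)
  state <- .adam_init(nets)
  tstep <- 0L
  history <- numeric(config$epochs)
  b_cfg <- min(config$batch_size, n)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_w <- 0
    for (start in seq(1L, n, by = b_cfg)) {
      idx <- perm[start:min(start + b_cfg - 1L, n)]
      if (length(idx) < 2L) next  # a 1-cell remainder has no pairs
      aug <- mixup_augment(X, Y, graph, idx, a = config$n_augment,
                           p_u = config$p_u)
      step <- .dv_train_step(nets, state, tstep, aug, config)
      nets <- step$nets; state <- step$state; tstep <- step$t
      if (!is.finite(step$loss))
        stop(sprintf(
          "non-finite loss at epoch %d (lr %g); try a smaller learning rate",
          epoch, config$learning_rate))
      m_rows <- nrow(aug$X_aug)
      ep_loss <- ep_loss + step$loss / m_rows^2 * length(idx)
      ep_w <- ep_w + length(idx)
    }
    history[epoch] <- ep_loss / ep_w
  }
  model$snet <- nets[[1]]; model$vnet <- nets[[2]]
  model$loss_history <- history
  model$trained <- TRUE
  model
}

# single optimization step on an augmented block. The O(m^2) per-pair
# arithmetic is fused in C++ (.pair_grads_cpp); BLAS does the rest.
.dv_train_step <- function(nets, state, tstep, aug, config) {
  sim <- config$sim
  spec <- config$manifold
  K <- spec$K
  b <- aug$b
  m <- nrow(aug$X_aug)

  fs <- .mlp_forward(nets[[1]], aug$X_aug, training = TRUE)
  nets[[1]] <- fs$net
  Z_st <- fs$out
  fv <- .mlp_forward(nets[[2]], Z_st, training = TRUE)
  nets[[2]] <- fv$net
  Tt <- fv$out
  Z_vi <- .exp_map0_rows(spec, Tt)

  Gst <- tcrossprod(Z_st)
  gst <- diag(Gst)
  mf <- match(spec$kind, c("euclidean", "poincare", "lorentz")) - 1L
  if (mf == 2L) {
    A <- -tcrossprod(Z_vi[, 1]) + tcrossprod(Z_vi[, -1, drop = FALSE])
    ga <- numeric(0)
    av <- numeric(0)
  } else {
    A <- tcrossprod(Z_vi)
    ga <- diag(A)
    av <- if (mf == 1L) 1 - K * ga else numeric(0)
  }
  if (!is.null(aug$Y_aug) && sim$beta > 0) {
    Gy <- tcrossprod(aug$Y_aug)
    gy <- diag(Gy)
  } else {
    Gy <- matrix(0, 0, 0)
    gy <- numeric(0)
  }

  res <- .pair_grads_cpp(Gst, gst, A, ga, av, Gy, gy,
                         as.integer(aug$source - 1L),
                         b, mf, K, sim$nu_st, sim$nu_vi,
                         normalizing_constant(sim$nu_st),
                         normalizing_constant(sim$nu_vi),
                         sim$gamma, sim$beta, sim$eps,
                         sim$loss_form == "standard_fuzzy_ce",
                         sim$detach_structure, sim$squared_input)

  dZ_st <- if (sim$detach_structure) 0 else
    rowSums(res$Wst) * Z_st - res$Wst %*% Z_st

  if (mf == 0L) {
    dT <- rowSums(res$Wvi) * Z_vi - res$Wvi %*% Z_vi
  } else if (mf == 1L) {
    gZ <- (2 / av) * (rowSums(res$Wvi) * Z_vi - res$Wvi %*% Z_vi) +
      (2 * K / av^2) * res$rn * Z_vi
    dT <- .expmap0_backward(spec, Tt, gZ)
  } else {
    gZ <- res$Wvi %*% Z_vi
    gZ[, 1] <- -gZ[, 1]
    dT <- .expmap0_backward(spec, Tt, gZ)
  }

  bv <- .mlp_backward(nets[[2]], fv$cache, dT)
  bs <- .mlp_backward(nets[[1]], fs$cache, dZ_st + bv$dX)

  tstep <- tstep + 1L
  ad <- .adam_step(nets, list(bs$grads, bv$grads), state, tstep,
                   config$learning_rate)
  list(nets = ad$nets, state = ad$state, t = tstep, loss = res$loss)
}

# dL/dZ for pairwise Euclidean distances; S = dL/dD over ordered pairs
.euclidean_dist_backward <- function(Z, D, S) {
  W <- (S + t(S)) / pmax(D, 1e-12)
  W[D < 1e-12] <- 0
  rowSums(W) * Z - W %*% Z
}

# chain dL/dZ back through the exponential map at the origin: Z = exp_0(T)
.expmap0_backward <- function(spec, Tt, gZ) {
  K <- spec$K
  if (spec$kind == "euclidean") return(gZ)
  r <- sqrt(rowSums(Tt^2))
  if (spec$kind == "poincare") {
    c_ <- sqrt(K)
    s <- ifelse(r < 1e-8, 1 - K * r^2 / 3, tanh(c_ * r) / (c_ * r))
    spr <- ifelse(r < 1e-8, -2 * K / 3,
                  (c_ * r / cosh(c_ * r)^2 - tanh(c_ * r)) / (c_ * r^3))
    s * gZ + (spr * rowSums(Tt * gZ)) * Tt
  } else {
    al <- r / sqrt(K)
    g0 <- gZ[, 1]
    gR <- gZ[, -1, drop = FALSE]
    coef0 <- ifelse(r < 1e-8, 1 / K, sinh(al) / (sqrt(K) * r))
    phi <- ifelse(r < 1e-8, 1 + r^2 / (6 * K), sqrt(K) * sinh(al) / r)
    dphi_r <- ifelse(r < 1e-8, 1 / (3 * K),
                     (r * cosh(al) - sqrt(K) * sinh(al)) / r^3)
    (g0 * coef0) * Tt + phi * gR + (dphi_r * rowSums(Tt * gR)) * Tt
  }
}

# ---- user-facing fit / transform --------------------------------------

#' Fit an embedding model on an expression matrix
#'
#' Runs the full pipeline: preprocessing (fit on this data), k-NN graph,
#' network training, and a final evaluation-mode pass producing the
#' embedding of the training cells.
#'
#' @param X An [expression_matrix()] of raw counts, or a bare numeric matrix
#'   that is used as the (already preprocessed) encoder input directly.
#' @param batch Optional [batch_design()] (or bare 0/1 matrix) for batch
#'   correction.
#' @param config A [dv_config()].
#' @return A trained `dv_model`; `$embedding` holds the training-cell
#'   [embedding_table()] and `$loss_history` the per-epoch loss.
#' @examples
#' sim <- make_clusters(n_cells = 120, n_genes = 60, n_clusters = 3, seed = 1)
#' cfg <- dv_config(epochs = 5, seed = 1, n_pcs = 20)
#' fit <- dv_fit(sim$X, config = cfg)
#' fit$embedding
#' @export
dv_fit <- function(X, batch = NULL, config = dv_config()) {
  if (inherits(X, "expression_matrix")) {
    pp <- fit_preprocess(X, target_sum = config$target_sum,
                         use_log = config$use_log,
                         use_scale = config$use_scale,
                         use_pca = config$use_pca, n_pcs = config$n_pcs)
    Xp <- apply_preprocess(pp, X)
    cell_ids <- X$cell_ids
  } else {
    pp <- NULL
    Xp <- as.matrix(X)
    cell_ids <- rownames(Xp)
  }
  model <- dv_train(Xp, Y = batch, config = config)
  model$preprocess <- pp
  emb <- forward_embed(model, Xp)
  model$embedding <- embedding_table(emb$Z_vi, model$manifold,
                                     cell_ids = cell_ids)
  model$training_input <- Xp
  model
}

#' Map new cells with a trained model
#'
#' Aligns the query genes to the training reference (shared genes kept,
#' missing genes zero-filled, extras dropped), applies the frozen
#' preprocessing statistics and runs the encoder in evaluation mode. Nothing
#' is refit, so heterogeneous new datasets land in the training latent space.
#'
#' @param object A trained `dv_model`.
#' @param newdata An [expression_matrix()] of raw counts (gene ids required),
#'   or a bare matrix of already-preprocessed encoder input.
#' @param ... Unused.
#' @return An [embedding_table()].
#' @export
predict.dv_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_matrix")) {
    if (is.null(object$preprocess))
      stop("model was fit on preprocessed input; pass a bare matrix")
    aligned <- align_genes(object$preprocess$reference_genes, newdata)
    Xp <- apply_preprocess(object$preprocess, aligned)
    cell_ids <- newdata$cell_ids
  } else {
    Xp <- as.matrix(newdata)
    cell_ids <- rownames(Xp)
  }
  emb <- forward_embed(object, Xp)
  embedding_table(emb$Z_vi, object$manifold, cell_ids = cell_ids)
}

#' Save / load a fitted model
#'
#' The archive is a single RDS file holding the network weights, the
#' configuration, the manifold and the preprocessing statistics; no absolute
#' paths are stored, so archives are portable. `load_dv_model()` validates
#' the format version and the presence of every block.
#'
#' @param model A `dv_model`.
#' @param path Archive path.
#' @export
save_dv_model <- function(model, path) {
  stopifnot(inherits(model, "dv_model"))
  obj <- unclass(model)
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dv_model
#' @export
load_dv_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L))
    stop("unsupported model archive version: ",
         format(obj$format_version))
  needed <- c("snet", "vnet", "config", "manifold", "input_dim",
              "preprocess")
  missing <- setdiff(needed, names(obj))
  if (length(missing))
    stop("model archive is missing blocks: ", paste(missing, collapse = ", "))
  obj$format_version <- NULL
  structure(obj, class = "dv_model")
}
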