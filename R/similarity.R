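# Distance-to-similarity conversion and the geometric-structure-preservation
# loss. Two graphs are compared: the structure graph (Euclidean distances of
# the 100-d structure embedding, with cell<->own-augmentation distances
# contracted by gamma) and the visualization graph (manifold distances of the
# latent embedding, with the prior batch-graph term beta * D_E(y_i, y_j)
# added inside the kernel argument).

#' Similarity and loss configuration
#'
#' @param nu_st Degrees of freedom of the t-kernel on the structure graph
#'   (default 100, a near-Gaussian kernel).
#' @param nu_vi Degrees of freedom on the visualization graph (default
#'   `5e-3`; heavy-tailed, the knob that controls how tightly neighbourhoods
#'   are drawn together).
#' @param gamma Local scale-contraction coefficient applied to the distance
#'   between a cell and its own augmentations in the structure graph
#'   (default 1000).
#' @param beta Weight of the batch-graph distance added to the visualization
#'   kernel argument (default 1; 0 disables batch correction).
#' @param eps Clamp applied to similarities before logarithms.
#' @param loss_form `"standard_fuzzy_ce"` (default) or `"as_printed"`; see
#'   [gsp_loss()].
#' @param squared_input If `TRUE` the kernel receives squared distances; by
#'   default the plain distance is used.
#' @param detach_structure If `TRUE`, the structure graph acts as a fixed
#'   per-step target: the loss gradient reaches the structure module only
#'   through the visualization branch, never through `u^st` directly. The
#'   default `FALSE` trains both graphs jointly, which recovers geometry
#'   markedly better (see the methods vignette).
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(nu_st = 100, nu_vi = 5e-3, gamma = 1000,
                              beta = 1,
                              eps = 1e-6,
                              loss_form = c("standard_fuzzy_ce", "as_printed"),
                              squared_input = FALSE,
                              detach_structure = FALSE) {
  loss_form <- match.arg(loss_form)
  stopifnot(nu_st > 0, nu_vi > 0, gamma >= 1, beta >= 0,
            eps > 0, eps < 0.5)
  structure(list(nu_st = nu_st, nu_vi = nu_vi, gamma = gamma, beta = beta,
                 eps = eps, loss_form = loss_form,
                 squared_input = isTRUE(squared_input),
                 detach_structure = isTRUE(detach_structure)),
            class = "similarity_config")
}

#' Normalizing constant of the t-distribution kernel
#'
#' `C_nu = 2*pi * (Gamma((nu+1)/2) / (sqrt(nu*pi) * Gamma(nu/2)))^2`,
#' evaluated through `lgamma` for stability. `C_1 = 2/pi`; `C_nu -> 1` as
#' `nu -> Inf`.
#'
#' @param nu Degrees of freedom, `> 0`.
#' @export
normalizing_constant <- function(nu) {
  if (any(nu <= 0)) stop("nu must be positive")
  2 * pi * exp(2 * (lgamma((nu + 1) / 2) - 0.5 * log(nu * pi) - lgamma(nu / 2)))
}

#' t-distribution similarity kernel
#'
#' `g(D | nu) = C_nu * (1 + D/nu)^(-(nu+1))`: strictly decreasing in the
#' distance `D >= 0`, equal to `C_nu` at `D = 0`.
#'
#' @param D Nonnegative distances (vector or matrix).
#' @param nu Degrees of freedom.
#' @export
t_kernel <- function(D, nu) {
  if (any(nu <= 0)) stop("nu must be positive")
  normalizing_constant(nu) * exp(-(nu + 1) * log1p(D / nu))
}

# d/dD of t_kernel, given the kernel values p at argument D
.t_kernel_grad <- function(p, D, nu) -p * (nu + 1) / (nu + D)

#' Symmetrize directed similarities
#'
#' `u_ij = u_i|j + u_j|i - 2 * u_i|j * u_j|i`: the fuzzy union of the two
#' directed edge memberships, in `[0, 1]` whenever both inputs are.
#'
#' @param u_ij,u_ji Directed similarities in `[0, 1]` (vectors or matrices;
#'   a matrix `u_ij` with `u_ji` missing uses its own transpose).
#' @export
symmetrize <- function(u_ij, u_ji = NULL) {
  if (is.null(u_ji)) {
    if (!is.matrix(u_ij)) stop("u_ji required for non-matrix input")
    u_ji <- t(u_ij)
  }
  u_ij + u_ji - 2 * u_ij * u_ji
}

#' Structure-graph similarities
#'
#' Pairwise Euclidean distances over an augmented block of structure
#' embeddings; distances between a cell and its own augmentations are divided
#' by `gamma` (local scale contraction), then all distances pass through the
#' t-kernel at `nu_st` and are symmetrized. The diagonal is zeroed (self
#' pairs never enter the loss).
#'
#' @param Z_st Structure embeddings, `(a+1)*b x q` matrix.
#' @param b,a Minibatch bookkeeping: `b` originals followed by `a*b`
#'   augmentations (see [mixup_augment()]). `a = 0` means no augmentations.
#' @param cfg A [similarity_config()].
#' @return Symmetric similarity matrix in `[0, 1]` with zero diagonal.
#' @export
structure_similarity <- function(Z_st, b, a = 1L, cfg = similarity_config()) {
  if (cfg$gamma <= 0) stop("gamma must be positive")
  D <- sqrt(.pdist2(as.matrix(Z_st)))
  D <- .contract_own_pairs(D, b, a, cfg$gamma)
  if (cfg$squared_input) D <- D^2
  P <- t_kernel(D, cfg$nu_st)
  U <- symmetrize(P)
  diag(U) <- 0
  U
}

.contract_own_pairs <- function(D, b, a, gamma) {
  if (a >= 1L && gamma != 1) {
    pr <- .own_aug_pairs(b, a)
    D[pr] <- D[pr] / gamma
    D[pr[, 2:1]] <- D[pr[, 2:1]] / gamma
  }
  D
}

#' Visualization-graph similarities
#'
#' Pairwise manifold distances of the latent embedding, plus
#' `beta * D_E(y_i, y_j)` (Euclidean distance of the multi-hot batch rows)
#' added inside the kernel argument, then the t-kernel at `nu_vi` and
#' symmetrization. With `beta = 0` or `Y_aug = NULL` this reduces to the
#' plain kernel of manifold distances.
#'
#' @param Z_vi Latent embedding, ambient coordinates in rows.
#' @param manifold A [manifold_spec()].
#' @param Y_aug Optional batch-encoding rows aligned with `Z_vi`.
#' @param cfg A [similarity_config()].
#' @return Symmetric similarity matrix in `[0, 1]` with zero diagonal.
#' @export
visualization_similarity <- function(Z_vi, manifold, Y_aug = NULL,
                                     cfg = similarity_config()) {
  D <- pairwise_distance(manifold, as.matrix(Z_vi))
  if (!is.null(Y_aug) && cfg$beta > 0)
    D <- D + cfg$beta * sqrt(.pdist2(as.matrix(Y_aug)))
  if (cfg$squared_input) D <- D^2
  P <- t_kernel(D, cfg$nu_vi)
  U <- symmetrize(P)
  diag(U) <- 0
  U
}

#' Geometric-structure-preservation loss
#'
#' Fuzzy cross-entropy between the structure and visualization similarity
#' graphs, summed over ordered pairs `i != j` after clamping both matrices to
#' `[eps, 1 - eps]`. Two forms are provided. `"standard_fuzzy_ce"` (the
#' default used in training) is the standard fuzzy-set cross entropy
#' `u^st log(u^st/u^vi) + (1 - u^st) log((1 - u^st)/(1 - u^vi))`, which is
#' nonnegative and zero iff the clamped graphs agree. `"as_printed"` swaps
#' the membership in the complement term,
#' `u^st log(u^st/u^vi) + (1 - u^vi) log((1 - u^vi)/(1 - u^st))`; it can be
#' negative and its visualization-side gradient does not vanish at
#' `u^vi = u^st` (see the methods vignette), so it is kept for sensitivity
#' analysis rather than as the trainer default.
#'
#' @param U_st,U_vi Similarity matrices of equal shape.
#' @param cfg A [similarity_config()] (supplies `eps` and `loss_form`).
#' @return Scalar loss.
#' @export
gsp_loss <- function(U_st, U_vi, cfg = similarity_config()) {
  if (!all(dim(U_st) == dim(U_vi))) stop("shape mismatch")
  s <- pmin(pmax(U_st, cfg$eps), 1 - cfg$eps)
  v <- pmin(pmax(U_vi, cfg$eps), 1 - cfg$eps)
  term <- if (cfg$loss_form == "standard_fuzzy_ce") {
    s * log(s / v) + (1 - s) * log((1 - s) / (1 - v))
  } else {
    s * log(s / v) + (1 - v) * log((1 - v) / (1 - s))
  }
  if (is.matrix(term)) diag(term) <- 0
  sum(term)
}

# gradients of the loss wrt the clamped similarities; zero outside the clamp
# range (straight-through). Returns list(ds, dv).
.gsp_loss_grad <- function(U_st, U_vi, cfg) {
  s <- pmin(pmax(U_st, cfg$eps), 1 - cfg$eps)
  v <- pmin(pmax(U_vi, cfg$eps), 1 - cfg$eps)
  if (cfg$loss_form == "standard_fuzzy_ce") {
    ds <- log(s / v) - log((1 - s) / (1 - v))
    dv <- -s / v + (1 - s) / (1 - v)
  } else {
    ds <- log(s / v) + 1 + (1 - v) / (1 - s)
    dv <- -s / v - log((1 - v) / (1 - s)) - 1
  }
  ds[U_st < cfg$eps | U_st > 1 - cfg$eps] <- 0
  dv[U_vi < cfg$eps | U_vi > 1 - cfg$eps] <- 0
  if (is.matrix(ds)) { diag(ds) <- 0; diag(dv) <- 0 }
  list(ds = ds, dv = dv)
}

# Backprop from dL/dU (G, over ordered pairs) through symmetrization and the
# t-kernel to dL/dD_kernel_arg. P is the directed kernel matrix, Darg the
# kernel argument matrix.
.similarity_backward <- function(G, P, Darg, nu) {
  dLdP <- (G + t(G)) * (1 - 2 * t(P))
  dLdP * .t_kernel_grad(P, Darg, nu)
}
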