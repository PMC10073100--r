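# Synthetic scRNA-seq-like count data: discrete clusters, branching
# trajectories with known depth, and multilevel batch effects. Cells live on
# a low-dimensional latent manifold that is lifted linearly into gene space;
# counts follow a Poisson-gamma (negative binomial) law with an extra
# dropout mass, reproducing the sparsity regime of droplet data.

.SIM_LATENT_DIM <- 10L
.SIM_BASE_LOGMEAN <- log(20)
.SIM_LOGMEAN_SD <- 0.5
.SIM_NB_SIZE <- 2
.SIM_LIFT_GAIN <- 2.5

# orthonormal lift from latent space to gene space (seeded by caller's RNG)
.sim_lift <- function(n_genes, L = .SIM_LATENT_DIM) {
  .SIM_LIFT_GAIN * t(qr.Q(qr(matrix(stats::rnorm(n_genes * L), n_genes, L))))
}

# NB + dropout sampling from per-cell-per-gene log means
.sim_counts <- function(log_mu, sparsity, size = .SIM_NB_SIZE) {
  n <- nrow(log_mu); d <- ncol(log_mu)
  counts <- matrix(stats::rnbinom(n * d, mu = exp(log_mu), size = size), n, d)
  if (sparsity > 0)
    counts[stats::runif(n * d) < sparsity] <- 0
  counts
}

.sim_dataset <- function(counts, latent, gene_log_means, params, seed,
                         cluster_labels = NULL, branch = NULL, depth = NULL,
                         batch = NULL) {
  n <- nrow(counts)
  X <- expression_matrix(Matrix::Matrix(counts, sparse = TRUE),
                         gene_ids = paste0("g", seq_len(ncol(counts))),
                         cell_ids = paste0("c", seq_len(n)))
  structure(list(X = X, cluster_labels = cluster_labels, branch = branch,
                 depth = depth, batch = batch, latent = latent,
                 gene_log_means = gene_log_means, params = params,
                 seed = seed), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d cells x %d genes (%s)%s\n",
              nrow(x$X$values), ncol(x$X$values),
              if (!is.null(x$depth)) "trajectory" else "clusters",
              if (!is.null(x$batch)) ", with batch factors" else ""))
  invisible(x)
}

#' Simulate clustered count data
#'
#' Cluster centres sit on the vertices of a centred simplex in a
#' 10-dimensional latent space, scaled so that every pair of centres is
#' `separation` apart; cells scatter around their centre with unit isotropic
#' noise, are lifted orthonormally into gene space on top of per-gene base
#' log-means `N(log 20, 0.5)` with a gene-space gain of 2.5 on the latent
#' signal (marker-like log-fold changes), and counts are drawn from a negative binomial
#' (size 2) with an independent dropout mass of `sparsity`. With the default
#' base expression the realized zero fraction tracks `sparsity` closely.
#'
#' @param n_cells,n_genes Dataset shape.
#' @param n_clusters Number of clusters (>= 2), assigned uniformly.
#' @param separation Latent distance between cluster centres (default 10;
#'   with unit within-cluster noise this emulates clearly distinct cell
#'   types, near-perfectly separable in the preprocessed input).
#' @param sparsity Dropout probability in `[0, 1)` (default 0.3).
#' @param seed RNG seed; the dataset is fully reproducible from
#'   `(params, seed)`.
#' @return A `synthetic_dataset`: counts (`$X`), `$cluster_labels`,
#'   ground-truth `$latent`, per-cell-per-gene `$gene_log_means` and the
#'   generator parameters.
#' @export
make_clusters <- function(n_cells, n_genes, n_clusters, separation = 10,
                          sparsity = 0.3, seed = 1L) {
  stopifnot(n_clusters >= 2, sparsity >= 0, sparsity < 1)
  set.seed(seed)
  L <- .SIM_LATENT_DIM
  # centred simplex vertices with unit pairwise distance, scaled
  k <- n_clusters
  V <- diag(1, k)
  V <- V - matrix(colMeans(V), k, k, byrow = TRUE)
  if (k > L + 1L) stop("n_clusters larger than latent dimension + 1")
  B <- qr.Q(qr(matrix(stats::rnorm(L * (k - 1L)), L, k - 1L)))
  centers <- (separation / sqrt(2)) * t(B %*% t(V %*% svd(V)$v[, 1:(k - 1L),
                                                              drop = FALSE]))
  labels <- factor(sample.int(k, n_cells, replace = TRUE),
                   labels = paste0("cluster", seq_len(k)))
  latent <- centers[as.integer(labels), , drop = FALSE] +
    matrix(stats::rnorm(n_cells * L), n_cells, L)
  lift <- .sim_lift(n_genes)
  base <- stats::rnorm(n_genes, .SIM_BASE_LOGMEAN, .SIM_LOGMEAN_SD)
  log_mu <- latent %*% lift + matrix(base, n_cells, n_genes, byrow = TRUE)
  counts <- .sim_counts(log_mu, sparsity)
  .sim_dataset(counts, latent, log_mu,
               params = list(type = "clusters", n_cells = n_cells,
                             n_genes = n_genes, n_clusters = n_clusters,
                             separation = separation, sparsity = sparsity),
               seed = seed, cluster_labels = labels)
}

#' Simulate a branching developmental trajectory
#'
#' Builds a rooted tree in the 10-dimensional latent space. The root sits at
#' the origin and is itself a branch point: level 1 grows `branching_factor`
#' arms in independent random directions (as a zygote-like progenitor fans
#' out into lineages, making the root the hub of the tree), and each
#' subsequent level splits every branch into `branching_factor` children
#' whose directions perturb the parent's. Cells are placed uniformly along
#' each branch with Gaussian latent noise, then lifted to genes and sampled
#' exactly as in [make_clusters()]. The normalized depth (position along the
#' root-to-leaf path, in `[0, 1]`) is the pseudotime ground truth.
#'
#' @param depth_levels Number of branch levels (>= 2).
#' @param branching_factor Children per branch (1 gives a single path).
#' @param cells_per_branch Cells placed on each branch.
#' @param n_genes Gene count.
#' @param noise Latent Gaussian noise around the branch path (default 0.5).
#' @param sparsity Dropout probability (default 0.3).
#' @param seed RNG seed.
#' @return A `synthetic_dataset` with `$branch` ids and `$depth` in
#'   `[0, 1]`.
#' @export
make_tree_trajectory <- function(depth_levels, branching_factor = 2L,
                                 cells_per_branch = 100L, n_genes = 200L,
                                 noise = 0.5, sparsity = 0.3, seed = 1L) {
  stopifnot(depth_levels >= 2, branching_factor >= 1, cells_per_branch >= 1)
  set.seed(seed)
  L <- .SIM_LATENT_DIM
  seg_len <- 6  # latent length of one branch segment
  # breadth-first construction of branch segments; the root branches too
  branches <- list()
  frontier <- list(list(level = 0L, start = rep(0, L), dir = NULL))
  next_id <- 1L
  for (lev in seq_len(depth_levels)) {
    newf <- list()
    for (br in frontier) {
      endp <- if (is.null(br$dir)) br$start else
        br$start + seg_len * br$dir
      for (ch in seq_len(branching_factor)) {
        dir <- if (is.null(br$dir)) .unit(stats::rnorm(L)) else
          .unit(br$dir + 0.9 * stats::rnorm(L))
        nb <- list(id = next_id, level = lev, start = endp, dir = dir)
        branches[[next_id]] <- nb
        newf[[length(newf) + 1L]] <- nb
        next_id <- next_id + 1L
      }
    }
    frontier <- newf
  }
  n <- length(branches) * cells_per_branch
  latent <- matrix(0, n, L)
  branch_id <- integer(n); depth <- numeric(n)
  row <- 1L
  for (br in branches) {
    tpos <- stats::runif(cells_per_branch)
    pts <- matrix(br$start, cells_per_branch, L, byrow = TRUE) +
      outer(tpos, seg_len * br$dir) +
      noise * matrix(stats::rnorm(cells_per_branch * L), cells_per_branch, L)
    rows <- row:(row + cells_per_branch - 1L)
    latent[rows, ] <- pts
    branch_id[rows] <- br$id
    depth[rows] <- (br$level - 1L + tpos) / depth_levels
    row <- row + cells_per_branch
  }
  lift <- .sim_lift(n_genes)
  base <- stats::rnorm(n_genes, .SIM_BASE_LOGMEAN, .SIM_LOGMEAN_SD)
  log_mu <- latent %*% lift + matrix(base, n, n_genes, byrow = TRUE)
  counts <- .sim_counts(log_mu, sparsity)
  .sim_dataset(counts, latent, log_mu,
               params = list(type = "tree", depth_levels = depth_levels,
                             branching_factor = branching_factor,
                             cells_per_branch = cells_per_branch,
                             n_genes = n_genes, noise = noise,
                             sparsity = sparsity),
               seed = seed, branch = factor(branch_id), depth = depth)
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Add multilevel batch effects to a synthetic dataset
#'
#' Each factor assigns its levels to cells independently and uniformly
#' (crossed design). Every level perturbs the latent gene log-means of its
#' cells with a per-gene additive offset `N(0, shift_scale)` and a per-gene
#' multiplicative jitter `exp(N(0, scale_jitter))` before counts are
#' resampled with the original count law, so the batch effect is baked into
#' the observed counts while all ground-truth labels are kept.
#'
#' @param data A `synthetic_dataset`.
#' @param factor_specs List of specs, each a list/vector with `name`,
#'   `n_levels` (>= 2), `shift_scale`, and optional `scale_jitter`
#'   (default 0).
#' @param seed RNG seed for level assignment, effect draws and resampling.
#' @return The dataset with perturbed counts and `$batch` set to the
#'   [batch_design()] over all factors.
#' @export
inject_batch_effects <- function(data, factor_specs, seed = 1L) {
  stopifnot(inherits(data, "synthetic_dataset"), length(factor_specs) >= 1)
  set.seed(seed)
  n <- nrow(data$X$values); d <- ncol(data$X$values)
  log_mu <- data$gene_log_means
  assignments <- list()
  for (fs in factor_specs) {
    fs <- as.list(fs)
    if (is.null(fs$scale_jitter)) fs$scale_jitter <- 0
    n_levels <- as.integer(fs$n_levels)
    if (n_levels < 2L) stop("factor '", fs$name, "' needs >= 2 levels")
    lev <- sample.int(n_levels, n, replace = TRUE)
    for (l in seq_len(n_levels)) {
      sel <- lev == l
      if (!any(sel)) next
      shift <- stats::rnorm(d, 0, as.numeric(fs$shift_scale))
      jitter <- stats::rnorm(d, 0, as.numeric(fs$scale_jitter))
      log_mu[sel, ] <- sweep(log_mu[sel, , drop = FALSE], 2,
                             shift + jitter, "+")
    }
    assignments[[fs$name]] <- factor(paste0(fs$name, lev))
  }
  no_effect <- all(vapply(factor_specs, function(fs) {
    fs <- as.list(fs)
    as.numeric(fs$shift_scale) == 0 &&
      (is.null(fs$scale_jitter) || as.numeric(fs$scale_jitter) == 0)
  }, logical(1)))
  if (!no_effect) {  # zero-effect factors leave the counts untouched
    counts <- .sim_counts(log_mu, data$params$sparsity)
    data$gene_log_means <- log_mu
    data$X <- expression_matrix(Matrix::Matrix(counts, sparse = TRUE),
                                gene_ids = data$X$gene_ids,
                                cell_ids = data$X$cell_ids)
  }
  data$batch <- batch_design(assignments, cell_ids = data$X$cell_ids)
  data$params$batch_factors <- factor_specs
  data
}
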