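# Shared study protocol for the end-to-end recovery checks, with one-time
# caching so several test blocks (and grids) can reuse the same fits.
#
# Protocol constants: the cluster benchmark is make_clusters(600, 200, 4,
# seed 0) with a fixed 450/150 train/test split; the trajectory benchmark is
# make_tree_trajectory(3 levels, branching 2, ~1200 cells, seed 0).
# Training uses batch size 500 (from the method's typical grid) and 100
# epochs for clusters / 50 for trajectories — fitting completes well within
# those budgets at this scale.

.protocol_cache <- new.env(parent = emptyenv())

protocol_memo <- function(key, expr) {
  if (!exists(key, envir = .protocol_cache))
    assign(key, force(expr), envir = .protocol_cache)
  get(key, envir = .protocol_cache)
}

protocol_clusters <- function() {
  protocol_memo("clusters", {
    sim <- make_clusters(600, 200, 4, seed = 0)
    set.seed(100)
    te <- sort(sample.int(600, 150))
    tr <- setdiff(seq_len(600), te)
    list(sim = sim, tr = tr, te = te,
         Xtr = expression_matrix(sim$X$values[tr, ], sim$X$gene_ids,
                                 sim$X$cell_ids[tr]),
         Xte = expression_matrix(sim$X$values[te, ], sim$X$gene_ids,
                                 sim$X$cell_ids[te]))
  })
}

protocol_cluster_fit <- function(seed) {
  protocol_memo(paste0("cluster_fit_", seed), {
    px <- protocol_clusters()
    dv_fit(px$Xtr, config = dv_config(epochs = 100, seed = seed,
                                      batch_size = 500))
  })
}

protocol_tree <- function() {
  protocol_memo("tree", make_tree_trajectory(3, 2, 86, 200, seed = 0))
}

# Spearman correlation between true depth and hyperbolic distance to the
# manifold origin for one trained trajectory model
protocol_tree_rho <- function(kind, seed, gamma = 1000, nu_vi = 5e-3) {
  key <- sprintf("tree_%s_s%d_g%g_n%g", kind, seed, gamma, nu_vi)
  protocol_memo(key, {
    sim <- protocol_tree()
    cfg <- dv_config(manifold = kind, latent_dim = 2, epochs = 50,
                     seed = seed, batch_size = 500,
                     sim = similarity_config(gamma = gamma, nu_vi = nu_vi))
    fit <- dv_fit(sim$X, config = cfg)
    spec <- fit$manifold
    r0 <- pairwise_distance(spec, fit$embedding$coords,
                            matrix(manifold_origin(spec), 1))[, 1]
    cor(sim$depth, r0, method = "spearman")
  })
}

# batch-correction benchmark: returns c(mix, acc) for one (seed, beta)
protocol_batch_run <- function(seed, beta) {
  key <- sprintf("batch_s%d_b%g", seed, beta)
  protocol_memo(key, {
    bsim <- protocol_memo("batch_sim", {
      inject_batch_effects(make_clusters(600, 200, 4, seed = 0),
                           list(list(name = "batch", n_levels = 2,
                                     shift_scale = 2)), seed = 0)
    })
    px <- protocol_clusters()   # same split indices
    blab <- factor(bsim$batch$encoding[, 1])
    fit <- dv_fit(expression_matrix(bsim$X$values[px$tr, ], bsim$X$gene_ids,
                                    bsim$X$cell_ids[px$tr]),
                  batch = batch_design(list(batch = blab[px$tr])),
                  config = dv_config(epochs = 50, seed = seed,
                                     batch_size = 500,
                                     sim = similarity_config(beta = beta)))
    emb_te <- predict(fit, expression_matrix(bsim$X$values[px$te, ],
                                             bsim$X$gene_ids,
                                             bsim$X$cell_ids[px$te]))
    c(mix = batch_mixing(fit$embedding, blab[px$tr], k = 10),
      acc = knn_transfer_accuracy(fit$embedding,
                                  bsim$cluster_labels[px$tr], emb_te,
                                  bsim$cluster_labels[px$te], k = 5))
  })
}
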