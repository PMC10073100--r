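# Network construction, forward embedding, training behaviour, archives.

tiny_clusters <- function(seed = 1) make_clusters(120, 60, 3, seed = seed)

tiny_config <- function(...) {
  dv_config(structure_dims = c(64L, 32L), vis_dims = c(32L),
            n_pcs = 20L, batch_size = 500L, ...)
}

test_that("model construction follows the configured widths and seed", {
  cfg <- dv_config(manifold = "euclidean", latent_dim = 2, seed = 4)
  m <- build_model(50, cfg)
  expect_equal(m$snet$dims, c(50L, 500L, 300L, 100L))
  expect_equal(m$vnet$dims, c(100L, 300L, 100L, 2L))
  m2 <- build_model(50, cfg)
  expect_identical(m$snet$layers, m2$snet$layers)
  m3 <- build_model(50, cfg, seed = 5)
  expect_false(identical(m$snet$layers, m3$snet$layers))
  expect_error(dv_config(latent_dim = 4), "2 or 3")
})

test_that("forward embeddings respect the manifold constraints", {
  for (kind in c("poincare", "lorentz")) {
    cfg <- tiny_config(manifold = kind, latent_dim = 2, seed = 2)
    m <- build_model(20, cfg)
    X <- matrix(rnorm(40 * 20), 40, 20)
    emb <- forward_embed(m, X)
    if (kind == "poincare") {
      expect_true(all(rowSums(emb$Z_vi^2) < 1))
      expect_equal(ncol(emb$Z_vi), 2L)
    } else {
      q <- -emb$Z_vi[, 1]^2 + rowSums(emb$Z_vi[, -1]^2)
      expect_equal(q, rep(-1, 40), tolerance = 1e-9)
      expect_equal(ncol(emb$Z_vi), 3L)  # ambient = latent + 1
    }
    expect_equal(ncol(emb$Z_st), 32L)
    # a single row works in evaluation mode
    one <- forward_embed(m, X[1, , drop = FALSE])
    expect_equal(nrow(one$Z_vi), 1L)
    expect_equal(one$Z_vi[1, ], emb$Z_vi[1, ])
  }
})

test_that("a zeroed final layer sends every cell to the origin", {
  cfg <- tiny_config(manifold = "poincare", seed = 3)
  m <- build_model(10, cfg)
  k <- length(m$vnet$layers)
  m$vnet$layers[[k]]$W[] <- 0
  m$vnet$layers[[k]]$b[] <- 0
  emb <- forward_embed(m, matrix(rnorm(50), 5, 10))
  expect_equal(emb$Z_vi, matrix(0, 5, 2), ignore_attr = TRUE)
  spec <- manifold_spec("poincare", dim = 2)
  expect_equal(pairwise_distance(spec, emb$Z_vi), matrix(0, 5, 5))
})

test_that("training descends, reproduces bit-identically, and can be off", {
  sim <- tiny_clusters()
  cfg <- tiny_config(epochs = 25L, seed = 7)
  fit1 <- dv_fit(sim$X, config = cfg)
  expect_length(fit1$loss_history, 25L)
  expect_lt(mean(tail(fit1$loss_history, 3)),
            mean(head(fit1$loss_history, 3)))
  fit2 <- dv_fit(sim$X, config = cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_identical(fit1$embedding$coords, fit2$embedding$coords)

  cfg0 <- tiny_config(epochs = 0L, seed = 7)
  un <- dv_train(matrix(rnorm(200), 20, 10), config = cfg0)
  expect_false(un$trained)
  expect_length(un$loss_history, 0L)
})

test_that("prediction is invariant to query gene order and reuses stats", {
  sim <- tiny_clusters(2)
  cfg <- tiny_config(epochs = 10L, seed = 1)
  fit <- dv_fit(sim$X, config = cfg)
  M <- as.matrix(sim$X$values)[1:15, ]
  q1 <- expression_matrix(M, sim$X$gene_ids, paste0("q", 1:15))
  perm <- sample(ncol(M))
  q2 <- expression_matrix(M[, perm], sim$X$gene_ids[perm], paste0("q", 1:15))
  expect_equal(predict(fit, q1)$coords, predict(fit, q2)$coords)
  # transform of the training data reproduces the stored embedding
  expect_equal(predict(fit, sim$X)$coords, fit$embedding$coords)
  # disjoint gene sets are refused
  bad <- expression_matrix(M, paste0("other", seq_len(ncol(M))))
  expect_error(predict(fit, bad), "overlap")
})

test_that("model archives round-trip and validate their blocks", {
  sim <- tiny_clusters(3)
  fit <- dv_fit(sim$X, config = tiny_config(epochs = 5L, seed = 9))
  f <- withr::local_tempfile(fileext = ".rds")
  save_dv_model(fit, f)
  back <- load_dv_model(f)
  expect_s3_class(back, "dv_model")
  expect_identical(predict(back, sim$X)$coords,
                   predict(fit, sim$X)$coords)
  # a truncated archive is rejected with a clear message
  obj <- readRDS(f)
  obj$preprocess <- NULL
  f2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(obj, f2)
  expect_error(load_dv_model(f2), "preprocess")
  obj2 <- readRDS(f)
  obj2$format_version <- 99L
  saveRDS(obj2, f2)
  expect_error(load_dv_model(f2), "version")
})

test_that("the batch vector never enters the encoder input", {
  # identical data with and without a batch design gives identical
  # predictions for a fixed seed when beta = 0 (the loss ignores Y too)
  sim <- tiny_clusters(4)
  bd <- batch_design(list(b = rep(c("x", "y"), 60)))
  cfg <- tiny_config(epochs = 8L, seed = 5, sim = similarity_config(beta = 0))
  f1 <- dv_fit(sim$X, batch = bd, config = cfg)
  f2 <- dv_fit(sim$X, batch = NULL, config = cfg)
  expect_identical(f1$embedding$coords, f2$embedding$coords)
})
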