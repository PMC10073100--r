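# Co-ranking quality criteria, k-NN transfer and batch mixing, each checked
# against brute-force oracles on small instances.

test_that("coranking concentrates on the diagonal under rank agreement", {
  set.seed(1)
  X <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(X))
  C <- coranking(D, D)
  expect_equal(sum(diag(C)), sum(C))
  expect_equal(sum(C), 8 * 7)
  expect_equal(unname(rowSums(C)), rep(8, 7))
  expect_equal(unname(colSums(C)), rep(8, 7))
})

test_that("coranking matches brute-force enumeration, incl. reversals", {
  # three collinear points embedded in reversed order
  Dh <- as.matrix(dist(c(0, 1, 3)))
  Dl <- as.matrix(dist(c(3, 1, 0)))
  expect_equal(unclass(coranking(Dh, Dl)), brute_coranking(Dh, Dl),
               ignore_attr = TRUE)
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    Dh <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    Dl <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    expect_equal(unclass(coranking(Dh, Dl)), brute_coranking(Dh, Dl),
                 ignore_attr = TRUE)
  }
})

test_that("quality scores equal the brute-force oracle on 50 instances", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:25, 1)
    X <- matrix(rnorm(n * 5), n)
    Z <- matrix(rnorm(n * 2), n)
    qs <- quality_scores(X, Z)
    bf <- brute_quality(as.matrix(dist(X)), as.matrix(dist(Z)))
    expect_equal(qs$Q_NX, bf$Q_NX)
    expect_equal(qs$split_K, bf$split_K)
    expect_equal(qs$Q_local, bf$Q_local)
    expect_equal(qs$Q_global, bf$Q_global)
  }
})

test_that("isometric embeddings score 1 and noise degrades Q_local", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Z <- X %*% R + 5  # rotation + translation
  qs <- quality_scores(X, Z)
  expect_equal(qs$Q_local, 1)
  expect_equal(qs$Q_global, 1)
  # increasing noise lowers median Q_local over repeated draws
  med_q <- vapply(c(0.05, 2), function(sd_n) {
    median(vapply(1:20, function(s) {
      set.seed(s)
      quality_scores(X, Z + matrix(rnorm(60, 0, sd_n), 30))$Q_local
    }, numeric(1)))
  }, numeric(1))
  expect_gt(med_q[1], med_q[2])
  expect_error(quality_scores(X[1:5, ], Z[1:5, ]), "at least 10")
})

test_that("hyperbolic embeddings are scored in their own metric", {
  set.seed(5)
  X <- matrix(rnorm(100), 20, 5)
  Zb <- t(replicate(20, rand_ball(2, rmax = 0.97)))
  qs_h <- quality_scores(X, embedding_table(Zb, manifold_spec("poincare",
                                                              dim = 2)))
  qs_e <- quality_scores(X, Zb)
  # near the boundary the two metrics rank neighbourhoods differently
  expect_false(isTRUE(all.equal(qs_h$Q_NX, qs_e$Q_NX)))
})

test_that("subsampling caps the co-ranking size reproducibly", {
  set.seed(6)
  X <- matrix(rnorm(120 * 3), 120)
  q1 <- quality_scores(X, X[, 1:2], max_n = 50, subsample_seed = 9)
  q2 <- quality_scores(X, X[, 1:2], max_n = 50, subsample_seed = 9)
  expect_equal(q1$n, 50)
  expect_identical(q1$Q_NX, q2$Q_NX)
})

test_that("kNN transfer accuracy behaves at the edges and matches 1-NN", {
  set.seed(7)
  # separable two-cluster fixture
  Ztr <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
  ltr <- rep(c("a", "b"), each = 20)
  Zte <- rbind(Ztr[3, , drop = FALSE], Ztr[25, , drop = FALSE])
  expect_equal(knn_transfer_accuracy(Ztr, ltr, Zte, c("a", "b"), k = 5), 1)
  # shuffled labels on balanced classes sit near chance
  accs <- vapply(1:30, function(s) {
    set.seed(s)
    knn_transfer_accuracy(Ztr, sample(ltr), Zte <- matrix(rnorm(60, 4), 30),
                          rep(c("a", "b"), 15), k = 5)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * 0.5 / sqrt(30 * 30) * 10)
  # k = 1 equals exhaustive nearest-neighbour classification
  Zte2 <- matrix(rnorm(30 * 2, 4), 30)
  lte <- brute_1nn(Ztr, ltr, Zte2)
  expect_equal(knn_transfer_accuracy(Ztr, ltr, Zte2, lte, k = 1), 1)
  # unseen labels count as errors unless dropped
  expect_equal(knn_transfer_accuracy(Ztr, ltr, Zte2[1:2, ], c("zz", "zz")),
               0)
})

test_that("leave-one-group-out returns one accuracy per group", {
  set.seed(8)
  Z <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  labs <- rep(c("t1", "t2"), each = 30)
  grp <- rep(c("p1", "p2", "p3"), 20)
  acc <- leave_one_group_out_accuracy(Z, labs, grp, k = 5)
  expect_named(acc, c("p1", "p2", "p3"))
  expect_true(all(acc > 0.9))
})

test_that("batch mixing separates the extremes and ignores relabeling", {
  set.seed(9)
  # disjoint half-planes: no mixing
  Zsep <- rbind(matrix(rnorm(100, -10), 50), matrix(rnorm(100, 10), 50))
  b <- rep(c("x", "y"), each = 50)
  expect_lt(batch_mixing(Zsep, b, k = 10), 0.05)
  # random labels on one blob: ideal mixing
  Zmix <- matrix(rnorm(200), 100)
  bm <- batch_mixing(Zmix, sample(b), k = 10)
  expect_gt(bm, 0.8); expect_lt(bm, 1.2)
  # invariant to permuting label names
  b2 <- ifelse(b == "x", "y", "x")
  expect_equal(batch_mixing(Zsep, b, k = 10),
               batch_mixing(Zsep, b2, k = 10))
  expect_error(batch_mixing(Zmix, rep("x", 100)), "2 batches")
})

test_that("per-batch quality evaluates groups independently", {
  set.seed(10)
  X <- matrix(rnorm(40 * 4), 40)
  Z <- X[, 1:2]
  one <- per_batch_quality(X, Z, rep("b1", 40))
  all_q <- quality_scores(X, Z)
  expect_equal(one$Q_local, all_q$Q_local)
  expect_equal(one$Q_global, all_q$Q_global)
  expect_warning(
    res <- per_batch_quality(X, Z, c(rep("big", 35), rep("tiny", 5))),
    "skipped")
  expect_true(is.na(res$Q_local[res$batch == "tiny"]))
  expect_false(is.na(res$Q_local[res$batch == "big"]))
})
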