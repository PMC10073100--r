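# Kernel normalizer, t-kernel, symmetrization and the
# geometric-structure-preservation loss.

test_that("normalizing constant matches closed forms and limits", {
  # Gamma(1) = 1, Gamma(1/2) = sqrt(pi)  =>  C_1 = 2/pi
  expect_equal(normalizing_constant(1), 2 / pi)
  # independent evaluation through gamma() at a non-trivial value
  nu <- 100
  expect_equal(normalizing_constant(nu),
               2 * pi * (gamma((nu + 1) / 2) /
                           (sqrt(nu * pi) * gamma(nu / 2)))^2)
  for (nu in c(1e-3, 1, 10, 100)) {
    C <- normalizing_constant(nu)
    expect_true(C > 0 && C < 1)
  }
  expect_equal(normalizing_constant(1e8), 1, tolerance = 1e-6)
  expect_error(normalizing_constant(0), "positive")
})

test_that("t-kernel values and monotonicity", {
  expect_equal(t_kernel(0, 5), normalizing_constant(5))
  # nu = 1, D = 1: (2/pi) * 2^-2 = 1/(2*pi)
  expect_equal(t_kernel(1, 1), 1 / (2 * pi))
  D <- seq(0, 10, by = 0.25)
  for (nu in c(5e-3, 1, 100)) {
    k <- t_kernel(D, nu)
    expect_true(all(diff(k) < 0))
    expect_true(all(k > 0 & k <= normalizing_constant(nu)))
  }
})

test_that("symmetrization is the fuzzy union with the right endpoints", {
  expect_equal(symmetrize(1, 1), 0)
  expect_equal(symmetrize(0.5, 0.5), 0.5)
  expect_equal(symmetrize(1, 0), 1)
  expect_equal(symmetrize(0, 1), 1)
  set.seed(1)
  u <- runif(500); w <- runif(500)
  s <- symmetrize(u, w)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, symmetrize(w, u))
})

test_that("structure similarities contract only own-augmentation pairs", {
  cfg <- similarity_config(gamma = 10, nu_st = 1)
  # b = 1, a = 1: row 2 is the augmentation of row 1, distance 10
  Z <- rbind(c(0, 0), c(10, 0))
  U <- structure_similarity(Z, b = 1, a = 1, cfg)
  # contracted distance 1 through the kernel, then Eq-style symmetrization
  p <- t_kernel(1, 1)
  expect_equal(U[1, 2], symmetrize(p, p))
  # gamma = 1 leaves distances untouched
  cfg1 <- similarity_config(gamma = 1, nu_st = 1)
  U1 <- structure_similarity(Z, b = 1, a = 1, cfg1)
  p10 <- t_kernel(10, 1)
  expect_equal(U1[1, 2], symmetrize(p10, p10))
  # a block of plain cells (a = 0) is never contracted
  Z3 <- rbind(c(0, 0), c(10, 0), c(0, 3))
  U3 <- structure_similarity(Z3, b = 3, a = 0, cfg)
  expect_equal(U3[1, 2], symmetrize(p10, p10))
  expect_equal(diag(U3), rep(0, 3))
  # identical rows meet at the kernel maximum
  Zs <- rbind(c(1, 1), c(1, 1))
  Us <- structure_similarity(Zs, b = 2, a = 0, cfg)
  pmaxv <- t_kernel(0, 1)
  expect_equal(Us[1, 2], symmetrize(pmaxv, pmaxv))
})

test_that("visualization similarities apply the prior batch graph", {
  spec <- manifold_spec("euclidean", dim = 2)
  Z <- rbind(c(0, 0), c(1, 0), c(0, 1))
  Y <- rbind(c(1, 0), c(1, 0), c(0, 1))
  cfg0 <- similarity_config(beta = 0, nu_vi = 1)
  cfgb <- similarity_config(beta = 2, nu_vi = 1)
  U0 <- visualization_similarity(Z, spec, Y, cfg0)
  p <- t_kernel(1, 1)
  expect_equal(U0[1, 2], symmetrize(p, p))            # beta = 0: plain kernel
  Ub <- visualization_similarity(Z, spec, Y, cfgb)
  expect_equal(Ub[1, 2], U0[1, 2])                    # same batch: unchanged
  expect_lt(Ub[1, 3], U0[1, 3])                       # cross batch: smaller
  # equal embedding distance, different batch term
  expect_lt(Ub[1, 3], Ub[1, 2])
})

test_that("loss forms evaluate to their closed-form spot checks", {
  cfg_std <- similarity_config(loss_form = "standard_fuzzy_ce")
  cfg_pr <- similarity_config(loss_form = "as_printed")
  U <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_equal(gsp_loss(U, U, cfg_std), 0)
  expect_equal(gsp_loss(U, U, cfg_pr), 0)
  # scalar spot checks on a single ordered pair (scalars bypass the
  # diagonal exclusion applied to matrices)
  expect_equal(gsp_loss(0.2, 0.8, cfg_std), 0.2 * log(0.25) + 0.8 * log(4))
  expect_equal(gsp_loss(0.2, 0.8, cfg_pr), 0.2 * log(0.25) + 0.2 * log(0.25))
  # the standard form is nonnegative everywhere
  set.seed(2)
  for (i in 1:200) expect_gte(gsp_loss(runif(1), runif(1), cfg_std), 0)
  expect_error(gsp_loss(matrix(0.5, 2, 2), matrix(0.5, 3, 3)), "shape")
})

test_that("loss gradient moves the visualization graph toward the target", {
  # three embedded points; perturb one pairwise distance and check the sign
  # of the finite-difference derivative under the standard form
  cfg <- similarity_config(loss_form = "standard_fuzzy_ce", nu_vi = 1)
  spec <- manifold_spec("euclidean", dim = 2)
  loss_at <- function(d12) {
    Z <- rbind(c(0, 0), c(d12, 0), c(0, 2))
    U_vi <- visualization_similarity(Z, spec, NULL, cfg)
    gsp_loss(U_target, U_vi, cfg)
  }
  h <- 1e-6
  # target more similar than current: shrinking the distance must help
  Zt <- rbind(c(0, 0), c(0.5, 0), c(0, 2))
  U_target <- visualization_similarity(Zt, spec, NULL, cfg)
  expect_gt((loss_at(1 + h) - loss_at(1 - h)) / (2 * h), 0)
  # target less similar: growing the distance must help
  Zt <- rbind(c(0, 0), c(3, 0), c(0, 2))
  U_target <- visualization_similarity(Zt, spec, NULL, cfg)
  expect_lt((loss_at(1 + h) - loss_at(1 - h)) / (2 * h), 0)
})

test_that("similarity matrices stay symmetric in [0, 1] on random inputs", {
  set.seed(3)
  cfg <- similarity_config()
  for (i in 1:20) {
    Z <- matrix(rnorm(40), 10, 4)
    U <- structure_similarity(Z, b = 5, a = 1, cfg)
    expect_equal(U, t(U))
    expect_true(all(U >= 0 & U <= 1))
  }
})
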