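# Exactness of the manifold primitives: closed-form values, metric axioms,
# the Lorentz-to-Poincare isometry (the module's master oracle) and
# exp-map/distance consistency at the origin.

test_that("euclidean distance matches closed forms and axioms", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3)
    expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))
  }
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("poincare distance agrees with both closed-form expressions", {
  # acosh(5/3) and 2*artanh(0.5) are the same number, ln 3
  expect_equal(poincare_distance(c(0.5, 0), c(0, 0)), log(3))
  expect_equal(poincare_distance(c(0.5, 0), c(0, 0)), 2 * atanh(0.5))
  expect_equal(poincare_distance(c(0.3, -0.2), c(0.3, -0.2)), 0)
  # near-boundary evaluation stays finite and large
  d <- poincare_distance(c(0.99, 0), c(-0.99, 0))
  expect_true(is.finite(d) && d > 8)
  expect_error(poincare_distance(c(1.2, 0), c(0, 0)), "outside")
})

test_that("lorentz inner product and distance follow the model", {
  o <- c(1, 0, 0)
  expect_equal(lorentz_inner(o, o), -1)
  expect_equal(lorentz_inner(c(1, 0, 0), c(0, 1, 0)), 0)
  x <- c(1.2, 0.4, -0.3)
  expect_equal(lorentz_inner(3 * x, o), 3 * lorentz_inner(x, o))
  y <- c(cosh(1), sinh(1), 0)
  expect_equal(lorentz_distance(o, y), 1)
  expect_equal(lorentz_distance(y, y), 0, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:20) {
    a <- rand_hyperboloid(2); b <- rand_hyperboloid(2)
    expect_equal(lorentz_distance(a, b), lorentz_distance(b, a))
  }
  expect_error(lorentz_distance(c(1, 1, 1), o), "hyperboloid")
})

test_that("Moebius addition satisfies the gyrogroup identities", {
  set.seed(3)
  x <- rand_ball(2)
  expect_equal(mobius_add(x, c(0, 0)), x)
  expect_equal(mobius_add(c(0, 0), x), x)
  expect_equal(mobius_add(-x, x), c(0, 0))
  for (i in 1:1000) {
    a <- rand_ball(2); b <- rand_ball(2)
    expect_lt(sum(mobius_add(a, b)^2), 1)
  }
  # the sign-negated variant breaks the left-inverse identity (it can even
  # leave the ball, triggering the boundary clamp)
  set.seed(4)
  a <- rand_ball(2, rmax = 0.8)
  expect_gt(sum(suppressWarnings(
    mobius_add(-a, a, variant = "negated"))^2), 1e-8)
})

test_that("exponential maps land on the manifold with the right distances", {
  eu <- manifold_spec("euclidean", dim = 2)
  expect_equal(exp_map(eu, c(3, 4), base = c(1, 2)), c(4, 6))

  po <- manifold_spec("poincare", K = 1, dim = 2)
  z <- exp_map(po, c(0.5, 0))
  expect_equal(z, c(tanh(0.5), 0))
  # conformal factor at the origin is 2: D(0, exp_0(v)) = 2 |v|
  expect_equal(poincare_distance(z, c(0, 0)), 2 * 0.5)
  expect_equal(exp_map(po, c(0, 0)), c(0, 0))

  lo <- manifold_spec("lorentz", K = 1, dim = 2)
  zl <- exp_map(lo, c(0, 1, 0))
  expect_equal(zl, c(cosh(1), sinh(1), 0))
  expect_equal(lorentz_distance(c(1, 0, 0), zl), 1)
  expect_equal(lorentz_inner(zl, zl), -1, tolerance = 1e-9)
  expect_error(exp_map(lo, c(1, 0, 0)), "orthogonal|norm")

  # Riemannian norm consistency on random tangents
  set.seed(5)
  for (i in 1:50) {
    v <- rnorm(2) * 0.6
    expect_equal(poincare_distance(exp_map(po, v), c(0, 0)),
                 2 * sqrt(sum(v^2)), tolerance = 1e-9)
    vl <- c(0, rnorm(2))
    expect_equal(lorentz_distance(exp_map(lo, vl), c(1, 0, 0)),
                 sqrt(sum(vl^2)), tolerance = 1e-9)
  }
})

test_that("Lorentz -> Poincare projection is the expected isometry", {
  expect_equal(lorentz_to_poincare(c(1, 0, 0)), c(0, 0))
  # sinh(t) / (cosh(t) + 1) = tanh(t/2)
  expect_equal(lorentz_to_poincare(c(cosh(1), sinh(1), 0)),
               c(tanh(0.5), 0))
  set.seed(6)
  for (i in 1:1000) {
    a <- rand_hyperboloid(2); b <- rand_hyperboloid(2)
    expect_equal(poincare_distance(lorentz_to_poincare(a),
                                   lorentz_to_poincare(b)),
                 lorentz_distance(a, b), tolerance = 1e-8)
  }
})

test_that("all three metrics satisfy the triangle inequality", {
  set.seed(7)
  specs <- list(manifold_spec("euclidean", dim = 2),
                manifold_spec("poincare", dim = 2),
                manifold_spec("lorentz", dim = 2))
  draw <- function(kind) {
    switch(kind, euclidean = rnorm(2), poincare = rand_ball(2),
           lorentz = rand_hyperboloid(2))
  }
  for (spec in specs) {
    for (i in 1:300) {
      x <- draw(spec$kind); y <- draw(spec$kind); z <- draw(spec$kind)
      expect_lte(manifold_distance(spec, x, z),
                 manifold_distance(spec, x, y) +
                   manifold_distance(spec, y, z) + 1e-8)
    }
  }
})

test_that("pairwise_distance agrees with the scalar metrics", {
  set.seed(8)
  for (kind in c("euclidean", "poincare", "lorentz")) {
    spec <- manifold_spec(kind, dim = 2)
    pts <- t(replicate(6, switch(kind, euclidean = rnorm(2),
                                 poincare = rand_ball(2),
                                 lorentz = rand_hyperboloid(2))))
    D <- pairwise_distance(spec, pts)
    for (i in 1:6) for (j in 1:6) {
      expect_equal(D[i, j],
                   if (i == j) 0 else
                     manifold_distance(spec, pts[i, ], pts[j, ]),
                   tolerance = 1e-7)
    }
  }
})
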