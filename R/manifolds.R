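# Latent-space geometry: Euclidean space, the Poincare ball and the Lorentz
# (hyperboloid) model of hyperbolic space. All hyperbolic points in this
# package are produced by the exponential map at the manifold origin, so log
# maps and parallel transport are not needed.

#' Describe a latent manifold
#'
#' A `manifold_spec` records the kind of latent space an embedding lives in
#' and, for the hyperbolic kinds, the magnitude `K` of the (negative)
#' curvature `-K`. The Lorentz model represents a `d`-dimensional space by
#' points in `d + 1` ambient coordinates on the upper sheet of the hyperboloid
#' `<x, x>_L = -1`, `x0 > 0`.
#'
#' @param kind One of `"euclidean"`, `"poincare"`, `"lorentz"`.
#' @param K Positive curvature magnitude; ignored for `"euclidean"`.
#' @param dim Intrinsic dimension of the manifold (2 or 3 for visualization).
#' @return An object of class `manifold_spec` with fields `kind`, `K`, `dim`
#'   and `ambient_dim` (`dim + 1` for Lorentz, otherwise `dim`).
#' @examples
#' manifold_spec("poincare", K = 1, dim = 2)
#' @export
manifold_spec <- function(kind = c("euclidean", "poincare", "lorentz"),
                          K = 1, dim = 2L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(K), length(K) == 1L, K > 0)
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  structure(
    list(kind = kind, K = as.numeric(K), dim = dim,
         ambient_dim = if (kind == "lorentz") dim + 1L else dim),
    class = "manifold_spec")
}

#' @export
print.manifold_spec <- function(x, ...) {
  cat(sprintf("<manifold_spec> %s, dim %d%s\n", x$kind, x$dim,
              if (x$kind == "euclidean") "" else sprintf(", curvature -%g", x$K)))
  invisible(x)
}

# numerical guards shared by the hyperbolic formulas
.BALL_EPS <- 1e-5

# guard acosh against arguments pushed below 1 by rounding
.acosh_safe <- function(x) acosh(pmax(x, 1))

#' Euclidean distance between two points
#'
#' @param x,y Numeric vectors of equal length.
#' @return The geodesic (straight-line) distance `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  sqrt(sum((x - y)^2))
}

#' Poincare ball distance
#'
#' Distance on the ball of radius `1/sqrt(K)` with curvature `-K`:
#' `acosh(1 + 2K |x-y|^2 / ((1 - K|x|^2)(1 - K|y|^2))) / sqrt(K)`.
#' Points are required to lie strictly inside the ball; the `acosh` argument
#' is clamped to `>= 1` against rounding.
#'
#' @param x,y Points inside the ball (numeric vectors).
#' @param K Curvature magnitude.
#' @export
poincare_distance <- function(x, y, K = 1) {
  if (length(x) != length(y)) stop("dimension mismatch")
  nx <- K * sum(x^2); ny <- K * sum(y^2)
  if (nx >= 1 || ny >= 1) stop("point outside the open Poincare ball")
  arg <- 1 + 2 * K * sum((x - y)^2) / ((1 - nx) * (1 - ny))
  .acosh_safe(arg) / sqrt(K)
}

#' Lorentzian scalar product
#'
#' `<x, y>_L = -x0*y0 + sum_{i>=1} xi*yi` on ambient Minkowski space.
#'
#' @param x,y Numeric vectors of equal length `>= 2`.
#' @export
lorentz_inner <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  if (length(x) < 2L) stop("Lorentz ambient dimension must be >= 2")
  -x[1] * y[1] + sum(x[-1] * y[-1])
}

.on_hyperboloid <- function(x, tol = 1e-6) {
  abs(lorentz_inner(x, x) + 1) <= tol && x[1] > 0
}

#' Lorentz model distance
#'
#' `sqrt(K) * acosh(-<x, y>_L / K)` for points on the upper hyperboloid sheet
#' (`<x, x>_L = -1`, `x0 > 0`). The `acosh` argument is clamped to `>= 1`.
#'
#' @param x,y Points on the hyperboloid.
#' @param K Curvature magnitude.
#' @param tol Tolerance for the on-manifold check.
#' @export
lorentz_distance <- function(x, y, K = 1, tol = 1e-6) {
  if (length(x) != length(y)) stop("dimension mismatch")
  if (!.on_hyperboloid(x, tol) || !.on_hyperboloid(y, tol))
    stop("input point is not on the hyperboloid (within tolerance)")
  sqrt(K) * .acosh_safe(-lorentz_inner(x, y) / K)
}

#' Moebius addition on the Poincare ball
#'
#' Gyrogroup addition with curvature `-K`. The default sign convention
#' (numerator coefficient `1 + 2K<x,y> + K|y|^2`) satisfies the gyrogroup
#' identities `0 + x = x` and `(-x) + x = 0`; an alternative variant with a
#' negated `K|y|^2` term is kept behind `variant = "negated"` for sensitivity
#' checks, but it breaks the left-inverse identity and is not used internally.
#' Results that land on or outside the boundary through rounding are clamped
#' just inside the ball.
#'
#' @param x,y Points inside the ball.
#' @param K Curvature magnitude.
#' @param variant `"standard"` (default) or `"negated"`.
#' @export
mobius_add <- function(x, y, K = 1, variant = c("standard", "negated")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("dimension mismatch")
  xy <- sum(x * y); nx <- sum(x^2); ny <- sum(y^2)
  sgn <- if (variant == "standard") 1 else -1
  num <- (1 + 2 * K * xy + sgn * K * ny) * x + (1 - K * nx) * y
  den <- 1 + 2 * K * xy + K^2 * nx * ny
  out <- num / den
  r <- sqrt(K * sum(out^2))
  if (r >= 1) {
    warning("Moebius sum on/outside the boundary; clamping inside the ball")
    out <- out * (1 - .BALL_EPS) / r
  }
  out
}

#' Exponential map on a latent manifold
#'
#' Maps a tangent vector `v` at `base` to a manifold point. Euclidean:
#' `base + v`. Poincare: Moebius translation of the ball geodesic
#' `tanh(sqrt(K) * lambda_base * |v| / 2) * v / (sqrt(K) |v|)`. Lorentz:
#' `cosh(|v|_L / sqrt(K)) * base + sqrt(K) * sinh(|v|_L / sqrt(K)) * v / |v|_L`,
#' requiring `<base, v>_L = 0`. `v = 0` returns `base` for every kind.
#'
#' @param spec A [manifold_spec()].
#' @param base Base point (on the manifold); defaults to the origin.
#' @param v Tangent vector (ambient coordinates for Lorentz).
#' @return A point on the manifold.
#' @export
exp_map <- function(spec, v, base = manifold_origin(spec)) {
  stopifnot(inherits(spec, "manifold_spec"))
  K <- spec$K
  switch(spec$kind,
    euclidean = base + v,
    poincare = {
      nv <- sqrt(sum(v^2))
      if (nv == 0) return(base)
      lam <- 2 / (1 - K * sum(base^2))  # conformal factor at base
      w <- tanh(sqrt(K) * lam * nv / 2) * v / (sqrt(K) * nv)
      if (all(base == 0)) w else mobius_add(base, w, K)
    },
    lorentz = {
      if (length(v) != spec$ambient_dim) stop("dimension mismatch")
      if (abs(lorentz_inner(base, v)) > 1e-6)
        stop("tangent vector is not orthogonal to the base point")
      nv2 <- lorentz_inner(v, v)
      if (nv2 <= 0) {
        if (max(abs(v)) == 0) return(base)
        stop("tangent vector has non-positive Lorentzian norm")
      }
      nv <- sqrt(nv2)
      cosh(nv / sqrt(K)) * base + sqrt(K) * sinh(nv / sqrt(K)) * v / nv
    })
}

#' Origin of a latent manifold
#'
#' The zero vector for Euclidean space and the Poincare ball;
#' `(1, 0, ..., 0)` for the Lorentz model.
#'
#' @param spec A [manifold_spec()].
#' @export
manifold_origin <- function(spec) {
  stopifnot(inherits(spec, "manifold_spec"))
  if (spec$kind == "lorentz") c(1, rep(0, spec$dim)) else rep(0, spec$dim)
}

#' Project Lorentz coordinates onto the Poincare ball
#'
#' The isometry `(x0, x1, ..., xn) -> (x1, ..., xn) / (sqrt(K) x0 + 1)`,
#' used to draw Lorentz embeddings on a Poincare disk.
#'
#' @param x A hyperboloid point, or a matrix of such points in rows.
#' @param K Curvature magnitude.
#' @param tol On-manifold tolerance.
#' @return Point(s) strictly inside the ball, one output row per input row.
#' @export
lorentz_to_poincare <- function(x, K = 1, tol = 1e-6) {
  if (is.matrix(x)) return(t(apply(x, 1, lorentz_to_poincare, K = K, tol = tol)))
  if (!.on_hyperboloid(x, tol)) stop("input point is not on the hyperboloid")
  x[-1] / (sqrt(K) * x[1] + 1)
}

#' Manifold distance between two points
#'
#' Dispatches to the metric of `spec`.
#'
#' @param spec A [manifold_spec()].
#' @param x,y Points on the manifold (ambient coordinates).
#' @export
manifold_distance <- function(spec, x, y) {
  switch(spec$kind,
    euclidean = euclidean_distance(x, y),
    poincare = poincare_distance(x, y, spec$K),
    lorentz = lorentz_distance(x, y, spec$K))
}

# ---- vectorized pairwise machinery (rows of Z are points) ----

# squared Euclidean cross/pairwise distances, clamped at 0
.pdist2 <- function(A, B = A) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Pairwise manifold distance matrix
#'
#' Computes all pairwise distances between the rows of `Z` (and `Z2`, when
#' given) under the metric of `spec`. Poincare rows are clipped to radius
#' `(1 - 1e-5)/sqrt(K)` before evaluation, and `acosh` arguments are clamped
#' to `>= 1`, the usual guards against rounding at the ball boundary.
#'
#' @param spec A [manifold_spec()].
#' @param Z Matrix of points in rows (ambient coordinates).
#' @param Z2 Optional second matrix; defaults to `Z`.
#' @return A `nrow(Z) x nrow(Z2)` matrix of distances.
#' @export
pairwise_distance <- function(spec, Z, Z2 = NULL) {
  Z <- as.matrix(Z)
  sym <- is.null(Z2)
  Z2 <- if (sym) Z else as.matrix(Z2)
  K <- spec$K
  D <- switch(spec$kind,
    euclidean = sqrt(.pdist2(Z, Z2)),
    poincare = {
      Z <- .clip_ball(Z, K); Z2 <- if (sym) Z else .clip_ball(Z2, K)
      a1 <- 1 - K * rowSums(Z^2); a2 <- 1 - K * rowSums(Z2^2)
      arg <- 1 + 2 * K * .pdist2(Z, Z2) / outer(a1, a2)
      .acosh_safe(arg) / sqrt(K)
    },
    lorentz = {
      ip <- -tcrossprod(Z[, 1], Z2[, 1]) +
        tcrossprod(Z[, -1, drop = FALSE], Z2[, -1, drop = FALSE])
      sqrt(K) * .acosh_safe(-ip / K)
    })
  if (sym) diag(D) <- 0
  D
}

# clip rows of Z to radius (1 - eps)/sqrt(K)
.clip_ball <- function(Z, K, eps = .BALL_EPS) {
  r <- sqrt(K * rowSums(Z^2))
  bad <- r >= 1 - eps
  if (any(bad)) Z[bad, ] <- Z[bad, , drop = FALSE] * ((1 - eps) / r[bad])
  Z
}

# exp map at the origin applied to rows of raw network output V (n x dim);
# returns manifold points in ambient coordinates. Used by the encoder.
.exp_map0_rows <- function(spec, V) {
  K <- spec$K
  switch(spec$kind,
    euclidean = V,
    poincare = {
      r <- sqrt(rowSums(V^2))
      s <- ifelse(r < 1e-12, 1 - K * r^2 / 3, tanh(sqrt(K) * r) / (sqrt(K) * r))
      V * s
    },
    lorentz = {
      r <- sqrt(rowSums(V^2))
      al <- r / sqrt(K)
      phi <- ifelse(r < 1e-12, 1 + r^2 / (6 * K), sqrt(K) * sinh(al) / r)
      cbind(cosh(al), V * phi)
    })
}
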