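# Minimal fully-connected network machinery: linear layers, batch
# normalization, LeakyReLU, reverse-mode gradients and Adam. Everything is
# plain matrix arithmetic so training stays deterministic given the seed.
# Internal: the user-facing surface is in model.R.

.LRELU_SLOPE <- 0.01
.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# ---- layer constructors ------------------------------------------------

# PyTorch-style uniform init: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
.layer_linear <- function(d_in, d_out, init_scale = 1) {
  bound <- 1 / sqrt(d_in)
  list(type = "linear",
       W = matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out) *
         init_scale,
       b = stats::runif(d_out, -bound, bound) * init_scale)
}

.layer_bn <- function(d) {
  list(type = "bn", gamma = rep(1, d), beta = rep(0, d),
       running_mean = rep(0, d), running_var = rep(1, d))
}

.layer_lrelu <- function() list(type = "lrelu")

# hidden stack: linear -> BN -> LeakyReLU per hidden width, final linear bare
.make_mlp <- function(dims, final_init_scale = 1) {
  layers <- list()
  for (i in seq_len(length(dims) - 2L)) {
    layers <- c(layers, list(.layer_linear(dims[i], dims[i + 1L]),
                             .layer_bn(dims[i + 1L]), .layer_lrelu()))
  }
  nl <- length(dims)
  layers <- c(layers, list(.layer_linear(dims[nl - 1L], dims[nl],
                                         init_scale = final_init_scale)))
  list(layers = layers, dims = dims)
}

# ---- forward / backward ------------------------------------------------

# returns list(out, cache); cache[[i]] holds what layer i needs for backward.
# `training` toggles BN batch statistics (and running-stat updates when
# `update_stats`). Networks are updated in place via the returned `net`.
.mlp_forward <- function(net, X, training = FALSE, update_stats = training) {
  cache <- vector("list", length(net$layers))
  H <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      cache[[i]] <- list(X = H)
      H <- H %*% ly$W + rep(ly$b, each = nrow(H))
    } else if (ly$type == "bn") {
      if (training && nrow(H) > 1L) {
        mu <- colMeans(H)
        v <- colMeans(H^2) - mu^2
        if (update_stats) {
          nb <- nrow(H)
          unb <- v * nb / max(nb - 1L, 1L)
          net$layers[[i]]$running_mean <-
            (1 - .BN_MOMENTUM) * ly$running_mean + .BN_MOMENTUM * mu
          net$layers[[i]]$running_var <-
            (1 - .BN_MOMENTUM) * ly$running_var + .BN_MOMENTUM * unb
        }
      } else {
        mu <- ly$running_mean
        v <- ly$running_var
      }
      inv_std <- 1 / sqrt(v + .BN_EPS)
      xhat <- sweep(H, 2, mu, "-") * rep(inv_std, each = nrow(H))
      cache[[i]] <- list(xhat = xhat, inv_std = inv_std,
                         batch_stats = training && nrow(H) > 1L)
      H <- xhat * rep(ly$gamma, each = nrow(H)) +
        rep(ly$beta, each = nrow(H))
    } else { # lrelu
      cache[[i]] <- list(mask = H >= 0)
      H <- pmax(H, 0) + .LRELU_SLOPE * pmin(H, 0)
    }
  }
  list(out = H, cache = cache, net = net)
}

# reverse pass; returns list(dX, grads) where grads[[i]] matches layer i.
.mlp_backward <- function(net, cache, dOut) {
  grads <- vector("list", length(net$layers))
  G <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "linear") {
      grads[[i]] <- list(W = crossprod(cc$X, G), b = colSums(G))
      G <- tcrossprod(G, ly$W)
    } else if (ly$type == "bn") {
      n <- nrow(G)
      dgamma <- colSums(G * cc$xhat)
      dbeta <- colSums(G)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      if (cc$batch_stats) {
        gg <- G * rep(ly$gamma, each = n)
        G <- (gg - rep(colMeans(gg), each = n) -
                cc$xhat * rep(colMeans(gg * cc$xhat), each = n)) *
          rep(cc$inv_std, each = n)
      } else {
        G <- G * rep(ly$gamma * cc$inv_std, each = n)
      }
    } else {
      G <- G * (.LRELU_SLOPE + (1 - .LRELU_SLOPE) * cc$mask)
    }
  }
  list(dX = G, grads = grads)
}

# ---- Adam --------------------------------------------------------------

.PARAM_NAMES <- c("W", "b", "gamma", "beta")

.adam_init <- function(nets) {
  lapply(nets, function(net) lapply(net$layers, function(ly) {
    ps <- intersect(names(ly), .PARAM_NAMES)
    stats::setNames(lapply(ps, function(p)
      list(m = ly[[p]] * 0, v = ly[[p]] * 0)), ps)
  }))
}

# one Adam step over a list of networks and matching gradient lists;
# returns list(nets, state, t)
.adam_step <- function(nets, grads, state, t, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (k in seq_along(nets)) {
    for (i in seq_along(nets[[k]]$layers)) {
      g_layer <- grads[[k]][[i]]
      if (is.null(g_layer)) next
      for (p in names(state[[k]][[i]])) {
        g <- g_layer[[p]]
        st <- state[[k]][[i]][[p]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        state[[k]][[i]][[p]] <- st
        nets[[k]]$layers[[i]][[p]] <- nets[[k]]$layers[[i]][[p]] -
          lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      }
    }
  }
  list(nets = nets, state = state)
}
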