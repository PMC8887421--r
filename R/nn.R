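## Minimal reverse-mode multilayer-perceptron engine in base R matrix code.
## Layers are plain lists; a network is a list of layers. Forward passes
## return the output together with per-layer caches; backward passes consume
## the caches and return the input gradient plus per-layer parameter
## gradients (NULL for parameter-free layers). All randomness (dropout masks)
## is drawn from the current R RNG stream so that callers control seeding.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

layer_dense <- function(n_in, n_out, init = c("he", "xavier", "zero")) {
  init <- match.arg(init)
  sdv <- switch(init, he = sqrt(2 / n_in), xavier = sqrt(1 / n_in), zero = 0)
  W <- matrix(if (sdv > 0) stats::rnorm(n_in * n_out, 0, sdv) else 0, n_in, n_out)
  list(kind = "dense", W = W, b = numeric(n_out))
}

layer_bn <- function(n) {
  list(kind = "bn", gamma = rep(1, n), beta = numeric(n),
       running_mean = numeric(n), running_var = rep(1, n))
}

layer_act <- function(kind) list(kind = kind)          # relu/softplus/hardsig/identity
layer_dropout <- function(rate) list(kind = "dropout", rate = rate)

## broadcast a length-p vector across the rows of an n x p matrix
rowbc <- function(M, v, op = `+`) op(M, rep(v, each = nrow(M)))

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
hardsig <- function(x) pmin(pmax(0.2 * x + 0.5, 0), 1)

layer_forward <- function(layer, X, training) {
  switch(layer$kind,
    dense = {
      out <- rowbc(X %*% layer$W, layer$b)
      list(out = out, cache = list(X = X), layer = layer)
    },
    bn = {
      if (training) {
        mu <- colMeans(X)
        Xc <- rowbc(X, mu, `-`)
        v <- colMeans(Xc^2)
        inv <- 1 / sqrt(v + BN_EPS)
        Xhat <- rowbc(Xc, inv, `*`)
        layer$running_mean <- BN_MOMENTUM * layer$running_mean + (1 - BN_MOMENTUM) * mu
        layer$running_var <- BN_MOMENTUM * layer$running_var + (1 - BN_MOMENTUM) * v
        out <- rowbc(rowbc(Xhat, layer$gamma, `*`), layer$beta)
        list(out = out, cache = list(Xhat = Xhat, inv = inv), layer = layer)
      } else {
        inv <- 1 / sqrt(layer$running_var + BN_EPS)
        Xhat <- rowbc(rowbc(X, layer$running_mean, `-`), inv, `*`)
        out <- rowbc(rowbc(Xhat, layer$gamma, `*`), layer$beta)
        list(out = out, cache = list(Xhat = Xhat, inv = inv), layer = layer)
      }
    },
    relu = {
      out <- pmax(X, 0)
      list(out = out, cache = list(mask = X > 0), layer = layer)
    },
    softplus = {
      out <- softplus(X)
      list(out = out, cache = list(sig = 1 / (1 + exp(-X))), layer = layer)
    },
    hardsig = {
      lin <- 0.2 * X + 0.5
      out <- pmin(pmax(lin, 0), 1)
      list(out = out, cache = list(mask = lin > 0 & lin < 1), layer = layer)
    },
    identity = list(out = X, cache = list(), layer = layer),
    dropout = {
      if (training && layer$rate > 0) {
        mask <- matrix(stats::rbinom(length(X), 1, 1 - layer$rate), nrow(X)) /
          (1 - layer$rate)
        list(out = X * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = X, cache = list(mask = NULL), layer = layer)
      }
    },
    stop("unknown layer kind: ", layer$kind))
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$kind,
    dense = list(dX = dY %*% t(layer$W),
                 grad = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    bn = {
      ## dX = inv/n * (n dXhat - sum(dXhat) - Xhat * sum(dXhat Xhat)), per column
      n <- nrow(dY)
      dXhat <- rowbc(dY, layer$gamma, `*`)
      A <- rowbc(dXhat, colSums(dXhat) / n, `-`)
      A <- A - rowbc(cache$Xhat, colSums(dXhat * cache$Xhat) / n, `*`)
      list(dX = rowbc(A, cache$inv, `*`),
           grad = list(gamma = colSums(dY * cache$Xhat), beta = colSums(dY)))
    },
    relu = list(dX = dY * cache$mask, grad = NULL),
    softplus = list(dX = dY * cache$sig, grad = NULL),
    hardsig = list(dX = dY * 0.2 * cache$mask, grad = NULL),
    identity = list(dX = dY, grad = NULL),
    dropout = list(dX = if (is.null(cache$mask)) dY else dY * cache$mask,
                   grad = NULL),
    stop("unknown layer kind: ", layer$kind))
}

net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], X, training)
    X <- step$out
    caches[[i]] <- step$cache
    layers[[i]] <- step$layer      # running BN stats may have been updated
  }
  list(out = X, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    step <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- step$dX
    grads[i] <- list(step$grad)   # [[<-]] with NULL would drop the element
  }
  list(dX = dY, grads = grads)
}

## ---- Adam optimizer over a list of networks --------------------------------

adam_init <- function(nets) {
  lapply(nets, function(layers) lapply(layers, function(l) {
    if (l$kind == "dense")
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else if (l$kind == "bn")
      list(mg = l$gamma * 0, vg = l$gamma * 0, mb = l$beta * 0, vb = l$beta * 0)
    else NULL
  }))
}

adam_update_param <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step <- function(nets, grads, state, lr, t) {
  for (k in seq_along(nets)) {
    for (i in seq_along(nets[[k]])) {
      g <- grads[[k]][[i]]
      if (is.null(g)) next
      l <- nets[[k]][[i]]
      s <- state[[k]][[i]]
      if (l$kind == "dense") {
        uW <- adam_update_param(l$W, g$W, s$mW, s$vW, lr, t)
        ub <- adam_update_param(l$b, g$b, s$mb, s$vb, lr, t)
        nets[[k]][[i]]$W <- uW$p; nets[[k]][[i]]$b <- ub$p
        state[[k]][[i]] <- list(mW = uW$m, vW = uW$v, mb = ub$m, vb = ub$v)
      } else if (l$kind == "bn") {
        ug <- adam_update_param(l$gamma, g$gamma, s$mg, s$vg, lr, t)
        ub <- adam_update_param(l$beta, g$beta, s$mb, s$vb, lr, t)
        nets[[k]][[i]]$gamma <- ug$p; nets[[k]][[i]]$beta <- ub$p
        state[[k]][[i]] <- list(mg = ug$m, vg = ug$v, mb = ub$m, vb = ub$v)
      }
    }
  }
  list(nets = nets, state = state)
}
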