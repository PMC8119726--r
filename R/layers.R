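# Internal layer machinery: conv + batch-norm + ReLU blocks with
# explicit forward/backward passes, pyramid-pooling layers, softmax,
# and the Adam update.  All tensors are (H, W, C, N) arrays.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

init_conv_layer <- function(kh, kw, ci, co, bias = TRUE, bn = TRUE,
                            rate = 1L, act = c("relu", "none")) {
  act <- match.arg(act)
  W <- array(rnorm(kh * kw * ci * co, sd = sqrt(2 / (kh * kw * ci))),
             c(kh, kw, ci, co))
  layer <- list(W = W, b = if (bias) numeric(co) else NULL,
                rate = as.integer(rate), act = act)
  if (bn) layer$bn <- list(gamma = rep(1, co), beta = numeric(co),
                           rmean = numeric(co), rvar = rep(1, co))
  layer
}

layer_n_params <- function(layer) {
  length(layer$W) + length(layer$b) +
    (if (is.null(layer$bn)) 0L else length(layer$bn$gamma) + length(layer$bn$beta))
}

bn_fwd <- function(x, bn, training) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- chan_sum(x) / m
    var <- chan_sum(x * x) / m - mu^2
    var[var < 0] <- 0
    bn$rmean <- BN_MOMENTUM * bn$rmean + (1 - BN_MOMENTUM) * mu
    bn$rvar <- BN_MOMENTUM * bn$rvar + (1 - BN_MOMENTUM) * var
  } else {
    mu <- bn$rmean
    var <- bn$rvar
  }
  ivstd <- 1 / sqrt(var + BN_EPS)
  xhat <- chan_bcast(chan_bcast(x, -mu, "+"), ivstd, "*")
  y <- chan_bcast(chan_bcast(xhat, bn$gamma, "*"), bn$beta, "+")
  list(y = y, bn = bn, cache = list(xhat = xhat, ivstd = ivstd, m = m))
}

bn_bwd <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  dgamma <- chan_sum(dy * xhat)
  dbeta <- chan_sum(dy)
  dxhat <- chan_bcast(dy, gamma, "*")
  s1 <- chan_sum(dxhat)
  s2 <- chan_sum(dxhat * xhat)
  dx <- chan_bcast(dxhat - chan_bcast(xhat, s2 / cache$m, "*") , -s1 / cache$m, "+")
  dx <- chan_bcast(dx, cache$ivstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# conv -> (bn) -> (relu)
block_fwd <- function(layer, x, training) {
  y <- cpp_conv2d_fwd(x, layer$W, layer$b, layer$rate)
  cache <- list(x = x)
  if (!is.null(layer$bn)) {
    r <- bn_fwd(y, layer$bn, training)
    y <- r$y
    layer$bn <- r$bn
    cache$bncache <- r$cache
  }
  if (layer$act == "relu") {
    mask <- y > 0
    y <- y * mask
    cache$mask <- mask
  }
  list(y = y, cache = cache, layer = layer)
}

block_bwd <- function(layer, cache, dy) {
  grads <- list()
  if (layer$act == "relu") dy <- dy * cache$mask
  if (!is.null(layer$bn)) {
    r <- bn_bwd(cache$bncache, layer$bn$gamma, dy)
    dy <- r$dx
    grads$gamma <- r$dgamma
    grads$beta <- r$dbeta
  }
  cb <- cpp_conv2d_bwd(cache$x, layer$W, dy, layer$rate, !is.null(layer$b))
  grads$W <- cb$dw
  if (!is.null(layer$b)) grads$b <- cb$db
  list(dx = cb$dx, grads = grads)
}

# Pyramid pooling layer: ppm = list(branches = <conv blocks>, sizes = <ints>)
ppm_layer_fwd <- function(ppm, x, training) {
  d <- dim(x)
  parts <- list(x)
  caches <- vector("list", length(ppm$sizes))
  branches <- ppm$branches
  for (i in seq_along(ppm$sizes)) {
    s <- ppm$sizes[i]
    p <- cpp_adaptive_avgpool_fwd(x, s, s)
    bf <- block_fwd(branches[[i]], p, training)
    branches[[i]] <- bf$layer
    u <- cpp_bilinear_fwd(bf$y, d[1], d[2])
    parts[[i + 1]] <- u
    caches[[i]] <- list(block = bf$cache, zdim = dim(bf$y))
  }
  y <- parts[[1]]
  for (i in seq_along(ppm$sizes)) y <- chan_cat(y, parts[[i + 1]])
  list(y = y, branches = branches,
       cache = list(caches = caches, xdim = d))
}

ppm_layer_bwd <- function(ppm, cache, dy) {
  d <- cache$xdim
  C <- d[3]
  b <- dim(ppm$branches[[1]]$W)[4]
  dx <- dy[, , seq_len(C), , drop = FALSE]
  dim(dx) <- d
  grads <- vector("list", length(ppm$sizes))
  for (i in seq_along(ppm$sizes)) {
    du <- dy[, , C + (i - 1) * b + seq_len(b), , drop = FALSE]
    dim(du) <- c(d[1], d[2], b, d[4])
    zd <- cache$caches[[i]]$zdim
    dz <- cpp_bilinear_bwd(du, zd[1], zd[2])
    bb <- block_bwd(ppm$branches[[i]], cache$caches[[i]]$block, dz)
    grads[[i]] <- bb$grads
    dx <- dx + cpp_adaptive_avgpool_bwd(bb$dx, d[1], d[2])
  }
  list(dx = dx, grads = grads)
}

# Softmax over the channel dimension of an (H, W, C, N) tensor.
# Internally works on a (C, H*W*N) channel-major matrix.
softmax_fwd <- function(logits) {
  d <- dim(logits)
  C <- d[3]
  m <- aperm(logits, c(3, 1, 2, 4))
  dim(m) <- c(C, prod(d) / C)
  mx <- m[1, ]
  if (C > 1) for (c in 2:C) mx <- pmax(mx, m[c, ])
  e <- exp(m - rep(mx, each = C))
  p <- e / rep(colSums(e), each = C)
  dim(p) <- c(C, d[1], d[2], d[4])
  aperm(p, c(2, 3, 1, 4))
}

softmax_bwd <- function(probs, dprobs) {
  d <- dim(probs)
  C <- d[3]
  p <- aperm(probs, c(3, 1, 2, 4))
  dp <- aperm(dprobs, c(3, 1, 2, 4))
  dim(p) <- dim(dp) <- c(C, prod(d) / C)
  s <- colSums(p * dp)
  dl <- p * (dp - rep(s, each = C))
  dim(dl) <- c(C, d[1], d[2], d[4])
  aperm(dl, c(2, 3, 1, 4))
}

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
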