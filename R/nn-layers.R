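# Primitive layers with explicit forward/backward passes. Each forward
# returns list(x = output tensor, cache = ..., layer = possibly-updated
# layer); each backward returns list(dx = gradient matrix, grads = named
# list mirroring layer$params).

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

xavier_init <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# conv ---------------------------------------------------------------------
nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       params = list(W = he_init(k * k * cin, cout, k * k * cin),
                     b = numeric(cout)))
}

conv_fwd <- function(layer, x, training) {
  k <- layer$k; C <- layer$cin
  if (k == 1L && layer$stride == 1L) {
    y <- x$a %*% layer$params$W
    y <- y + rep(layer$params$b, each = nrow(y))
    return(list(x = nn_tensor(y, x$H, x$W, x$N),
                cache = list(P = x$a, one = TRUE, dims = x), layer = layer))
  }
  iv <- conv_iv(x$H, x$W, k, layer$stride, layer$pad, x$N)
  P <- im2col(x$a, iv$IV, k * k, C)
  y <- P %*% layer$params$W
  y <- y + rep(layer$params$b, each = nrow(y))
  list(x = nn_tensor(y, iv$Hout, iv$Wout, x$N),
       cache = list(P = P, IV = iv$IV, one = FALSE, dims = x), layer = layer)
}

conv_bwd <- function(layer, cache, dy) {
  dW <- crossprod(cache$P, dy)
  db <- colSums(dy)
  if (cache$one) {
    dx <- tcrossprod(dy, layer$params$W)
  } else {
    dP <- tcrossprod(dy, layer$params$W)
    dx <- col2im(dP, cache$IV, layer$k^2, layer$cin,
                 nrow(cache$dims$a))
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# batch norm ---------------------------------------------------------------
nn_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", C = C, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)),
       buffers = list(rm = numeric(C), rv = rep(1, C)))
}

bn_fwd <- function(layer, x, training) {
  a <- x$a
  if (training) {
    mu <- colMeans(a)
    ac <- sweep(a, 2L, mu)
    v <- colMeans(ac^2)
    layer$buffers$rm <- (1 - layer$momentum) * layer$buffers$rm + layer$momentum * mu
    layer$buffers$rv <- (1 - layer$momentum) * layer$buffers$rv + layer$momentum * v
  } else {
    mu <- layer$buffers$rm
    v <- layer$buffers$rv
    ac <- sweep(a, 2L, mu)
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(ac, 2L, inv, "*")
  y <- sweep(xhat, 2L, layer$params$gamma, "*")
  y <- y + rep(layer$params$beta, each = nrow(y))
  list(x = nn_tensor(y, x$H, x$W, x$N),
       cache = list(ac = ac, inv = inv, xhat = xhat, training = training),
       layer = layer)
}

bn_bwd <- function(layer, cache, dy) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, layer$params$gamma, "*")
  if (cache$training) {
    M <- nrow(dy)
    inv <- cache$inv; ac <- cache$ac
    dv <- colSums(dxhat * ac) * (-0.5) * inv^3
    dmu <- -colSums(sweep(dxhat, 2L, inv, "*")) + dv * (-2) * colMeans(ac)
    dx <- sweep(dxhat, 2L, inv, "*") +
      sweep(ac, 2L, 2 * dv / M, "*") +
      rep(dmu / M, each = M)
  } else {
    dx <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# relu ---------------------------------------------------------------------
nn_relu <- function() list(type = "relu", params = list())

relu_fwd <- function(layer, x, training) {
  mask <- x$a > 0
  list(x = nn_tensor(x$a * mask, x$H, x$W, x$N), cache = mask, layer = layer)
}

relu_bwd <- function(layer, cache, dy) list(dx = dy * cache, grads = list())

# max pool -----------------------------------------------------------------
nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), params = list())
}

maxpool_fwd <- function(layer, x, training) {
  C <- ncol(x$a)
  iv <- conv_iv(x$H, x$W, layer$k, layer$stride, layer$pad, x$N)
  X0 <- rbind(matrix(-Inf, 1L, C), x$a)
  k2 <- layer$k^2
  NP <- nrow(iv$IV)
  best <- matrix(-Inf, NP, C)
  bt <- matrix(0L, NP, C)
  for (t in seq_len(k2)) {
    cur <- X0[iv$IV[, t], , drop = FALSE]
    upd <- cur > best
    best[upd] <- cur[upd]
    bt[upd] <- t
  }
  list(x = nn_tensor(best, iv$Hout, iv$Wout, x$N),
       cache = list(bt = bt, IV = iv$IV, in_rows = nrow(x$a), k2 = k2),
       layer = layer)
}

maxpool_bwd <- function(layer, cache, dy) {
  C <- ncol(dy)
  k2 <- cache$k2
  NP <- nrow(dy)
  long <- matrix(0, NP * k2, C)
  for (t in seq_len(k2)) {
    rows <- ((t - 1L) * NP + 1L):(t * NP)
    long[rows, ] <- dy * (cache$bt == t)
  }
  agg <- rowsum(long, group = as.vector(cache$IV))
  ids <- as.integer(rownames(agg))
  dX0 <- matrix(0, cache$in_rows + 1L, C)
  dX0[ids, ] <- agg
  list(dx = dX0[-1L, , drop = FALSE], grads = list())
}

# linear (acts on token/channel rows; spatial dims pass through) -----------
nn_linear <- function(cin, cout, init = c("he", "xavier"), bias = TRUE) {
  init <- match.arg(init)
  W <- if (init == "he") he_init(cin, cout, cin) else xavier_init(cin, cout)
  params <- list(W = W)
  if (bias) params$b <- numeric(cout)
  list(type = "linear", cin = cin, cout = cout, bias = bias, params = params)
}

linear_fwd <- function(layer, x, training) {
  y <- x$a %*% layer$params$W
  if (layer$bias) y <- y + rep(layer$params$b, each = nrow(y))
  list(x = nn_tensor(y, x$H, x$W, x$N), cache = x$a, layer = layer)
}

linear_bwd <- function(layer, cache, dy) {
  g <- list(W = crossprod(cache, dy))
  if (layer$bias) g$b <- colSums(dy)
  list(dx = tcrossprod(dy, layer$params$W), grads = g)
}

# layer norm (per token over channels) --------------------------------------
nn_ln <- function(C, eps = 1e-5) {
  list(type = "ln", C = C, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)))
}

ln_fwd <- function(layer, x, training) {
  a <- x$a
  mu <- rowMeans(a)
  ac <- a - mu
  v <- rowMeans(ac^2)
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- ac * inv
  y <- sweep(xhat, 2L, layer$params$gamma, "*")
  y <- y + rep(layer$params$beta, each = nrow(y))
  list(x = nn_tensor(y, x$H, x$W, x$N),
       cache = list(ac = ac, inv = inv, xhat = xhat), layer = layer)
}

ln_bwd <- function(layer, cache, dy) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, layer$params$gamma, "*")
  D <- ncol(dy)
  inv <- cache$inv; ac <- cache$ac
  dv <- rowSums(dxhat * ac) * (-0.5) * inv^3
  dmu <- -rowSums(dxhat * inv) + dv * (-2) * rowMeans(ac)
  dx <- dxhat * inv + ac * (2 * dv / D) + dmu / D
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# gelu ----------------------------------------------------------------------
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
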