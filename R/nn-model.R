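# Layer dispatch, the residual bottleneck composite, the classification
# head, and whole-model forward/backward with SGD updates.

# bottleneck ----------------------------------------------------------------
# ResNet-style bottleneck: 1x1 reduce -> 3x3 (optionally strided) -> 1x1
# expand, each conv followed by batch norm; projection shortcut when the
# shape changes.
nn_bottleneck <- function(cin, cout, mid, stride = 1L) {
  sub <- list(c1 = nn_conv(cin, mid, 1L), b1 = nn_bn(mid),
              c2 = nn_conv(mid, mid, 3L, stride = stride), b2 = nn_bn(mid),
              c3 = nn_conv(mid, cout, 1L), b3 = nn_bn(cout))
  down <- (stride != 1L || cin != cout)
  if (down) {
    sub$cd <- nn_conv(cin, cout, 1L, stride = stride, pad = 0L)
    sub$bd <- nn_bn(cout)
  }
  list(type = "bottleneck", down = down, params = list(), sub = sub)
}

bottleneck_fwd <- function(layer, x, training) {
  caches <- list()
  run <- function(name, inp) {
    r <- layer_forward(layer$sub[[name]], inp, training)
    layer$sub[[name]] <<- r$layer
    caches[[name]] <<- r$cache
    r$x
  }
  h <- run("c1", x); h <- run("b1", h)
  m1 <- h$a > 0; h$a <- h$a * m1
  h <- run("c2", h); h <- run("b2", h)
  m2 <- h$a > 0; h$a <- h$a * m2
  h <- run("c3", h); h <- run("b3", h)
  sc <- if (layer$down) run("bd", run("cd", x)) else x
  y <- h$a + sc$a
  m3 <- y > 0
  list(x = nn_tensor(y * m3, h$H, h$W, h$N),
       cache = list(caches = caches, m1 = m1, m2 = m2, m3 = m3),
       layer = layer)
}

bottleneck_bwd <- function(layer, cache, dy) {
  grads <- list()
  back <- function(name, d) {
    r <- layer_backward(layer$sub[[name]], cache$caches[[name]], d)
    grads[[name]] <<- r$grads
    r$dx
  }
  d <- dy * cache$m3
  dsc <- if (layer$down) back("cd", back("bd", d)) else d
  d3 <- back("c3", back("b3", d))
  d3 <- d3 * cache$m2
  d2 <- back("c2", back("b2", d3))
  d2 <- d2 * cache$m1
  d1 <- back("c1", back("b1", d2))
  list(dx = d1 + dsc, grads = list(sub = grads))
}

# classification head: global average pool over tokens + fully connected.
# The head starts at zero so a fresh model is exactly balanced (p = 0.5,
# initial cross-entropy ln 2 on balanced data).
nn_head <- function(D, num_classes = 2L) {
  list(type = "head", D = D, num_classes = num_classes,
       params = list(W = matrix(0, D, num_classes), b = numeric(num_classes)))
}

head_fwd <- function(layer, x, training) {
  L <- x$H * x$W
  grp <- rep(seq_len(x$N), each = L)
  pooled <- rowsum(x$a, grp) / L
  logits <- pooled %*% layer$params$W
  logits <- logits + rep(layer$params$b, each = nrow(logits))
  list(x = nn_tensor(logits, 1L, 1L, x$N),
       cache = list(pooled = pooled, grp = grp, L = L), layer = layer)
}

head_bwd <- function(layer, cache, dy) {
  dW <- crossprod(cache$pooled, dy)
  db <- colSums(dy)
  dpooled <- tcrossprod(dy, layer$params$W)
  dx <- dpooled[cache$grp, , drop = FALSE] / cache$L
  list(dx = dx, grads = list(W = dW, b = db))
}

# dispatch -------------------------------------------------------------------
layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
         conv = conv_fwd(layer, x, training),
         bn = bn_fwd(layer, x, training),
         relu = relu_fwd(layer, x, training),
         maxpool = maxpool_fwd(layer, x, training),
         linear = linear_fwd(layer, x, training),
         ln = ln_fwd(layer, x, training),
         swin = swin_fwd(layer, x, training),
         patch_merge = patch_merge_fwd(layer, x, training),
         bottleneck = bottleneck_fwd(layer, x, training),
         head = head_fwd(layer, x, training),
         stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
         conv = conv_bwd(layer, cache, dy),
         bn = bn_bwd(layer, cache, dy),
         relu = relu_bwd(layer, cache, dy),
         maxpool = maxpool_bwd(layer, cache, dy),
         linear = linear_bwd(layer, cache, dy),
         ln = ln_bwd(layer, cache, dy),
         swin = swin_bwd(layer, cache, dy),
         patch_merge = patch_merge_bwd(layer, cache, dy),
         bottleneck = bottleneck_bwd(layer, cache, dy),
         head = head_bwd(layer, cache, dy),
         stop("unknown layer type: ", layer$type))
}

# whole-model passes ---------------------------------------------------------
model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$x
    caches[[i]] <- r$cache
    model$layers[[i]] <- r$layer
  }
  list(logits = x$a, caches = caches, model = model)
}

model_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  dy <- dlogits
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], dy)
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

# SGD with classical momentum: v <- mom * v + g; p <- p - lr * v. The
# velocity tree mirrors the layer/grads tree.
init_velocity <- function(layer) {
  v <- list()
  if (length(layer$params))
    v$params <- lapply(layer$params, function(p) p * 0)
  if (!is.null(layer$sub))
    v$sub <- lapply(layer$sub, init_velocity)
  v
}

sgd_update_layer <- function(layer, grads, vel, lr, mom) {
  if (length(layer$params)) {
    g <- if (!is.null(grads$sub) || !is.null(grads$params)) grads$params else grads
    for (nm in names(layer$params)) {
      vel$params[[nm]] <- mom * vel$params[[nm]] + g[[nm]]
      layer$params[[nm]] <- layer$params[[nm]] - lr * vel$params[[nm]]
    }
  }
  if (!is.null(layer$sub)) {
    for (nm in names(layer$sub)) {
      r <- sgd_update_layer(layer$sub[[nm]], grads$sub[[nm]], vel$sub[[nm]],
                            lr, mom)
      layer$sub[[nm]] <- r$layer
      vel$sub[[nm]] <- r$vel
    }
  }
  list(layer = layer, vel = vel)
}

sgd_step <- function(model, grads, vel, lr, mom) {
  for (i in seq_along(model$layers)) {
    r <- sgd_update_layer(model$layers[[i]], grads[[i]], vel[[i]], lr, mom)
    model$layers[[i]] <- r$layer
    vel[[i]] <- r$vel
  }
  list(model = model, vel = vel)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy over 2 classes; y is an integer vector of class indices.
cross_entropy <- function(logits, y) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_along(y), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, nrow(p), ncol(p))
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / nrow(p), probs = p)
}
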