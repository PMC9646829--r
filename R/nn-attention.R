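# Windowed self-attention stage (shifted-window blocks + patch merging),
# with explicit backward passes. Token grids reuse the tensor layout of
# nn-tensor.R: rows are sample-major, row-major spatial (x fastest).

.perm_cache <- new.env(parent = emptyenv())

# Permutation grouping tokens by window (row-major windows, row-major
# within each window), replicated over the batch with offsets.
win_perm <- function(H, W, s, N) {
  key <- paste("wp", H, W, s, N, sep = "_")
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  nWy <- H %/% s; nWx <- W %/% s
  q <- integer(H * W)
  k <- 1L
  for (wy in seq_len(nWy)) for (wx in seq_len(nWx))
    for (iy in seq_len(s)) for (ix in seq_len(s)) {
      y <- (wy - 1L) * s + iy; x <- (wx - 1L) * s + ix
      q[k] <- (y - 1L) * W + x
      k <- k + 1L
    }
  full <- as.vector(vapply(seq_len(N) - 1L,
                           function(n) q + n * H * W, integer(H * W)))
  inv <- integer(length(full)); inv[full] <- seq_along(full)
  val <- list(perm = full, inv = inv, nW = nWy * nWx)
  .perm_cache[[key]] <- val
  val
}

# Cyclic shift permutation: destination token (y, x) reads source
# (y + shift, x + shift), wrapped (a roll by -shift in both axes).
shift_perm <- function(H, W, shift, N) {
  key <- paste("sp", H, W, shift, N, sep = "_")
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  y <- rep(seq_len(H), each = W); x <- rep(seq_len(W), times = H)
  ys <- ((y + shift - 1L) %% H) + 1L
  xs <- ((x + shift - 1L) %% W) + 1L
  q <- (ys - 1L) * W + xs
  full <- as.vector(vapply(seq_len(N) - 1L,
                           function(n) q + n * H * W, integer(H * W)))
  inv <- integer(length(full)); inv[full] <- seq_along(full)
  val <- list(perm = full, inv = inv)
  .perm_cache[[key]] <- val
  val
}

# Attention masks for shifted windows: one Lw x Lw additive mask per window,
# -1e9 where the two tokens come from different pre-shift image regions.
swin_masks <- function(H, W, s, shift) {
  key <- paste("mask", H, W, s, shift, sep = "_")
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  bin <- function(v, n) ifelse(v <= n - s, 0L, ifelse(v <= n - shift, 1L, 2L))
  y <- rep(seq_len(H), each = W); x <- rep(seq_len(W), times = H)
  ys <- ((y + shift - 1L) %% H) + 1L   # region of the source token
  xs <- ((x + shift - 1L) %% W) + 1L
  id <- bin(ys, H) * 3L + bin(xs, W)
  wp <- win_perm(H, W, s, 1L)
  ids_by_window <- split(id[wp$perm], rep(seq_len(wp$nW), each = s * s))
  masks <- lapply(ids_by_window, function(ids)
    matrix(ifelse(outer(ids, ids, "!="), -1e9, 0), s * s, s * s))
  .perm_cache[[key]] <- masks
  masks
}

# swin block ----------------------------------------------------------------
nn_swin_block <- function(D, heads, window, shift = 0L, mlp_ratio = 4L) {
  stopifnot(D %% heads == 0L)
  list(type = "swin", D = D, heads = heads, window = as.integer(window),
       shift = as.integer(shift), params = list(),
       sub = list(ln1 = nn_ln(D),
                  qkv = nn_linear(D, 3L * D, init = "xavier"),
                  proj = nn_linear(D, D, init = "xavier"),
                  ln2 = nn_ln(D),
                  fc1 = nn_linear(D, mlp_ratio * D, init = "xavier"),
                  fc2 = nn_linear(mlp_ratio * D, D, init = "xavier")))
}

swin_fwd <- function(layer, x, training) {
  D <- layer$D; s <- layer$window; hds <- layer$heads
  if (x$H %% s != 0L || x$W %% s != 0L)
    stop(sprintf("window size %d does not divide feature grid %dx%d",
                 s, x$H, x$W), call. = FALSE)
  dh <- D %/% hds
  scale <- 1 / sqrt(dh)
  Lw <- s * s

  r1 <- ln_fwd(layer$sub$ln1, x, training)
  h1 <- r1$x$a
  sp <- NULL
  if (layer$shift > 0L) {
    sp <- shift_perm(x$H, x$W, layer$shift, x$N)
    h1 <- h1[sp$perm, , drop = FALSE]
  }
  rq <- linear_fwd(layer$sub$qkv, nn_tensor(h1, x$H, x$W, x$N), training)
  qkv <- rq$x$a
  wp <- win_perm(x$H, x$W, s, x$N)
  part <- qkv[wp$perm, , drop = FALSE]
  masks <- if (layer$shift > 0L) swin_masks(x$H, x$W, s, layer$shift) else NULL

  nB <- x$N * wp$nW
  out_part <- matrix(0, nrow(part), D)
  Pms <- vector("list", nB * hds)
  for (b in seq_len(nB)) {
    rows <- ((b - 1L) * Lw + 1L):(b * Lw)
    w_id <- ((b - 1L) %% wp$nW) + 1L
    for (h in seq_len(hds)) {
      qc <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- part[rows, qc, drop = FALSE]
      K <- part[rows, D + qc, drop = FALSE]
      V <- part[rows, 2L * D + qc, drop = FALSE]
      A <- tcrossprod(Q, K) * scale
      if (!is.null(masks)) A <- A + masks[[w_id]]
      A <- A - apply(A, 1L, max)
      Pm <- exp(A); Pm <- Pm / rowSums(Pm)
      out_part[rows, qc] <- Pm %*% V
      Pms[[(b - 1L) * hds + h]] <- Pm
    }
  }
  att <- out_part[wp$inv, , drop = FALSE]
  if (!is.null(sp)) att <- att[sp$inv, , drop = FALSE]
  rp <- linear_fwd(layer$sub$proj, nn_tensor(att, x$H, x$W, x$N), training)
  x2 <- x$a + rp$x$a

  r2 <- ln_fwd(layer$sub$ln2, nn_tensor(x2, x$H, x$W, x$N), training)
  rf1 <- linear_fwd(layer$sub$fc1, r2$x, training)
  m1 <- rf1$x$a
  g <- gelu(m1)
  rf2 <- linear_fwd(layer$sub$fc2, nn_tensor(g, x$H, x$W, x$N), training)
  y <- x2 + rf2$x$a

  list(x = nn_tensor(y, x$H, x$W, x$N),
       cache = list(c_ln1 = r1$cache, c_qkv = rq$cache, part = part,
                    Pms = Pms, c_proj = rp$cache, c_ln2 = r2$cache,
                    c_fc1 = rf1$cache, m1 = m1, g = g, c_fc2 = rf2$cache,
                    sp = sp, wp = wp, dims = c(x$H, x$W, x$N)),
       layer = layer)
}

swin_bwd <- function(layer, cache, dy) {
  D <- layer$D; s <- layer$window; hds <- layer$heads
  dh <- D %/% hds
  scale <- 1 / sqrt(dh)
  Lw <- s * s
  wp <- cache$wp; sp <- cache$sp

  # MLP branch
  bf2 <- linear_bwd(layer$sub$fc2, cache$g, dy)
  dm1 <- bf2$dx * gelu_grad(cache$m1)
  bf1 <- linear_bwd(layer$sub$fc1, cache$c_fc1, dm1)
  bl2 <- ln_bwd(layer$sub$ln2, cache$c_ln2, bf1$dx)
  dx2 <- dy + bl2$dx

  # attention branch
  bp <- linear_bwd(layer$sub$proj, cache$c_proj, dx2)
  datt <- bp$dx
  if (!is.null(sp)) datt <- datt[sp$perm, , drop = FALSE]
  dout_part <- datt[wp$perm, , drop = FALSE]

  part <- cache$part
  dpart <- matrix(0, nrow(part), 3L * D)
  nB <- nrow(part) %/% Lw
  for (b in seq_len(nB)) {
    rows <- ((b - 1L) * Lw + 1L):(b * Lw)
    for (h in seq_len(hds)) {
      qc <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- part[rows, qc, drop = FALSE]
      K <- part[rows, D + qc, drop = FALSE]
      V <- part[rows, 2L * D + qc, drop = FALSE]
      Pm <- cache$Pms[[(b - 1L) * hds + h]]
      dO <- dout_part[rows, qc, drop = FALSE]
      dPm <- tcrossprod(dO, V)
      dV <- crossprod(Pm, dO)
      dA <- Pm * (dPm - rowSums(dPm * Pm))
      dpart[rows, qc] <- (dA %*% K) * scale
      dpart[rows, D + qc] <- crossprod(dA, Q) * scale
      dpart[rows, 2L * D + qc] <- dV
    }
  }
  dqkv <- dpart[wp$inv, , drop = FALSE]
  bq <- linear_bwd(layer$sub$qkv, cache$c_qkv, dqkv)
  dh1 <- bq$dx
  if (!is.null(sp)) dh1 <- dh1[sp$inv, , drop = FALSE]
  bl1 <- ln_bwd(layer$sub$ln1, cache$c_ln1, dh1)
  dx <- dx2 + bl1$dx

  list(dx = dx,
       grads = list(sub = list(ln1 = bl1$grads, qkv = bq$grads,
                               proj = bp$grads, ln2 = bl2$grads,
                               fc1 = bf1$grads, fc2 = bf2$grads)))
}

# patch merging --------------------------------------------------------------
nn_patch_merge <- function(D) {
  list(type = "patch_merge", D = D, params = list(),
       sub = list(ln = nn_ln(4L * D),
                  red = nn_linear(4L * D, 2L * D, init = "xavier",
                                  bias = FALSE)))
}

merge_idx <- function(H, W, N) {
  key <- paste("mi", H, W, N, sep = "_")
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  oy <- rep(seq_len(H2), each = W2); ox <- rep(seq_len(W2), times = H2)
  p <- function(y, x) (y - 1L) * W + x
  base <- list(p(2L * oy - 1L, 2L * ox - 1L),   # (even y, even x) block
               p(2L * oy,      2L * ox - 1L),
               p(2L * oy - 1L, 2L * ox),
               p(2L * oy,      2L * ox))
  full <- lapply(base, function(q)
    as.vector(vapply(seq_len(N) - 1L, function(n) q + n * H * W,
                     integer(length(q)))))
  val <- list(idx = full, H2 = H2, W2 = W2)
  .perm_cache[[key]] <- val
  val
}

patch_merge_fwd <- function(layer, x, training) {
  if (x$H %% 2L != 0L || x$W %% 2L != 0L)
    stop(sprintf("patch merging needs an even grid, got %dx%d", x$H, x$W),
         call. = FALSE)
  mi <- merge_idx(x$H, x$W, x$N)
  D <- layer$D
  g <- cbind(x$a[mi$idx[[1]], , drop = FALSE], x$a[mi$idx[[2]], , drop = FALSE],
             x$a[mi$idx[[3]], , drop = FALSE], x$a[mi$idx[[4]], , drop = FALSE])
  tg <- nn_tensor(g, mi$H2, mi$W2, x$N)
  rl <- ln_fwd(layer$sub$ln, tg, training)
  rr <- linear_fwd(layer$sub$red, rl$x, training)
  list(x = rr$x,
       cache = list(mi = mi, c_ln = rl$cache, c_red = rr$cache,
                    in_rows = nrow(x$a)),
       layer = layer)
}

patch_merge_bwd <- function(layer, cache, dy) {
  D <- layer$D
  br <- linear_bwd(layer$sub$red, cache$c_red, dy)
  bl <- ln_bwd(layer$sub$ln, cache$c_ln, br$dx)
  dg <- bl$dx
  dx <- matrix(0, cache$in_rows, D)
  for (k in 1:4) {
    cols <- ((k - 1L) * D + 1L):(k * D)
    dx[cache$mi$idx[[k]], ] <- dx[cache$mi$idx[[k]], , drop = FALSE] +
      dg[, cols, drop = FALSE]
  }
  list(dx = dx, grads = list(sub = list(ln = bl$grads, red = br$grads)))
}
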