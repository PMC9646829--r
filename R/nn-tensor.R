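# Minimal tensor plumbing for the ResNetST backbone.
#
# Activations are stored as a matrix `a` of shape (N*H*W, C): rows are
# sample-major, then row-major spatial positions p = (y-1)*W + x (x fastest);
# columns are channels. This layout keeps every layer a BLAS matrix product
# plus index gymnastics, which is what makes a pure-R backbone tractable.

nn_tensor <- function(a, H, W, N) {
  list(a = a, H = as.integer(H), W = as.integer(W), N = as.integer(N))
}

# Convert a fused_input (or a list of them, stacked as a batch) to a tensor.
inputs_to_tensor <- function(inputs) {
  if (inherits(inputs, "fused_input")) inputs <- list(inputs)
  d <- dim(inputs[[1]]$pixels)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- length(inputs)
  a <- matrix(0, N * H * W, C)
  for (n in seq_len(N)) {
    px <- inputs[[n]]$pixels
    rows <- ((n - 1L) * H * W + 1L):(n * H * W)
    for (c in seq_len(C)) a[rows, c] <- as.vector(t(px[, , c]))
  }
  nn_tensor(a, H, W, N)
}

# im2col index cache -------------------------------------------------------
# For a given geometry, IV is an (N*Pout x k^2) integer matrix whose entry
# [r, t] is the row of rbind(<sentinel row>, a) holding the input pixel under
# tap t of output position r; 1 points at the sentinel (zero padding).
.iv_cache <- new.env(parent = emptyenv())

conv_iv <- function(H, W, k, stride, pad, N) {
  key <- paste(H, W, k, stride, pad, N, sep = "_")
  hit <- .iv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hout <- (H + 2L * pad - k) %/% stride + 1L
  Wout <- (W + 2L * pad - k) %/% stride + 1L
  Pout <- Hout * Wout
  oy <- rep(seq_len(Hout), each = Wout)
  ox <- rep(seq_len(Wout), times = Hout)
  M <- matrix(0L, Pout, k * k)
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    t <- (ky - 1L) * k + kx
    iy <- (oy - 1L) * stride + ky - pad
    ix <- (ox - 1L) * stride + kx - pad
    ok <- iy >= 1L & iy <= H & ix >= 1L & ix <= W
    M[, t] <- ifelse(ok, (iy - 1L) * W + ix, 0L)
  }
  Mrep <- M[rep(seq_len(Pout), times = N), , drop = FALSE]
  off <- rep((seq_len(N) - 1L) * H * W, each = Pout)
  IV <- ifelse(Mrep > 0L, Mrep + off + 1L, 1L)
  val <- list(IV = IV, Hout = Hout, Wout = Wout)
  .iv_cache[[key]] <- val
  val
}

# Gather im2col patches: (N*Pout, k^2*C), tap-major column blocks.
im2col <- function(a, IV, k2, C) {
  X0 <- rbind(matrix(0, 1L, C), a)
  P <- matrix(0, nrow(IV), k2 * C)
  for (t in seq_len(k2))
    P[, ((t - 1L) * C + 1L):(t * C)] <- X0[IV[, t], , drop = FALSE]
  P
}

# Scatter-add patch gradients back to input rows (inverse of im2col).
col2im <- function(dP, IV, k2, C, n_rows) {
  NP <- nrow(IV)
  A <- array(dP, dim = c(NP, C, k2))
  long <- matrix(aperm(A, c(1, 3, 2)), NP * k2, C)
  agg <- rowsum(long, group = as.vector(IV))
  ids <- as.integer(rownames(agg))
  dX0 <- matrix(0, n_rows + 1L, C)
  dX0[ids, ] <- agg
  dX0[-1L, , drop = FALSE]
}
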