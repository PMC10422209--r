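# Convolutional layer primitives with explicit backward passes.
#
# No neural-network framework exists in this environment, so the few layer
# types the encoder needs are implemented directly on batch tensors of
# shape (H, W, C, B), with convolutions done as im2col matrix products so
# the heavy lifting stays inside BLAS. Weight matrices for a k x k
# convolution have shape (k*k*Cin, Cout); rows are ordered offset-major,
# channel-minor, and the same ordering is used by both directions.

# im2col for a k x k convolution, stride 1, "same" padding for k = 3.
im2col <- function(x, k) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  if (k == 1L) {
    return(matrix(aperm(x, c(1L, 2L, 4L, 3L)), H * W * B, C))
  }
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, B))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  cols <- matrix(0, H * W * B, k * k * C)
  o <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sl <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      cols[, o * C + seq_len(C)] <- matrix(aperm(sl, c(1L, 2L, 4L, 3L)),
                                           H * W * B, C)
      o <- o + 1L
    }
  }
  cols
}

# Scatter-add inverse of im2col.
col2im <- function(dcols, dims, k) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]; B <- dims[4]
  if (k == 1L) {
    dx <- array(aperm(array(dcols, c(H, W, B, C)), c(1L, 2L, 4L, 3L)),
                c(H, W, C, B))
    return(dx)
  }
  pad <- (k - 1L) %/% 2L
  dxp <- array(0, c(H + 2L * pad, W + 2L * pad, C, B))
  o <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      block <- aperm(array(dcols[, o * C + seq_len(C)], c(H, W, B, C)),
                     c(1L, 2L, 4L, 3L))
      dxp[di:(di + H - 1L), dj:(dj + W - 1L), , ] <-
        dxp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE] + block
      o <- o + 1L
    }
  }
  dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

conv_fw <- function(x, W, b, k) {
  d <- dim(x)
  cols <- im2col(x, k)
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  out <- aperm(array(out, c(d[1], d[2], d[4], ncol(W))), c(1L, 2L, 4L, 3L))
  list(out = out, cache = list(cols = cols, dims = d))
}

conv_bw <- function(dout, W, k, cache) {
  d <- cache$dims
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], ncol(W))
  list(
    dx = col2im(dmat %*% t(W), d, k),
    dW = crossprod(cache$cols, dmat),
    db = colSums(dmat)
  )
}

relu_fw <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = x > 0)
}

relu_bw <- function(dout, mask) dout * mask

# 2x2 average pooling, stride 2; odd trailing rows/columns are dropped.
pool_fw <- function(x) {
  d <- dim(x)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  i1 <- seq_len(h) * 2L - 1L
  j1 <- seq_len(w) * 2L - 1L
  out <- (x[i1, j1, , , drop = FALSE] + x[i1 + 1L, j1, , , drop = FALSE] +
            x[i1, j1 + 1L, , , drop = FALSE] +
            x[i1 + 1L, j1 + 1L, , , drop = FALSE]) / 4
  list(out = out, cache = d)
}

pool_bw <- function(dout, dims) {
  dx <- array(0, dims)
  h <- dims[1] %/% 2L; w <- dims[2] %/% 2L
  i1 <- seq_len(h) * 2L - 1L
  j1 <- seq_len(w) * 2L - 1L
  g <- dout / 4
  dx[i1, j1, , ] <- g
  dx[i1 + 1L, j1, , ] <- g
  dx[i1, j1 + 1L, , ] <- g
  dx[i1 + 1L, j1 + 1L, , ] <- g
  dx
}

# Global average pooling: (H, W, C, B) -> (C, B).
gap_fw <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  list(out = matrix(colMeans(m), d[3], d[4]), cache = d)
}

gap_bw <- function(dout, dims) {
  hw <- dims[1] * dims[2]
  array(rep(as.numeric(dout) / hw, each = hw), dims)
}

# Column-wise L2 normalization with its Jacobian-vector product.
l2norm_fw <- function(v, tol = 1e-12) {
  nrm <- sqrt(colSums(v^2))
  if (any(nrm < tol)) {
    stop("projection produced a zero vector; cannot normalize onto the ",
         "unit hypersphere", call. = FALSE)
  }
  z <- sweep(v, 2L, nrm, "/")
  list(out = z, cache = list(z = z, nrm = nrm))
}

l2norm_bw <- function(dz, cache) {
  z <- cache$z
  sweep(dz - sweep(z, 2L, colSums(z * dz), "*"), 2L, cache$nrm, "/")
}
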