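# Shared helpers for the test suite. Oracles here are deliberately written as
# direct, loop-based implementations independent of the package's vectorised
# and C++ code paths.

ad_with_tape <- octseg:::ad_with_tape
ad_backward <- octseg:::ad_backward
ad_const <- octseg:::ad_const
ad_param <- octseg:::ad_param
ad_sum <- octseg:::ad_sum
ad_sigmoid <- octseg:::ad_sigmoid
nodeval <- octseg:::val

# brute-force bilinear sample of x (H, W, C) at 0-based (gy, gx), border clamp
oracle_bilinear <- function(x, gy, gx) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  cl <- function(v, n) min(max(v, 0), n - 1)
  y <- cl(gy, H); xx <- cl(gx, W)
  i0 <- min(floor(y), max(H - 2, 0)); i1 <- min(i0 + 1, H - 1)
  j0 <- min(floor(xx), max(W - 2, 0)); j1 <- min(j0 + 1, W - 1)
  wy <- y - i0; wx <- xx - j0
  out <- numeric(C)
  for (c in seq_len(C)) {
    out[c] <- (1 - wy) * (1 - wx) * x[i0 + 1, j0 + 1, c] +
      wy * (1 - wx) * x[i1 + 1, j0 + 1, c] +
      (1 - wy) * wx * x[i0 + 1, j1 + 1, c] +
      wy * wx * x[i1 + 1, j1 + 1, c]
  }
  out
}

# brute-force deformable convolution: nested loops over output pixels, taps,
# channels; bilinear gather at p + p_k + offset
oracle_deform_conv <- function(x, offsets, kernel, bias = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(kernel)[1]; kw <- dim(kernel)[2]; Cout <- dim(kernel)[4]
  K <- kh * kw; mid <- (kh + 1) %/% 2
  out <- array(0, c(H, W, Cout))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- if (is.null(bias)) numeric(Cout) else bias
    for (iw in seq_len(kw)) for (ih in seq_len(kh)) {
      k <- ih + kh * (iw - 1)
      gx <- (j - 1) + (iw - mid) + offsets[i, j, k]
      gy <- (i - 1) + (ih - mid) + offsets[i, j, K + k]
      s <- oracle_bilinear(x, gy, gx)
      for (co in seq_len(Cout)) {
        acc[co] <- acc[co] + sum(s * kernel[ih, iw, , co])
      }
    }
    out[i, j, ] <- acc
  }
  out
}

# brute-force orthonormal DCT-II of a vector
oracle_dct2 <- function(v, k) {
  n <- length(v)
  sapply(0:(k - 1), function(m) {
    s <- if (m == 0) sqrt(1 / n) else sqrt(2 / n)
    s * sum(v * cos(pi * (2 * (0:(n - 1)) + 1) * m / (2 * n)))
  })
}

# brute-force dense single-window attention with edge-modulated queries
oracle_window_attention <- function(tok, ew, wq, bq, wk, bk, wv, bv, d) {
  tokm <- tok * matrix(ew, nrow(tok), ncol(tok))
  Q <- sweep(tokm %*% wq, 2, bq, "+")
  K <- sweep(tok %*% wk, 2, bk, "+")
  V <- sweep(tok %*% wv, 2, bv, "+")
  S <- Q %*% t(K) / sqrt(d)
  A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  list(out = A %*% V, attn = A)
}

# brute-force Chebyshev dilation of a binary matrix by radius r
oracle_dilate <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    i0 <- max(1, i - r); i1 <- min(H, i + r)
    j0 <- max(1, j - r); j1 <- min(W, j + r)
    out[i, j] <- max(m[i0:i1, j0:j1])
  }
  out
}

# erosion with zero border: out-of-image pixels count as background
oracle_erode <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    lo_i <- i - r; hi_i <- i + r; lo_j <- j - r; hi_j <- j + r
    if (lo_i < 1 || lo_j < 1 || hi_i > H || hi_j > W) { out[i, j] <- 0; next }
    out[i, j] <- min(m[lo_i:hi_i, lo_j:hi_j])
  }
  out
}

# brute-force hard boundary band: (m XOR erode3(m)) dilated r times with 3x3
oracle_boundary_band <- function(m, r = 2) {
  b <- m - oracle_erode(m, 1)
  oracle_dilate(b, r)
}

# brute-force HD95 from all-pairs distances between boundary point sets
oracle_hd95_px <- function(pred, g) {
  bp <- function(m) {
    b <- m - oracle_erode(m, 1)
    which(b > 0.5, arr.ind = TRUE)
  }
  a <- bp(pred); b <- bp(g)
  dmat <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  as.numeric(quantile(c(d_ab, d_ba), 0.95, type = 7))
}

# small disk mask helper (0-based centre coords)
disk_mask <- function(n, cx, cy, r) {
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  (sqrt((xs - cx)^2 + (ys - cy)^2) <= r) * 1
}

tiny_model_config <- function(...) {
  model_config(widths = c(16L, 24L, 32L, 48L), decoder_channels = 16L,
               rim_n_theta = 90L, ...)
}
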