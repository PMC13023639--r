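# Boundary-aware Attention Module: Laplacian-of-Gaussian edge extraction and
# edge-modulated query attention inside non-overlapping 7x7 windows.

#' Discretised Laplacian-of-Gaussian kernel
#' @param sigma Gaussian std in pixels
#' @return square kernel matrix with zero sum
#' @export
log_kernel <- function(sigma) {
  if (sigma <= 0) stop("log_kernel: sigma must be positive")
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  xs <- (-r):r
  g <- outer(xs, xs, function(x, y) {
    (x^2 + y^2 - 2 * sigma^2) / sigma^4 * exp(-(x^2 + y^2) / (2 * sigma^2))
  })
  g - mean(g)   # zero response to constants
}

#' Laplacian-of-Gaussian edge map
#'
#' Marks pixels where the absolute LoG response of the channel mean exceeds a
#' prominence threshold: the per-map 90th percentile of `|response|`
#' (`tau_mode = "quantile"`) or a fixed value. Computed with reflect padding;
#' constant inputs give an empty map. The binary map is treated as a constant
#' during backpropagation.
#'
#' @param f feature map (matrix or `(H, W, C)` array)
#' @param sigma Gaussian std in pixels (default 1)
#' @param tau_mode `"quantile"` or `"fixed"`
#' @param tau_value quantile level (default 0.9) or fixed threshold
#' @return binary `(H, W)` matrix of class-less 0/1 values
#' @export
log_edge_map <- function(f, sigma = 1.0, tau_mode = c("quantile", "fixed"),
                         tau_value = NULL) {
  tau_mode <- match.arg(tau_mode)
  k <- log_kernel(sigma)
  r <- (nrow(k) - 1L) %/% 2L
  fx <- as_hwc(f); fx <- if (is_node(fx)) val(fx) else fx
  m <- val(ad_channel_mean(ad_const(fx)))
  resp <- val(ad_conv2d(ad_pad(ad_const(m), r, r, r, r, "reflect"),
                        ad_const(array(k, c(dim(k), 1, 1)))))
  a <- abs(matrix(resp, dim(fx)[1], dim(fx)[2]))
  tau <- if (tau_mode == "quantile") {
    as.numeric(quantile(a, if (is.null(tau_value)) 0.9 else tau_value))
  } else {
    if (is.null(tau_value)) stop("log_edge_map: tau_value required for fixed mode")
    tau_value
  }
  (a > tau) * 1
}

#' Window attention parameters (trainable)
#'
#' @param channels feature channels C
#' @param window window side (default 7)
#' @param d key dimension (default C)
#' @param heads attention head count (C and d must be divisible by it)
#' @return module list
#' @export
bam_new <- function(channels, window = 7L, d = NULL, heads = 1L) {
  if (window < 1L) stop("bam_new: window must be >= 1")
  if (is.null(d)) d <- channels
  if (d < 1L) stop("bam_new: key dimension must be >= 1")
  stopifnot(d %% heads == 0L, channels %% heads == 0L)
  list(wq = nn_linear(channels, d), wk = nn_linear(channels, d),
       wv = nn_linear(channels, channels),
       window = as.integer(window), d = as.integer(d),
       heads = as.integer(heads), channels = channels)
}

ad_cols <- function(x, idx) {
  x <- if (is_node(x)) x else ad_const(x)
  dm <- dim(x$value)
  y <- x$value[, idx, drop = FALSE]
  new_node(y, list(x), function(g) {
    dx <- matrix(0, dm[1], dm[2])
    dx[, idx] <- g
    acc_grad(x, dx)
  }, node_requires(x))
}

window_starts <- function(n, win) seq.int(1L, n, by = win)

#' Partition a map into non-overlapping windows (padding to multiples)
#'
#' @param x `(H, W)` matrix or `(H, W, C)` array
#' @param win window side
#' @return list with `windows` (list of `(win, win, C)` arrays, column-major
#'   window order), `H`, `W` (original size) and padded size
#' @export
window_partition <- function(x, win) {
  x <- as_hwc(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  Hp <- ceiling(H / win) * win; Wp <- ceiling(W / win) * win
  if (win > Hp || win > Wp) stop("window_partition: window larger than padded map")
  xp <- val(ad_pad(ad_const(x), 0, Hp - H, 0, Wp - W, "replicate"))
  wins <- list()
  for (cs in window_starts(Wp, win)) for (rs in window_starts(Hp, win)) {
    wins[[length(wins) + 1L]] <- xp[rs:(rs + win - 1L), cs:(cs + win - 1L), , drop = FALSE]
  }
  list(windows = wins, H = H, W = W, Hp = Hp, Wp = Wp, win = win)
}

#' Reassemble windows produced by [window_partition()]
#' @param part a `window_partition()` result (windows possibly modified)
#' @return `(H, W, C)` array cropped to the original size
#' @export
window_unpartition <- function(part) {
  win <- part$win
  C <- dim(part$windows[[1]])[3]
  out <- array(0, c(part$Hp, part$Wp, C))
  k <- 0L
  for (cs in window_starts(part$Wp, win)) for (rs in window_starts(part$Hp, win)) {
    k <- k + 1L
    out[rs:(rs + win - 1L), cs:(cs + win - 1L), ] <- part$windows[[k]]
  }
  out[seq_len(part$H), seq_len(part$W), , drop = FALSE]
}

#' Edge-modulated attention within local windows
#'
#' Partitions `f` into non-overlapping `win x win` windows (replicate-padded
#' to multiples, cropped after) and computes, per window,
#' `Softmax( Wq(E ⊙ f) Wk(f)^T / sqrt(d_head) ) Wv(f)`, residually added to
#' `f`. Attention rows sum to one; the edge map `E` modulates only the query
#' path so that boundary pixels drive where attention looks.
#'
#' @param f feature map `(H, W, C)` (array or node)
#' @param E binary edge map `(H, W)`
#' @param mod a [bam_new()] module
#' @param return_attn also return the per-window attention matrices
#' @return feature map like `f`, or `list(out, attn)` when `return_attn`
#' @export
edge_windowed_attention <- function(f, E, mod, return_attn = FALSE) {
  fx <- as_hwc(f)
  fn <- if (is_node(fx)) fx else ad_const(fx)
  dm <- dim(val(fn)); H <- dm[1]; W <- dm[2]; C <- dm[3]
  if (!all(dim(E)[1:2] == c(H, W)))
    stop("edge_windowed_attention: edge map not aligned with features")
  win <- mod$window
  Hp <- ceiling(H / win) * win; Wp <- ceiling(W / win) * win
  if (win > Hp || win > Wp) stop("edge_windowed_attention: window larger than padded map")
  fp <- if (Hp > H || Wp > W) ad_pad(fn, 0, Hp - H, 0, Wp - W, "replicate") else fn
  Ep <- matrix(val(ad_pad(ad_const(array(E, c(H, W, 1))), 0, Hp - H, 0, Wp - W,
                          "replicate")), Hp, Wp)
  nh <- mod$heads; dh <- mod$d %/% nh; ch <- C %/% nh
  canvas <- NULL
  attns <- list()
  for (cs in window_starts(Wp, win)) for (rs in window_starts(Hp, win)) {
    fw <- ad_crop(fp, rs, rs + win - 1L, cs, cs + win - 1L)
    tok <- ad_reshape(fw, c(win * win, C))
    ew <- as.numeric(Ep[rs:(rs + win - 1L), cs:(cs + win - 1L)])
    tok_m <- ad_mul(tok, ad_const(matrix(ew, win * win, C)))
    Q <- mod$wq$fwd(tok_m); K <- mod$wk$fwd(tok); V <- mod$wv$fwd(tok)
    outs <- NULL
    for (h in seq_len(nh)) {
      qi <- ((h - 1L) * dh + 1L):(h * dh)
      ci <- ((h - 1L) * ch + 1L):(h * ch)
      A <- ad_softmax_rows(ad_cmul(ad_matmul(ad_cols(Q, qi), ad_cols(K, qi), tb = TRUE),
                                   1 / sqrt(dh)))
      if (return_attn) attns[[length(attns) + 1L]] <- val(A)
      oh <- ad_matmul(A, ad_cols(V, ci))
      outs <- if (is.null(outs)) oh else {
        # concatenate head outputs along columns
        a <- outs; b <- oh
        da <- dim(val(a)); db <- dim(val(b))
        y <- cbind(val(a), val(b))
        new_node(y, list(a, b), function(g) {
          acc_grad(a, g[, seq_len(da[2]), drop = FALSE])
          acc_grad(b, g[, da[2] + seq_len(db[2]), drop = FALSE])
        }, node_requires(a, b))
      }
    }
    wout <- ad_reshape(outs, c(win, win, C))
    placed <- local({
      rs0 <- rs; cs0 <- cs
      new_node({
        z <- array(0, c(Hp, Wp, C))
        z[rs0:(rs0 + win - 1L), cs0:(cs0 + win - 1L), ] <- val(wout)
        z
      }, list(wout), function(g) {
        dim(g) <- c(Hp, Wp, C)
        acc_grad(wout, g[rs0:(rs0 + win - 1L), cs0:(cs0 + win - 1L), , drop = FALSE])
      }, node_requires(wout))
    })
    canvas <- if (is.null(canvas)) placed else ad_add(canvas, placed)
  }
  outp <- ad_add(fp, canvas)
  out <- if (Hp > H || Wp > W) ad_crop(outp, 1L, H, 1L, W) else outp
  res <- if (is_node(f)) out else val(out)
  if (return_attn) list(out = res, attn = attns) else res
}

#' Full boundary-aware attention forward pass
#'
#' Extracts the LoG edge map of `f` (treated as a constant for gradients) and
#' applies [edge_windowed_attention()].
#'
#' @param f feature map (array or node)
#' @param mod a [bam_new()] module
#' @param sigma LoG Gaussian std
#' @param tau_mode,tau_value threshold mode, see [log_edge_map()]
#' @return feature map like `f`
#' @export
bam_forward <- function(f, mod, sigma = 1.0, tau_mode = "quantile", tau_value = NULL) {
  E <- log_edge_map(val(as_hwc(f)), sigma = sigma, tau_mode = tau_mode,
                    tau_value = tau_value)
  edge_windowed_attention(f, E, mod)
}
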