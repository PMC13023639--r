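# Differentiable operations. Each ad_* function accepts nodes or plain arrays,
# computes the forward value eagerly and, when gradients are required, records
# a node whose $backward closure accumulates into its parents.
#
# Feature maps are arrays dim = c(H, W, C); token matrices are (n, d);
# scalars are length-1 numerics.

same_or_scalar <- function(a, b) length(a) == 1L || length(b) == 1L ||
  identical(dim(a), dim(b)) || (is.null(dim(a)) && is.null(dim(b)) && length(a) == length(b))

reduce_like <- function(g, ref) {
  # collapse a gradient to the shape of `ref` (scalar broadcast case)
  if (length(ref) == 1L && length(g) > 1L) sum(g) else g
}

ad_add <- function(a, b) {
  a <- if (is_node(a)) a else ad_const(a); b <- if (is_node(b)) b else ad_const(b)
  stopifnot(same_or_scalar(a$value, b$value))
  new_node(a$value + b$value, list(a, b), function(g) {
    acc_grad(a, reduce_like(g, a$value)); acc_grad(b, reduce_like(g, b$value))
  }, node_requires(a, b))
}

ad_sub <- function(a, b) {
  a <- if (is_node(a)) a else ad_const(a); b <- if (is_node(b)) b else ad_const(b)
  new_node(a$value - b$value, list(a, b), function(g) {
    acc_grad(a, reduce_like(g, a$value)); acc_grad(b, reduce_like(-g, b$value))
  }, node_requires(a, b))
}

ad_neg <- function(a) {
  a <- if (is_node(a)) a else ad_const(a)
  new_node(-a$value, list(a), function(g) acc_grad(a, -g), node_requires(a))
}

ad_mul <- function(a, b) {
  a <- if (is_node(a)) a else ad_const(a); b <- if (is_node(b)) b else ad_const(b)
  stopifnot(same_or_scalar(a$value, b$value))
  av <- a$value; bv <- b$value
  new_node(av * bv, list(a, b), function(g) {
    acc_grad(a, reduce_like(g * bv, av)); acc_grad(b, reduce_like(g * av, bv))
  }, node_requires(a, b))
}

ad_div <- function(a, b) {
  a <- if (is_node(a)) a else ad_const(a); b <- if (is_node(b)) b else ad_const(b)
  av <- a$value; bv <- b$value
  new_node(av / bv, list(a, b), function(g) {
    acc_grad(a, reduce_like(g / bv, av))
    acc_grad(b, reduce_like(-g * av / (bv * bv), bv))
  }, node_requires(a, b))
}

ad_cmul <- function(a, k) {
  a <- if (is_node(a)) a else ad_const(a)
  new_node(a$value * k, list(a), function(g) acc_grad(a, g * k), node_requires(a))
}

ad_cadd <- function(a, k) {
  a <- if (is_node(a)) a else ad_const(a)
  new_node(a$value + k, list(a), function(g) acc_grad(a, g), node_requires(a))
}

ad_pow_const <- function(a, p) {
  a <- if (is_node(a)) a else ad_const(a)
  av <- a$value
  new_node(av^p, list(a), function(g) acc_grad(a, g * p * av^(p - 1)), node_requires(a))
}

ad_sigmoid <- function(a) {
  a <- if (is_node(a)) a else ad_const(a)
  y <- 1 / (1 + exp(-a$value))
  new_node(y, list(a), function(g) acc_grad(a, g * y * (1 - y)), node_requires(a))
}

ad_relu <- function(a) {
  a <- if (is_node(a)) a else ad_const(a)
  m <- a$value > 0
  new_node(a$value * m, list(a), function(g) acc_grad(a, g * m), node_requires(a))
}

ad_sum <- function(a) {
  a <- if (is_node(a)) a else ad_const(a)
  dm <- dim(a$value)
  new_node(sum(a$value), list(a), function(g) {
    gg <- array(as.numeric(g), dim = if (is.null(dm)) length(a$value) else dm)
    if (is.null(dm)) gg <- as.numeric(gg)
    acc_grad(a, gg)
  }, node_requires(a))
}

ad_mean <- function(a) ad_cmul(ad_sum(a), 1 / length(val(a)))

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- if (is_node(a)) a else ad_const(a); b <- if (is_node(b)) b else ad_const(b)
  av <- a$value; bv <- b$value
  y <- if (!ta && !tb) av %*% bv else if (ta && !tb) crossprod(av, bv)
       else if (!ta && tb) tcrossprod(av, bv) else t(bv %*% av)
  new_node(y, list(a, b), function(g) {
    if (!ta && !tb) { acc_grad(a, tcrossprod(g, bv)); acc_grad(b, crossprod(av, g)) }
    else if (ta && !tb) { acc_grad(a, tcrossprod(bv, g)); acc_grad(b, av %*% g) }
    else if (!ta && tb) { acc_grad(a, g %*% bv); acc_grad(b, crossprod(g, av)) }
    else { acc_grad(a, t(bv) %*% t(g)); acc_grad(b, t(g) %*% t(av)) }
  }, node_requires(a, b))
}

ad_transpose <- function(a) {
  a <- if (is_node(a)) a else ad_const(a)
  new_node(t(a$value), list(a), function(g) acc_grad(a, t(g)), node_requires(a))
}

ad_reshape <- function(a, dm) {
  a <- if (is_node(a)) a else ad_const(a)
  odm <- dim(a$value)
  y <- a$value; dim(y) <- dm
  new_node(y, list(a), function(g) {
    dim(g) <- odm
    acc_grad(a, g)
  }, node_requires(a))
}

ad_softmax_rows <- function(a) {
  a <- if (is_node(a)) a else ad_const(a)
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  new_node(y, list(a), function(g) {
    acc_grad(a, y * (g - rowSums(g * y)))
  }, node_requires(a))
}

ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- if (is_node(a)) a else ad_const(a)
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  gv <- val(gamma); bv <- val(beta)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, bv, "+")
  new_node(y, list(a, gamma, beta), function(g) {
    acc_grad(gamma, colSums(g * xhat))
    acc_grad(beta, colSums(g))
    gh <- sweep(g, 2L, gv, "*")
    dx <- istd * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
    acc_grad(a, dx)
  }, node_requires(a, gamma, beta))
}

# -- spatial ops -------------------------------------------------------------

PAD_MODES <- c(zero = 0L, reflect = 1L, replicate = 2L)

ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, pad_mode = "zero") {
  x <- if (is_node(x)) x else ad_const(x)
  w <- if (is_node(w)) w else ad_const(w)
  bnode <- if (!is.null(b)) { if (is_node(b)) b else ad_const(b) } else NULL
  xv <- x$value; wv <- w$value
  bv <- if (is.null(bnode)) numeric(0) else as.numeric(bnode$value)
  md <- PAD_MODES[[pad_mode]]
  y <- .conv2d_fwd(xv, dim(xv), wv, dim(wv), bv, as.integer(stride),
                   as.integer(pad), md)
  new_node(y, c(list(x, w), if (!is.null(bnode)) list(bnode)), function(g) {
    need_dx <- x$requires
    r <- .conv2d_bwd(xv, dim(xv), wv, dim(wv), as.numeric(g), as.integer(stride),
                     as.integer(pad), md, need_dx)
    acc_grad(w, r$dw)
    if (!is.null(bnode)) acc_grad(bnode, r$db)
    if (need_dx) acc_grad(x, r$dx)
  }, node_requires(x, w, bnode))
}

pad_index <- function(n, lo, hi, mode) {
  idx <- seq.int(1L - lo, n + hi)
  if (mode == "zero") { idx[idx < 1L | idx > n] <- NA_integer_; return(idx) }
  if (mode == "replicate") return(pmin(pmax(idx, 1L), n))
  # reflect (without repeating the edge sample)
  if (n == 1L) return(rep(1L, length(idx)))
  per <- 2L * (n - 1L)
  m <- (idx - 1L) %% per
  m[m > (n - 1L)] <- per - m[m > (n - 1L)]
  m + 1L
}

ad_pad <- function(x, top, bottom, left, right, mode = c("zero", "reflect", "replicate")) {
  mode <- match.arg(mode)
  x <- if (is_node(x)) x else ad_const(x)
  xv <- x$value
  dm <- dim(xv); H <- dm[1]; W <- dm[2]; C <- dm[3]
  ri <- pad_index(H, top, bottom, mode)
  ci <- pad_index(W, left, right, mode)
  rii <- ri; rii[is.na(rii)] <- 1L
  cii <- ci; cii[is.na(cii)] <- 1L
  y <- xv[rii, cii, , drop = FALSE]
  if (anyNA(ri)) y[is.na(ri), , ] <- 0
  if (anyNA(ci)) y[, is.na(ci), ] <- 0
  Hp <- length(ri); Wp <- length(ci)
  new_node(y, list(x), function(g) {
    dim(g) <- c(Hp, Wp, C)
    if (anyNA(ri)) g[is.na(ri), , ] <- 0
    if (anyNA(ci)) g[, is.na(ci), ] <- 0
    m <- matrix(g, Hp, Wp * C)
    a <- rowsum(m, group = rii, reorder = TRUE)          # (H', Wp*C), H' = sorted unique
    full <- matrix(0, H, Wp * C); full[as.integer(rownames(a)), ] <- a
    dim(full) <- c(H, Wp, C)
    m2 <- matrix(aperm(full, c(2, 1, 3)), Wp, H * C)
    a2 <- rowsum(m2, group = cii, reorder = TRUE)
    full2 <- matrix(0, W, H * C); full2[as.integer(rownames(a2)), ] <- a2
    dim(full2) <- c(W, H, C)
    acc_grad(x, aperm(full2, c(2, 1, 3)))
  }, node_requires(x))
}

ad_crop <- function(x, r0, r1, c0, c1) {
  x <- if (is_node(x)) x else ad_const(x)
  xv <- x$value; dm <- dim(xv)
  y <- xv[r0:r1, c0:c1, , drop = FALSE]
  new_node(y, list(x), function(g) {
    dx <- array(0, dm)
    dim(g) <- dim(y)
    dx[r0:r1, c0:c1, ] <- g
    acc_grad(x, dx)
  }, node_requires(x))
}

ad_channel_mean <- function(x) {
  x <- if (is_node(x)) x else ad_const(x)
  xv <- x$value; dm <- dim(xv); C <- dm[3]
  y <- array(rowMeans(matrix(xv, dm[1] * dm[2], C)), c(dm[1], dm[2], 1L))
  new_node(y, list(x), function(g) {
    acc_grad(x, array(rep(as.numeric(g) / C, C), dm))
  }, node_requires(x))
}

ad_mean_dim2 <- function(x) {
  # (T, R, C) -> (T, C): mean over the second (radial) axis
  x <- if (is_node(x)) x else ad_const(x)
  xv <- x$value; dm <- dim(xv); Tn <- dm[1]; Rn <- dm[2]; C <- dm[3]
  y <- colSums(matrix(aperm(xv, c(2, 1, 3)), Rn, Tn * C)) / Rn
  dim(y) <- c(Tn, C)
  new_node(y, list(x), function(g) {
    dim(g) <- c(Tn, C)
    acc_grad(x, aperm(array(rep(g / Rn, Rn), c(Tn, C, Rn)), c(1, 3, 2)))
  }, node_requires(x))
}

ad_scale_channels <- function(x, wgt) {
  # multiply map (H,W,C) by per-channel weights (length C)
  x <- if (is_node(x)) x else ad_const(x)
  wgt <- if (is_node(wgt)) wgt else ad_const(wgt)
  xv <- x$value; dm <- dim(xv); C <- dm[3]
  wv <- as.numeric(wgt$value)
  stopifnot(length(wv) == C)
  wfull <- rep(wv, each = dm[1] * dm[2])
  y <- xv * array(wfull, dm)
  new_node(y, list(x, wgt), function(g) {
    acc_grad(x, g * array(wfull, dm))
    dw <- colSums(matrix(g * xv, dm[1] * dm[2], C))
    dim(dw) <- dim(wgt$value)
    acc_grad(wgt, dw)
  }, node_requires(x, wgt))
}

ad_mul_gate <- function(x, gate) {
  # multiply every channel of (H,W,C) by a single-channel (H,W,1) gate
  x <- if (is_node(x)) x else ad_const(x)
  gate <- if (is_node(gate)) gate else ad_const(gate)
  xv <- x$value; gv <- gate$value
  dm <- dim(xv); C <- dm[3]
  garr <- array(rep(as.numeric(gv), C), dm)
  new_node(xv * garr, list(x, gate), function(g) {
    acc_grad(x, g * garr)
    dg <- array(rowSums(matrix(g * xv, dm[1] * dm[2], C)), c(dm[1], dm[2], 1L))
    acc_grad(gate, dg)
  }, node_requires(x, gate))
}

ad_grid_sample <- function(x, gy, gx, wrap_rows = FALSE, out_dim = NULL) {
  # sample (H,W,C) at 0-based (row=gy, col=gx); border replicate, optional
  # circular wrap along rows. gy/gx may be nodes (deformable offsets).
  x <- if (is_node(x)) x else ad_const(x)
  gyn <- if (is_node(gy)) gy else NULL
  gxn <- if (is_node(gx)) gx else NULL
  gyv <- as.numeric(val(gy)); gxv <- as.numeric(val(gx))
  shp <- if (!is.null(out_dim)) out_dim else dim(val(gy))
  xv <- x$value; dm <- dim(xv); C <- dm[3]
  y <- .grid_sample_fwd(xv, dm, gyv, gxv, wrap_rows)
  odim <- c(shp[1], shp[2], C)
  dim(y) <- odim
  parents <- c(list(x), if (!is.null(gyn)) list(gyn), if (!is.null(gxn)) list(gxn))
  need_coord <- node_requires(gyn, gxn)
  new_node(y, parents, function(g) {
    r <- .grid_sample_bwd(xv, dm, gyv, gxv, wrap_rows, as.numeric(g),
                          x$requires, need_coord)
    if (x$requires) acc_grad(x, r$dx)
    if (need_coord) {
      if (!is.null(gyn)) { dg <- r$dgy; dim(dg) <- dim(gyn$value); acc_grad(gyn, dg) }
      if (!is.null(gxn)) { dg <- r$dgx; dim(dg) <- dim(gxn$value); acc_grad(gxn, dg) }
    }
  }, node_requires(x, gyn, gxn))
}

ad_maxpool3 <- function(x) {
  x <- if (is_node(x)) x else ad_const(x)
  xv <- x$value; dm <- dim(xv)
  r <- .maxpool3_fwd(xv, dm)
  new_node(r$out, list(x), function(g) {
    acc_grad(x, .maxpool3_bwd(as.numeric(g), dm, r$arg))
  }, node_requires(x))
}

ad_avgpool <- function(x, k) {
  # non-overlapping k x k average pooling; H and W must be divisible by k
  x <- if (is_node(x)) x else ad_const(x)
  if (k == 1L) return(x)
  xv <- x$value; dm <- dim(xv); H <- dm[1]; W <- dm[2]; C <- dm[3]
  stopifnot(H %% k == 0, W %% k == 0)
  pool1 <- function(a, n, k) {
    # collapse first axis of an (n*k, m) matrix by k
    m <- ncol(a)
    dim(a) <- c(k, n %/% k, m)
    colMeans(a)  # (n/k, m)
  }
  m <- pool1(matrix(xv, H, W * C), H, k)                 # (H/k, W*C)
  dim(m) <- c(H %/% k, W, C)
  m2 <- pool1(matrix(aperm(m, c(2, 1, 3)), W, (H %/% k) * C), W, k)
  dim(m2) <- c(W %/% k, H %/% k, C)
  y <- aperm(m2, c(2, 1, 3))
  new_node(y, list(x), function(g) {
    dim(g) <- c(H %/% k, W %/% k, C)
    gg <- g[rep(seq_len(H %/% k), each = k), rep(seq_len(W %/% k), each = k), ,
            drop = FALSE] / (k * k)
    acc_grad(x, gg)
  }, node_requires(x))
}

ad_upsample_bilinear <- function(x, Ho, Wo) {
  xv <- val(x); dm <- dim(xv); H <- dm[1]; W <- dm[2]
  gy <- if (Ho == 1L) rep(0, 1) else (0:(Ho - 1)) * (H - 1) / (Ho - 1)
  gx <- if (Wo == 1L) rep(0, 1) else (0:(Wo - 1)) * (W - 1) / (Wo - 1)
  ad_grid_sample(x, matrix(gy, Ho, Wo), matrix(gx, Ho, Wo, byrow = TRUE))
}

ad_concat_ch <- function(a, b) {
  a <- if (is_node(a)) a else ad_const(a); b <- if (is_node(b)) b else ad_const(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2])
  y <- array(c(a$value, b$value), c(da[1], da[2], da[3] + db[3]))
  new_node(y, list(a, b), function(g) {
    dim(g) <- dim(y)
    acc_grad(a, g[, , seq_len(da[3]), drop = FALSE])
    acc_grad(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  }, node_requires(a, b))
}

ad_slice_ch <- function(x, idx) {
  x <- if (is_node(x)) x else ad_const(x)
  dm <- dim(x$value)
  y <- x$value[, , idx, drop = FALSE]
  new_node(y, list(x), function(g) {
    dx <- array(0, dm)
    dim(g) <- dim(y)
    dx[, , idx] <- g
    acc_grad(x, dx)
  }, node_requires(x))
}

ad_linear <- function(x, w, b = NULL) {
  # fused x %*% w + b (b broadcast over rows)
  x <- if (is_node(x)) x else ad_const(x)
  w <- if (is_node(w)) w else ad_const(w)
  bnode <- if (!is.null(b)) { if (is_node(b)) b else ad_const(b) } else NULL
  xv <- x$value; wv <- w$value
  y <- xv %*% wv
  if (!is.null(bnode)) y <- sweep(y, 2L, as.numeric(bnode$value), "+")
  new_node(y, c(list(x, w), if (!is.null(bnode)) list(bnode)), function(g) {
    acc_grad(x, tcrossprod(g, wv))
    acc_grad(w, crossprod(xv, g))
    if (!is.null(bnode)) acc_grad(bnode, colSums(g))
  }, node_requires(x, w, bnode))
}

ad_add_rowvec <- function(x, b) {
  # add a length-d vector to every row of an (n, d) matrix
  x <- if (is_node(x)) x else ad_const(x)
  b <- if (is_node(b)) b else ad_const(b)
  xv <- x$value; bv <- as.numeric(b$value)
  stopifnot(ncol(xv) == length(bv))
  y <- sweep(xv, 2L, bv, "+")
  new_node(y, list(x, b), function(g) {
    acc_grad(x, g)
    acc_grad(b, colSums(g))
  }, node_requires(x, b))
}

ad_dwconv_theta <- function(x, w) {
  # circular depthwise convolution along the first (angular) axis.
  # x: (T, R, C); w: (L, C), L odd, centered.
  x <- if (is_node(x)) x else ad_const(x)
  w <- if (is_node(w)) w else ad_const(w)
  xv <- x$value; wv <- w$value
  dm <- dim(xv); Tn <- dm[1]; Rn <- dm[2]; C <- dm[3]
  L <- nrow(wv); mid <- (L + 1L) %/% 2L
  stopifnot(L %% 2L == 1L, ncol(wv) == C)
  y <- .dwtheta_fwd(xv, dm, wv)
  new_node(y, list(x, w), function(g) {
    r <- .dwtheta_bwd(xv, dm, wv, as.numeric(g))
    acc_grad(x, r$dx); acc_grad(w, r$dw)
  }, node_requires(x, w))
}
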