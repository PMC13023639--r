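# Deformable Cross-scale Fusion Module: offset prediction from concatenated
# multi-scale features, from-scratch deformable convolution via differentiable
# bilinear gather, and a Sobel-derived edge gate.
#
# OffsetField layout: (H, W, 2K) with K = kernel^2 taps ordered row-major in
# (di, dj) = (ih - mid, iw - mid) with ih fastest; channels 1..K hold the x
# displacements (columns), channels K+1..2K the y displacements (rows), in
# pixels of the low-level feature grid.

ad_slice_tap <- function(w, ih, iw) {
  # extract tap (ih, iw) of a (kh, kw, Cin, Cout) kernel as a 1x1 conv kernel
  w <- if (is_node(w)) w else ad_const(w)
  dm <- dim(w$value)
  y <- w$value[ih, iw, , , drop = FALSE]
  dim(y) <- c(1L, 1L, dm[3], dm[4])
  new_node(y, list(w), function(g) {
    dw <- array(0, dm)
    dim(g) <- c(dm[3], dm[4])
    dw[ih, iw, , ] <- g
    acc_grad(w, dw)
  }, node_requires(w))
}

#' Predict deformable sampling offsets from two feature scales
#'
#' The mid-level map is bilinearly upsampled to the low-level grid (integer
#' scale factor required), concatenated channel-wise with the low-level map
#' and passed through a 3x3 convolution with `2 * kernel^2` output channels.
#' With the zero-initialised predictor of [dcfm_new()] the offsets are
#' identically zero at initialisation.
#'
#' @param f_m mid-level feature map `(H_m, W_m, C_m)` (array or node)
#' @param f_l low-level feature map `(H_l, W_l, C_l)`
#' @param conv the offset prediction conv layer (from [dcfm_new()]; a fresh
#'   zero-initialised one is created when omitted)
#' @param kernel deformable kernel size
#' @return offset field `(H_l, W_l, 2 * kernel^2)`
#' @export
predict_offsets <- function(f_m, f_l, conv = NULL, kernel = 3L) {
  dm_m <- dim(val(as_hwc(f_m))); dm_l <- dim(val(as_hwc(f_l)))
  if (dm_l[1] %% dm_m[1] != 0 || dm_l[2] %% dm_m[2] != 0)
    stop("predict_offsets: mid-level size must divide low-level size (integer scale)")
  if (is.null(conv))
    conv <- nn_conv2d(dm_m[3] + dm_l[3], 2L * kernel^2, k = 3L, zero_init = TRUE)
  fm <- as_hwc(f_m); fl <- as_hwc(f_l)
  fm <- if (is_node(fm)) fm else ad_const(fm)
  fl <- if (is_node(fl)) fl else ad_const(fl)
  up <- if (dm_m[1] == dm_l[1] && dm_m[2] == dm_l[2]) fm
        else ad_upsample_bilinear(fm, dm_l[1], dm_l[2])
  out <- conv$fwd(ad_concat_ch(up, fl))
  if (is_node(f_m) || is_node(f_l)) out else val(out)
}

#' Deformable convolution via differentiable bilinear gather
#'
#' For each output location `p` and kernel tap `p_k`, samples the input at
#' `p + p_k + Delta_p(p, p_k)` by bilinear interpolation with replicate
#' borders, multiplies by the tap weight and sums over taps and channels.
#' Differentiable with respect to input, offsets and kernel. With all-zero
#' offsets this reduces exactly to a standard same-padding convolution.
#'
#' @param x input feature map `(H, W, Cin)` (array or node)
#' @param offsets offset field `(H, W, 2K)` as produced by [predict_offsets()]
#' @param kernel weights `(k, k, Cin, Cout)`
#' @param bias optional length-`Cout` bias
#' @return output feature map `(H, W, Cout)`
#' @export
deformable_conv <- function(x, offsets, kernel, bias = NULL) {
  xn <- as_hwc(x); xn <- if (is_node(xn)) xn else ad_const(xn)
  on <- as_hwc(offsets); on <- if (is_node(on)) on else ad_const(on)
  kn <- if (is_node(kernel)) kernel else ad_const(kernel)
  kd <- dim(val(kn)); kh <- kd[1]; kw <- kd[2]
  stopifnot(kh == kw)
  K <- kh * kw
  dm <- dim(val(xn)); H <- dm[1]; W <- dm[2]
  odm <- dim(val(on))
  if (odm[1] != H || odm[2] != W || odm[3] != 2L * K)
    stop("deformable_conv: offset field shape does not match kernel/input")
  mid <- (kh + 1L) %/% 2L
  base_x <- matrix(rep(0:(W - 1), each = H), H, W)
  base_y <- matrix(rep(0:(H - 1), times = W), H, W)
  bn <- if (!is.null(bias)) { if (is_node(bias)) bias else ad_const(bias) } else NULL
  out <- NULL
  for (iw in seq_len(kw)) {
    for (ih in seq_len(kh)) {
      k <- ih + kh * (iw - 1L)          # tap index, ih fastest
      dxk <- ad_reshape(ad_slice_ch(on, k), c(H, W))
      dyk <- ad_reshape(ad_slice_ch(on, K + k), c(H, W))
      gx <- ad_add(dxk, ad_const(base_x + (iw - mid)))
      gy <- ad_add(dyk, ad_const(base_y + (ih - mid)))
      sampled <- ad_grid_sample(xn, gy, gx)
      term <- ad_conv2d(sampled, ad_slice_tap(kn, ih, iw),
                        if (ih == 1L && iw == 1L) bn else NULL)
      out <- if (is.null(out)) term else ad_add(out, term)
    }
  }
  if (is_node(x) || is_node(offsets) || is_node(kernel)) out else val(out)
}

sobel_x_kernel <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_y_kernel <- function() t(sobel_x_kernel())

#' Sobel-derived edge gate
#'
#' Computes the Sobel gradient magnitude of the channel mean of `f` (3x3
#' kernels, reflect padding), passes it through a 1x1 convolution and a
#' logistic, yielding a single-channel gate strictly inside `(0, 1)`.
#'
#' @param f feature map `(H, W, C)` (array or node)
#' @param conv1x1 the trainable 1x1 conv (from [dcfm_new()]; identity scale
#'   with zero bias when omitted)
#' @return gate map `(H, W, 1)`
#' @export
sobel_edge_gate <- function(f, conv1x1 = NULL) {
  fn <- as_hwc(f); fn <- if (is_node(fn)) fn else ad_const(fn)
  m <- ad_channel_mean(fn)
  kx <- array(sobel_x_kernel(), c(3, 3, 1, 1))
  ky <- array(sobel_y_kernel(), c(3, 3, 1, 1))
  mp <- ad_pad(m, 1, 1, 1, 1, "reflect")
  sx <- ad_conv2d(mp, ad_const(kx))
  sy <- ad_conv2d(mp, ad_const(ky))
  mag <- ad_pow_const(ad_cadd(ad_add(ad_mul(sx, sx), ad_mul(sy, sy)), 1e-12), 0.5)
  z <- if (is.null(conv1x1)) mag else conv1x1$fwd(mag)
  out <- ad_sigmoid(z)
  if (is_node(f)) out else val(out)
}

#' Sobel gradient magnitude of the channel mean (no gating)
#' @param f feature map
#' @return `(H, W, 1)` array of gradient magnitudes
#' @export
sobel_magnitude <- function(f) {
  fn <- ad_const(as_hwc(f))
  m <- ad_channel_mean(fn)
  mp <- ad_pad(m, 1, 1, 1, 1, "reflect")
  sx <- ad_conv2d(mp, ad_const(array(sobel_x_kernel(), c(3, 3, 1, 1))))
  sy <- ad_conv2d(mp, ad_const(array(sobel_y_kernel(), c(3, 3, 1, 1))))
  val(ad_pow_const(ad_cadd(ad_add(ad_mul(sx, sx), ad_mul(sy, sy)), 1e-24), 0.5))
}

#' Deformable Cross-scale Fusion module (trainable)
#'
#' Fuses a low-level map `f_l` with an upsampled mid-level map `f_m`:
#' `out = g ⊙ DConv(f_l, Delta_p) + proj(U(f_m))` where the offsets
#' `Delta_p` are predicted from `Concat(U(f_m), f_l)` and `g` is the Sobel
#' edge gate. The offset predictor is zero-initialised so training starts
#' from a standard convolution.
#'
#' @param c_l,c_m channels of the low- and mid-level inputs
#' @param c_out output channels
#' @param kernel deformable kernel size (default 3)
#' @param gate enable the Sobel edge gate
#' @return module list with `$fwd(f_l, f_m)`
#' @export
dcfm_new <- function(c_l, c_m, c_out = c_l, kernel = 3L, gate = TRUE) {
  mod <- list(
    offset_conv = nn_conv2d(c_l + c_m, 2L * kernel^2, k = 3L, zero_init = TRUE),
    kernel = ad_param(he_init(kernel * kernel * c_l, c(kernel, kernel, c_l, c_out))),
    kbias = ad_param(rep(0, c_out)),
    gate_conv = nn_conv2d(1L, 1L, k = 1L, pad = 0L),
    proj = nn_conv2d(c_m, c_out, k = 1L, pad = 0L),
    gate = gate, ksize = as.integer(kernel))
  mod$fwd <- function(f_l, f_m) {
    dm_l <- dim(val(f_l)); dm_m <- dim(val(f_m))
    up <- if (dm_m[1] == dm_l[1] && dm_m[2] == dm_l[2]) f_m
          else ad_upsample_bilinear(f_m, dm_l[1], dm_l[2])
    off <- mod$offset_conv$fwd(ad_concat_ch(up, f_l))
    fdef <- deformable_conv(f_l, off, mod$kernel, mod$kbias)
    gated <- if (mod$gate) ad_mul_gate(fdef, sobel_edge_gate(f_l, mod$gate_conv)) else fdef
    ad_add(gated, mod$proj$fwd(up))
  }
  mod
}

#' One-shot functional D-CFM forward on plain arrays
#' @param f_l low-level feature map
#' @param f_m mid-level feature map
#' @param mod a [dcfm_new()] module (fresh module created when omitted)
#' @return fused feature map at `f_l`'s spatial size
#' @export
dcfm_forward <- function(f_l, f_m, mod = NULL) {
  fl <- as_hwc(f_l); fm <- as_hwc(f_m)
  if (is.null(mod)) mod <- dcfm_new(dim(fl)[3], dim(fm)[3])
  val(mod$fwd(ad_const(fl), ad_const(fm)))
}
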