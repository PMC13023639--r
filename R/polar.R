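# Radial Intensity Module: differentiable Cartesian <-> polar resampling,
# circular depthwise convolution along the angular axis, and DCT-frequency
# channel attention.
#
# Conventions: 0-based pixel-centre coordinates, origin top-left, y down,
# theta measured from +x toward +y and normalised by pi to (-1, 1]; the radius
# is normalised as r = 2 * dist / (D - 1) so r = 1 on the circle of diameter D.

#' Build a polar sampling grid
#'
#' Precomputes Cartesian sampling locations for `n_theta` uniform angular bins
#' over `(-1, 1]` (in units of pi) and `n_r` radial bins over `[0, 1]`. Bin
#' `(theta, r)` samples Cartesian point
#' `(c_x + r cos(pi theta) (D-1)/2, c_y + r sin(pi theta) (D-1)/2)`.
#'
#' @param height,width source image size
#' @param center `(c_x, c_y)` in 0-based pixel-centre coordinates; default
#'   geometric image centre
#' @param n_theta angular bins (default 720, i.e. 0.5 degree sampling)
#' @param n_r radial bins; default `floor(min(height, width) / 2)`
#' @param diameter normalising diameter `D` in pixels; default `min(height, width)`
#' @return object of class `polar_grid`
#' @export
build_polar_grid <- function(height, width, center = NULL, n_theta = 720L,
                             n_r = NULL, diameter = NULL) {
  if (is.null(center)) center <- c((width - 1) / 2, (height - 1) / 2)
  if (is.null(diameter)) diameter <- min(height, width)
  if (is.null(n_r)) n_r <- max(2L, floor(min(height, width) / 2))
  if (n_theta < 1L || n_r < 1L) stop("build_polar_grid: n_theta and n_r must be >= 1")
  if (diameter < 2) stop("build_polar_grid: diameter must be >= 2")
  if (center[1] < 0 || center[1] > width - 1 || center[2] < 0 || center[2] > height - 1)
    stop("build_polar_grid: center outside image")
  theta <- -1 + 2 * seq_len(n_theta) / n_theta          # (-1, 1], uniform
  r <- if (n_r == 1L) 0 else seq(0, 1, length.out = n_r)
  half <- (diameter - 1) / 2
  sx <- center[1] + outer(cos(pi * theta), r) * half    # n_theta x n_r
  sy <- center[2] + outer(sin(pi * theta), r) * half
  structure(list(height = height, width = width, center = center,
                 n_theta = as.integer(n_theta), n_r = as.integer(n_r),
                 diameter = diameter, theta = theta, r = r,
                 sample_x = sx, sample_y = sy),
            class = "polar_grid")
}

#' Normalised polar coordinates of Cartesian points
#'
#' @param x,y 0-based pixel-centre coordinates
#' @param grid a [build_polar_grid()] grid
#' @return list with `r = 2*dist/(D-1)` and `theta = atan2(dy, dx)/pi`
#' @export
polar_coords <- function(x, y, grid) {
  dx <- x - grid$center[1]; dy <- y - grid$center[2]
  list(r = 2 * sqrt(dx^2 + dy^2) / (grid$diameter - 1),
       theta = atan2(dy, dx) / pi)
}

as_hwc <- function(f) {
  if (is_node(f)) return(f)
  if (is.matrix(f)) f <- array(f, c(dim(f), 1L))
  f
}

#' Resample a feature map onto the polar grid
#'
#' Bilinear interpolation at each grid sample point; out-of-bounds samples use
#' border values. Accepts a matrix, an `(H, W, C)` array or an autodiff node
#' (the mapping is differentiable with respect to the features).
#'
#' @param f feature map (H, W) or (H, W, C), array or node
#' @param grid a `polar_grid` for the same spatial size
#' @return polar feature map `(n_theta, n_r, C)` (array in, array out)
#' @export
cartesian_to_polar <- function(f, grid) {
  fx <- as_hwc(f)
  dm <- dim(val(fx))
  if (dm[1] != grid$height || dm[2] != grid$width)
    stop("cartesian_to_polar: feature map shape does not match grid")
  out <- ad_grid_sample(fx, grid$sample_y, grid$sample_x)
  if (is_node(f)) out else val(out)
}

#' Resample a polar feature map back to Cartesian pixels
#'
#' Every pixel inside the disk of radius `(D-1)/2` is bilinearly sampled from
#' the polar map at its `(r, theta)` address with circular wrap-around in
#' theta; pixels outside the disk take `fallback` (default 0).
#'
#' @param fp polar feature map `(n_theta, n_r, C)`, array or node
#' @param grid the generating `polar_grid`
#' @param out_shape `c(H, W)` output size; default the grid source size
#' @param fallback value (or `(H, W, C)` array) for pixels outside the disk
#' @return Cartesian feature map `(H, W, C)`
#' @export
polar_to_cartesian <- function(fp, grid, out_shape = NULL, fallback = 0) {
  if (is.null(out_shape)) out_shape <- c(grid$height, grid$width)
  if (out_shape[1] < 1 || out_shape[2] < 1) stop("polar_to_cartesian: invalid out_shape")
  fpx <- as_hwc(fp)
  H <- out_shape[1]; W <- out_shape[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  pc <- polar_coords(xs, ys, grid)
  # fractional bin addresses (0-based): theta_i = -1 + 2i/n  =>  i = n(t+1)/2
  gy <- grid$n_theta * (pc$theta + 1) / 2 - 1
  gx <- pc$r * (grid$n_r - 1)
  out <- ad_grid_sample(fpx, gy, gx, wrap_rows = TRUE)
  inside <- (pc$r <= 1) * 1
  C <- dim(val(fpx))[3]
  m <- array(rep(inside, C), c(H, W, C))
  out <- ad_mul(out, ad_const(m))
  if (!identical(fallback, 0)) {
    fb <- if (length(fallback) == 1L) array(fallback, c(H, W, C)) else as_hwc(fallback)
    out <- ad_add(out, ad_const(val(ad_mul(ad_const(fb), ad_const(1 - m)))))
  }
  if (is_node(fp)) out else val(out)
}

#' Orthonormal DCT-II basis matrix
#' @param k retained frequencies (rows)
#' @param n signal length (columns)
#' @return `k x n` matrix `D` with `D[m+1, t+1] = s_m cos(pi (2t+1) m / (2n))`
#' @export
dct_matrix <- function(k, n) {
  m <- 0:(k - 1); t <- 0:(n - 1)
  d <- cos(pi * outer(m, 2 * t + 1) / (2 * n))
  d * c(sqrt(1 / n), rep(sqrt(2 / n), k - 1))[seq_len(k)]
}

#' RIM hyper-parameters
#' @param kernel_theta angular depthwise kernel length (odd, circular)
#' @param dct_k retained DCT frequencies
#' @param bottleneck MLP bottleneck ratio
#' @export
rim_params <- function(kernel_theta = 7L, dct_k = 16L, bottleneck = 4L) {
  if (kernel_theta %% 2L != 1L) stop("rim_params: kernel_theta must be odd")
  if (bottleneck < 1L) stop("rim_params: bottleneck must be >= 1")
  list(kernel_theta = as.integer(kernel_theta), dct_k = as.integer(dct_k),
       bottleneck = as.integer(bottleneck))
}

#' Radial Intensity Module (trainable)
#'
#' Builds the trainable parameters: a per-channel circular depthwise kernel
#' along theta (initialised to the identity delta kernel) and the
#' DCT-attention MLP. The forward pass computes
#' `f + P^{-1}( omega ⊙ DWConv_theta( P(f) ) )` where `P` is the polar
#' resampling and `omega` the per-channel attention weights.
#'
#' @param channels feature channels C
#' @param params a [rim_params()] list
#' @param n_theta,n_r polar grid resolution (defaults as in [build_polar_grid()])
#' @param center_mode one of `"image_center"`, `"dark_centroid"`, `"fixed"`
#' @param center fixed `(x, y)` centre when `center_mode = "fixed"`
#' @return module list with `$fwd(f, image = NULL)`
#' @export
rim_new <- function(channels, params = rim_params(), n_theta = 720L, n_r = NULL,
                    center_mode = c("image_center", "dark_centroid", "fixed"),
                    center = NULL) {
  center_mode <- match.arg(center_mode)
  L <- params$kernel_theta
  w0 <- matrix(0, L, channels); w0[(L + 1L) %/% 2L, ] <- 1   # delta kernel
  hidden <- max(1L, params$dct_k %/% params$bottleneck)
  mod <- list(
    w_theta = ad_param(w0),
    mlp1 = nn_linear(params$dct_k, hidden),
    mlp2 = nn_linear(hidden, 1L, zero_init = TRUE),
    params = params, n_theta = as.integer(n_theta), n_r = n_r,
    center_mode = center_mode, center = center, channels = channels,
    grid_cache = new.env(parent = emptyenv()))
  mod$get_grid <- function(H, W, center) {
    key <- paste(H, W, round(center[1], 4), round(center[2], 4), sep = "_")
    g <- mod$grid_cache[[key]]
    if (is.null(g)) {
      g <- build_polar_grid(H, W, center, n_theta = mod$n_theta, n_r = mod$n_r)
      mod$grid_cache[[key]] <- g
    }
    g
  }
  mod$fwd <- function(f, image = NULL, force_attention_one = FALSE) {
    dm <- dim(val(f))
    ctr <- switch(mod$center_mode,
      image_center = c((dm[2] - 1) / 2, (dm[1] - 1) / 2),
      dark_centroid = {
        stopifnot(!is.null(image))
        sc <- estimate_lumen_center(image)
        sc * c((dm[2] - 1) / max(1, dim(image)[2] - 1),
               (dm[1] - 1) / max(1, dim(image)[1] - 1))
      },
      fixed = mod$center)
    g <- mod$get_grid(dm[1], dm[2], ctr)
    fp <- cartesian_to_polar(if (is_node(f)) f else ad_const(as_hwc(f)), g)
    fc <- ad_dwconv_theta(fp, mod$w_theta)
    om <- if (force_attention_one) ad_const(rep(1, dm[3])) else dct_attention_node(fp, mod)
    branch <- polar_to_cartesian(ad_scale_channels(fc, om), g)
    ad_add(if (is_node(f)) f else ad_const(as_hwc(f)), branch)
  }
  mod
}

dct_attention_node <- function(fp, mod) {
  dmv <- dim(val(fp))
  if (mod$params$dct_k > dmv[1])
    stop("dct_attention: retained frequencies exceed n_theta")
  dk <- dct_matrix(mod$params$dct_k, dmv[1])
  profile <- ad_mean_dim2(fp)                        # (T, C)
  coeffs <- ad_matmul(ad_const(t(dk)), profile, ta = TRUE)  # (k, C)
  h <- ad_relu(mod$mlp1$fwd(ad_transpose(coeffs)))   # (C, hidden)
  ad_sigmoid(mod$mlp2$fwd(h))                        # (C, 1) in (0,1)
}

#' DCT-frequency channel attention weights
#'
#' Computes, per channel, the DCT-II of the radially averaged angular profile,
#' feeds the first `dct_k` coefficients through the bottleneck MLP and a
#' logistic, returning weights in `(0, 1)^C`.
#'
#' @param fp polar feature map `(n_theta, n_r, C)`
#' @param mod a [rim_new()] module (holds the MLP weights)
#' @return numeric vector of C channel weights
#' @export
dct_attention <- function(fp, mod) {
  as.numeric(val(dct_attention_node(ad_const(as_hwc(fp)), mod)))
}

#' Estimate the lumen centre as the weighted centroid of the darkest decile
#' @param image grayscale matrix
#' @return `(x, y)` 0-based coordinates
#' @export
estimate_lumen_center <- function(image) {
  q <- as.numeric(quantile(image, 0.1))
  w <- pmax(q - image, 0)
  if (sum(w) == 0) w <- (image <= q) * 1
  H <- nrow(image); W <- ncol(image)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  c(sum(xs * w), sum(ys * w)) / sum(w)
}

#' RIM forward pass on a plain feature map
#'
#' @param f `(H, W, C)` array (or matrix)
#' @param mod a [rim_new()] module
#' @param image optional source image for the dark-centroid centre estimator
#' @return enhanced feature map, same shape as `f`
#' @export
rim_forward <- function(f, mod, image = NULL) {
  val(mod$fwd(ad_const(as_hwc(f)), image = image))
}
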