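# Training-time augmentation: geometric transforms applied identically to
# image and mask (mask resampled nearest-neighbour and re-binarised),
# photometric transforms applied to the image only.

#' Augmentation configuration
#'
#' @param gaussian_sigma Gaussian noise std as a fraction of the intensity range
#' @param rotation_limit maximum absolute rotation in degrees
#' @param flip_h,flip_v allow horizontal / vertical flips
#' @param scale_range multiplicative scale range, must bracket 1
#' @param translate_frac maximum translation as a fraction of width/height
#' @param elastic_alpha elastic displacement magnitude (pixels, pre-smoothing)
#' @param elastic_sigma Gaussian smoothing std of the displacement field (px)
#' @param brightness_range additive brightness range
#' @param contrast_range multiplicative contrast range
#' @param apply_prob per-transform application probability; either a single
#'   number or a named vector over
#'   `rotation, flip, scale, translate, elastic, gaussian, intensity`
#' @return object of class `augment_config`
#' @export
augment_config <- function(gaussian_sigma = 0.05,
                           rotation_limit = 15,
                           flip_h = TRUE, flip_v = TRUE,
                           scale_range = c(0.9, 1.1),
                           translate_frac = 0.10,
                           elastic_alpha = 50,
                           elastic_sigma = 5,
                           brightness_range = c(-0.1, 0.1),
                           contrast_range = c(0.9, 1.1),
                           apply_prob = 0.5) {
  lim <- c(gaussian_sigma, rotation_limit, translate_frac, elastic_alpha, elastic_sigma)
  if (any(lim < 0)) stop("augment_config: limits must be non-negative")
  if (scale_range[1] > 1 || scale_range[2] < 1)
    stop("augment_config: scale_range must satisfy scale_range[1] <= 1 <= scale_range[2]")
  nm <- c("rotation", "flip", "scale", "translate", "elastic", "gaussian", "intensity")
  if (length(apply_prob) == 1L) apply_prob <- stats::setNames(rep(apply_prob, 7L), nm)
  stopifnot(all(nm %in% names(apply_prob)))
  structure(list(gaussian_sigma = gaussian_sigma, rotation_limit = rotation_limit,
                 flip_h = flip_h, flip_v = flip_v, scale_range = scale_range,
                 translate_frac = translate_frac, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, brightness_range = brightness_range,
                 contrast_range = contrast_range, apply_prob = apply_prob[nm]),
            class = "augment_config")
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(((-r):r)^2) / (2 * sigma^2))
  k / sum(k)
}

smooth_field <- function(f, sigma) {
  # separable Gaussian smoothing with reflect borders (plain matrices)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  kr <- array(k, c(length(k), 1, 1, 1))
  kc <- array(k, c(1, length(k), 1, 1))
  x <- array(f, c(nrow(f), ncol(f), 1))
  x <- val(ad_conv2d(ad_pad(ad_const(x), r, r, 0, 0, "reflect"), kr))
  x <- val(ad_conv2d(ad_pad(ad_const(x), 0, 0, r, r, "reflect"), kc))
  matrix(x, nrow(f), ncol(f))
}

sample_bilinear <- function(img, gy, gx) {
  x <- array(img, c(nrow(img), ncol(img), 1))
  matrix(.grid_sample_fwd(x, dim(x), as.numeric(gy), as.numeric(gx), FALSE),
         nrow(gy), ncol(gy))
}

sample_nearest <- function(img, gy, gx) {
  H <- nrow(img); W <- ncol(img)
  i <- pmin(pmax(round(gy), 0), H - 1) + 1
  j <- pmin(pmax(round(gx), 0), W - 1) + 1
  matrix(img[cbind(as.integer(i), as.integer(j))], nrow(gy), ncol(gy))
}

#' Warp an image/mask pair by an affine map plus optional elastic field
#'
#' The affine map is `p' = M (p - c) + c + t` about the image centre `c`;
#' sampling is inverse-warped, bilinear for the image and nearest-neighbour for
#' the mask (then re-binarised). Used by [augment_pair()] and directly in
#' tests of mask/image registration.
#'
#' @param image,mask numeric matrices of identical shape (`mask` may be NULL)
#' @param angle rotation in degrees (counter-clockwise in the y-down frame)
#' @param scale isotropic scale factor
#' @param translate `c(tx, ty)` in pixels
#' @param flip_h,flip_v mirror about the vertical / horizontal axis
#' @param elastic_dx,elastic_dy optional per-pixel displacement fields
#' @return `list(image =, mask =)`
#' @export
warp_pair <- function(image, mask = NULL, angle = 0, scale = 1,
                      translate = c(0, 0), flip_h = FALSE, flip_v = FALSE,
                      elastic_dx = NULL, elastic_dy = NULL) {
  H <- nrow(image); W <- ncol(image)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- angle * pi / 180
  # forward M = R(th) S F ; build inverse mapping output -> input
  sx <- scale * (if (flip_h) -1 else 1)
  sy <- scale * (if (flip_v) -1 else 1)
  m11 <- cos(th) * sx; m12 <- -sin(th) * sy
  m21 <- sin(th) * sx; m22 <- cos(th) * sy
  det <- m11 * m22 - m12 * m21
  i11 <- m22 / det; i12 <- -m12 / det; i21 <- -m21 / det; i22 <- m11 / det
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  px <- xs - cx - translate[1]
  py <- ys - cy - translate[2]
  gx <- i11 * px + i12 * py + cx
  gy <- i21 * px + i22 * py + cy
  if (!is.null(elastic_dx)) { gx <- gx + elastic_dx; gy <- gy + elastic_dy }
  out_img <- sample_bilinear(image, gy, gx)
  out_msk <- if (is.null(mask)) NULL else (sample_nearest(mask, gy, gx) > 0.5) * 1
  list(image = out_img, mask = out_msk)
}

#' Randomly augment an image/mask pair
#'
#' Each transform fires independently with its configured probability.
#' Geometric transforms (rotation, flips, scale, translation, elastic
#' deformation) are applied identically to image and mask; Gaussian noise and
#' brightness/contrast apply to the image only. The mask stays binary.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param mask binary matrix, same shape
#' @param cfg an [augment_config()]
#' @param seed integer RNG seed
#' @return `list(image =, mask =)`
#' @export
augment_pair <- function(image, mask, cfg = augment_config(), seed = 0L) {
  if (!all(dim(image) == dim(mask)))
    stop("augment_pair: image and mask shapes differ")
  with_seed(seed, {
    pr <- cfg$apply_prob
    fire <- runif(7) < pr
    names(fire) <- names(pr)
    angle <- if (fire[["rotation"]]) runif(1, -cfg$rotation_limit, cfg$rotation_limit) else 0
    fh <- fire[["flip"]] && cfg$flip_h && runif(1) < 0.5
    fv <- fire[["flip"]] && cfg$flip_v && runif(1) < 0.5
    sc <- if (fire[["scale"]]) runif(1, cfg$scale_range[1], cfg$scale_range[2]) else 1
    tr <- if (fire[["translate"]])
      c(runif(1, -1, 1) * cfg$translate_frac * ncol(image),
        runif(1, -1, 1) * cfg$translate_frac * nrow(image)) else c(0, 0)
    edx <- edy <- NULL
    if (fire[["elastic"]] && cfg$elastic_alpha > 0) {
      edx <- cfg$elastic_alpha *
        smooth_field(matrix(runif(length(image), -1, 1), nrow(image)), cfg$elastic_sigma)
      edy <- cfg$elastic_alpha *
        smooth_field(matrix(runif(length(image), -1, 1), nrow(image)), cfg$elastic_sigma)
    }
    geom_needed <- angle != 0 || fh || fv || sc != 1 || any(tr != 0) || !is.null(edx)
    if (geom_needed) {
      wp <- warp_pair(image, mask, angle, sc, tr, fh, fv, edx, edy)
      image <- wp$image; mask <- wp$mask
    }
    if (fire[["gaussian"]] && cfg$gaussian_sigma > 0)
      image <- image + matrix(rnorm(length(image), sd = cfg$gaussian_sigma), nrow(image))
    if (fire[["intensity"]]) {
      image <- image * runif(1, cfg$contrast_range[1], cfg$contrast_range[2]) +
        runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    }
    image <- pmin(pmax(image, 0), 1)
    list(image = image, mask = mask)
  })
}
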