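# Composite segmentation loss: soft Dice, BoundaryIoU on 2-pixel dilated
# boundary bands, and Focal Tversky, combined as 0.5/0.3/0.2.
#
# All ratio losses carry a smoothing epsilon in numerator and denominator so
# a perfect prediction scores exactly zero. Soft morphology uses 3x3
# max-pooling (Chebyshev structuring element): dilation = maxpool, erosion =
# -maxpool(-x) with a zero border (outside pixels are background, so masks
# touching the border have a boundary there); on binary inputs this coincides
# with exact morphology.

LOSS_EPS <- 1e-6

#' Loss weights and shape parameters of the composite loss
#'
#' @param w_dice,w_biou,w_ft component weights (defaults 0.5 / 0.3 / 0.2)
#' @param alpha,beta Tversky false-positive / false-negative weights
#'   (defaults 0.3 / 0.7, penalising missed lumen pixels harder)
#' @param gamma focal exponent (default 4/3)
#' @param dilation boundary band dilation radius in pixels (default 2)
#' @export
loss_weights <- function(w_dice = 0.5, w_biou = 0.3, w_ft = 0.2,
                         alpha = 0.3, beta = 0.7, gamma = 4 / 3,
                         dilation = 2L) {
  if (any(c(w_dice, w_biou, w_ft) < 0)) stop("loss_weights: weights must be >= 0")
  if (alpha < 0 || beta < 0) stop("loss_weights: alpha and beta must be >= 0")
  if (gamma <= 0) stop("loss_weights: gamma must be > 0")
  list(w_dice = w_dice, w_biou = w_biou, w_ft = w_ft,
       alpha = alpha, beta = beta, gamma = gamma, dilation = as.integer(dilation))
}

loss_input <- function(x) {
  x <- as_hwc(x)
  if (is_node(x)) x else ad_const(x)
}

check_loss_shapes <- function(p, g) {
  dp <- dim(val(p)); dg <- dim(val(g))
  if (length(val(p)) == 0L || length(val(g)) == 0L) stop("loss: empty input")
  if (!all(dp == dg)) stop("loss: prediction and target shapes differ")
}

dice_loss_node <- function(p, g, eps = LOSS_EPS) {
  inter <- ad_sum(ad_mul(p, g))
  ad_sub(ad_const(1), ad_div(ad_cadd(ad_cmul(inter, 2), eps),
                             ad_cadd(ad_add(ad_sum(p), ad_sum(g)), eps)))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum p + sum g + eps)`; zero iff `p = g`.
#'
#' @param p probability map in `[0, 1]` (matrix, array or node)
#' @param g binary mask, same shape
#' @return scalar loss in `[0, 1]`
#' @export
dice_loss <- function(p, g) {
  pn <- loss_input(p); gn <- loss_input(g)
  check_loss_shapes(pn, gn)
  out <- dice_loss_node(pn, gn)
  if (is_node(p)) out else as.numeric(val(out))
}

erode3_node <- function(x) {
  # 3x3 erosion with zero border: pixels outside the image count as background,
  # so a mask touching the border has a boundary there
  dm <- dim(val(x))
  xp <- ad_pad(x, 1, 1, 1, 1, "zero")
  e <- ad_neg(ad_maxpool3(ad_neg(xp)))
  ad_crop(e, 2L, dm[1] + 1L, 2L, dm[2] + 1L)
}

boundary_band_node <- function(m, dilation = 2L) {
  b <- ad_sub(m, erode3_node(m))     # inner boundary: m - erode(m)
  for (i in seq_len(dilation)) b <- ad_maxpool3(b)
  b
}

#' Extract a dilated boundary band
#'
#' Hard path (binary input): the inner boundary `m XOR erode3(m)` dilated
#' `dilation` times with a 3x3 square (Chebyshev radius `dilation`). The soft
#' path applies the same max-pool morphology to probabilities and converges to
#' the hard band as probabilities binarise.
#'
#' @param m binary mask or probability map
#' @param dilation dilation radius in pixels
#' @return boundary band, same shape as `m`
#' @export
boundary_extract <- function(m, dilation = 2L) {
  if (dilation < 0) stop("boundary_extract: dilation must be >= 0")
  mn <- loss_input(m)
  out <- boundary_band_node(mn, dilation)
  if (is_node(m)) out else {
    b <- val(out)
    if (is.matrix(m)) matrix(b, dim(b)[1], dim(b)[2]) else b
  }
}

biou_loss_node <- function(p, g, dilation = 2L, eps = LOSS_EPS) {
  bp <- boundary_band_node(p, dilation)
  bg <- boundary_band_node(g, dilation)
  inter <- ad_sum(ad_mul(bp, bg))
  union <- ad_sub(ad_add(ad_sum(bp), ad_sum(bg)), inter)
  ad_sub(ad_const(1), ad_div(ad_cadd(inter, eps), ad_cadd(union, eps)))
}

#' BoundaryIoU loss on dilated boundary bands
#'
#' `1 - |B(g) ∩ B(p)| / |B(g) ∪ B(p)|` with bands from [boundary_extract()].
#' For training, `p` may be a soft probability map (soft bands); for
#' evaluation pass `hard = TRUE` to threshold `p` at 0.5 first. Two empty
#' bands give loss 0 (perfect, by convention).
#'
#' @param p probability map or binary mask
#' @param g binary mask
#' @param dilation band dilation radius
#' @param hard threshold `p` at 0.5 before extracting the band
#' @return scalar loss in `[0, 1]`
#' @export
boundary_iou_loss <- function(p, g, dilation = 2L, hard = FALSE) {
  if (hard && !is_node(p)) p <- (p > 0.5) * 1
  pn <- loss_input(p); gn <- loss_input(g)
  check_loss_shapes(pn, gn)
  out <- biou_loss_node(pn, gn, dilation)
  if (is_node(p)) out else as.numeric(val(out))
}

ft_loss_node <- function(p, g, alpha = 0.3, beta = 0.7, gamma = 4 / 3,
                         eps = LOSS_EPS) {
  tp <- ad_sum(ad_mul(p, g))
  fp <- ad_sum(ad_mul(p, ad_sub(ad_const(1), g)))
  fn <- ad_sum(ad_mul(ad_sub(ad_const(1), p), g))
  ti <- ad_div(ad_cadd(tp, eps),
               ad_cadd(ad_add(tp, ad_add(ad_cmul(fp, alpha), ad_cmul(fn, beta))), eps))
  ad_pow_const(ad_sub(ad_const(1), ti), gamma)
}

#' Focal Tversky loss
#'
#' Tversky index `TI = sum(p g) / (sum(p g) + alpha sum p(1-g) + beta sum
#' (1-p) g)` raised to the focal form `(1 - TI)^gamma`.
#'
#' @param p probability map
#' @param g binary mask
#' @param alpha,beta,gamma Tversky/focal parameters
#' @return scalar loss in `[0, 1]` for `gamma >= 1`
#' @export
focal_tversky_loss <- function(p, g, alpha = 0.3, beta = 0.7, gamma = 4 / 3) {
  if (alpha < 0 || beta < 0) stop("focal_tversky_loss: alpha and beta must be >= 0")
  if (gamma <= 0) stop("focal_tversky_loss: gamma must be > 0")
  pn <- loss_input(p); gn <- loss_input(g)
  check_loss_shapes(pn, gn)
  out <- ft_loss_node(pn, gn, alpha, beta, gamma)
  if (is_node(p)) out else as.numeric(val(out))
}

#' Composite OCT segmentation loss
#'
#' `total = w_dice * L_Dice + w_biou * L_BIoU + w_ft * L_FT` with the
#' component losses above.
#'
#' @param p probability map
#' @param g binary mask
#' @param w a [loss_weights()] list
#' @return list with `total` and components `dice`, `biou`, `ft` (numerics for
#'   array input; autodiff nodes for node input)
#' @export
oct_loss <- function(p, g, w = loss_weights()) {
  pn <- loss_input(p); gn <- loss_input(g)
  check_loss_shapes(pn, gn)
  ld <- dice_loss_node(pn, gn)
  lb <- biou_loss_node(pn, gn, w$dilation)
  lf <- ft_loss_node(pn, gn, w$alpha, w$beta, w$gamma)
  tot <- ad_add(ad_cmul(ld, w$w_dice), ad_add(ad_cmul(lb, w$w_biou), ad_cmul(lf, w$w_ft)))
  if (is_node(p)) list(total = tot, dice = ld, biou = lb, ft = lf)
  else list(total = as.numeric(val(tot)), dice = as.numeric(val(ld)),
            biou = as.numeric(val(lb)), ft = as.numeric(val(lf)))
}
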