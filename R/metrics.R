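# Evaluation metrics: Dice, IoU and the 95th-percentile Hausdorff surface
# distance (HD95) at physical pixel spacing.

#' Dice similarity coefficient between binary masks
#'
#' `2 TP / (2 TP + FP + FN)`. Two empty masks score 1 (documented convention).
#'
#' @param pred,g binary masks of identical shape
#' @return fraction in `[0, 1]`
#' @export
dice_score <- function(pred, g) {
  stopifnot(all(dim(pred) == dim(g)))
  p <- pred > 0.5; t <- g > 0.5
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Intersection-over-union between binary masks
#' @inheritParams dice_score
#' @return fraction in `[0, 1]`; both-empty convention 1
#' @export
iou_score <- function(pred, g) {
  stopifnot(all(dim(pred) == dim(g)))
  p <- pred > 0.5; t <- g > 0.5
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

boundary_points <- function(m) {
  # inner boundary pixels of a binary mask, as 0-based (x, y) coordinates
  x <- array((m > 0.5) * 1, c(dim(m)[1], dim(m)[2], 1))
  er <- val(erode3_node(ad_const(x)))
  b <- matrix(x - er, dim(m)[1], dim(m)[2]) > 0.5
  idx <- which(b, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' 95th-percentile Hausdorff surface distance
#'
#' Extracts boundary pixel sets of both masks, pools the two directed
#' point-to-nearest-boundary distance lists and returns their 95th percentile
#' (linear interpolation), in pixels and in millimetres at the given spacing.
#' Symmetric in its arguments. Undefined (error) when either mask is empty.
#'
#' @param pred,g binary masks of identical shape
#' @param spacing_mm isotropic pixel spacing in millimetres (default 0.005,
#'   i.e. 5 micrometres)
#' @return list with `hd95_px` and `hd95_mm`
#' @export
hd95 <- function(pred, g, spacing_mm = 0.005) {
  stopifnot(all(dim(pred) == dim(g)))
  if (sum(pred > 0.5) == 0 || sum(g > 0.5) == 0)
    stop("hd95 undefined: empty mask", call. = FALSE)
  a <- boundary_points(pred); b <- boundary_points(g)
  d_ab <- .nn_min_dist(a * 1.0, b * 1.0)
  d_ba <- .nn_min_dist(b * 1.0, a * 1.0)
  q <- as.numeric(quantile(c(d_ab, d_ba), 0.95, type = 7))
  list(hd95_px = q, hd95_mm = q * spacing_mm)
}

#' Per-image segmentation metrics
#'
#' @param pred binary (or probability, thresholded at 0.5) prediction
#' @param g ground-truth binary mask
#' @param spacing_mm pixel spacing in millimetres
#' @return one-row data.frame with dice, iou, hd95_px, hd95_mm (the HD95
#'   columns are `NA` when undefined for an empty mask)
#' @export
evaluate_masks <- function(pred, g, spacing_mm = 0.005) {
  pb <- (pred > 0.5) * 1
  h <- tryCatch(hd95(pb, g, spacing_mm),
                error = function(e) list(hd95_px = NA_real_, hd95_mm = NA_real_))
  data.frame(dice = dice_score(pb, g), iou = iou_score(pb, g),
             hd95_px = h$hd95_px, hd95_mm = h$hd95_mm)
}

#' Aggregate per-image metrics into mean and standard deviation
#'
#' HD95 values that were undefined (empty masks) are reported via
#' `n_missing_hd95` and excluded from the HD95 mean/sd rather than scored as
#' zero.
#'
#' @param df data.frame of rows from [evaluate_masks()]
#' @return named list of aggregates
#' @export
aggregate_metrics <- function(df) {
  agg <- function(x) list(mean = mean(x, na.rm = TRUE),
                          sd = if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) else 0)
  list(n = nrow(df),
       dice = agg(df$dice), iou = agg(df$iou),
       hd95_px = agg(df$hd95_px), hd95_mm = agg(df$hd95_mm),
       n_missing_hd95 = sum(is.na(df$hd95_px)))
}
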