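# Synthetic intravascular OCT phantoms: a dark circular lumen inside bright
# concentric wall gradients, degraded by multiplicative Rayleigh speckle.
# Phantoms stand in for clinical frames so the whole pipeline is testable.

#' Phantom generation parameters
#'
#' Describes one synthetic vessel cross-section. Intensities are in `[0, 1]`,
#' lengths in pixels. The geometry is a dark lumen disk of `lumen_radius`
#' around `lumen_center`, a bright wall whose intensity ramps linearly to
#' `wall_peak_intensity` at `lumen_radius + wall_thickness/2` and then decays
#' exponentially toward `background_intensity`.
#'
#' @param image_size square image side in pixels
#' @param lumen_center `(x, y)` sub-pixel centre (0-based pixel-centre
#'   coordinates); default geometric image centre
#' @param lumen_radius lumen disk radius in pixels
#' @param wall_thickness vessel wall thickness in pixels
#' @param wall_peak_intensity peak wall brightness
#' @param lumen_intensity intensity of the blood-filled lumen (dark)
#' @param speckle_scale speckle strength in `[0, 1]`: 0 disables noise, 1 uses
#'   a full unit-mean Rayleigh multiplier
#' @param shadow_sector optional `c(start_angle, width)` in degrees for a
#'   guidewire shadow sector, or `NULL`
#' @param background_intensity far-field intensity
#' @return an object of class `phantom_params`
#' @export
phantom_params <- function(image_size = 512L,
                           lumen_center = NULL,
                           lumen_radius = 0.08 * image_size,
                           wall_thickness = 0.05 * image_size,
                           wall_peak_intensity = 0.85,
                           lumen_intensity = 0.05,
                           speckle_scale = 1.0,
                           shadow_sector = NULL,
                           background_intensity = 0.15) {
  if (is.null(lumen_center)) lumen_center <- c((image_size - 1) / 2, (image_size - 1) / 2)
  p <- structure(list(image_size = as.integer(image_size),
                      lumen_center = as.numeric(lumen_center),
                      lumen_radius = lumen_radius,
                      wall_thickness = wall_thickness,
                      wall_peak_intensity = wall_peak_intensity,
                      lumen_intensity = lumen_intensity,
                      speckle_scale = speckle_scale,
                      shadow_sector = shadow_sector,
                      background_intensity = background_intensity),
                 class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$lumen_radius + p$wall_thickness >= p$image_size / 2)
    stop("phantom_params: invariant violated: lumen_radius + wall_thickness < image_size/2")
  if (p$lumen_intensity >= p$wall_peak_intensity)
    stop("phantom_params: invariant violated: lumen_intensity < wall_peak_intensity")
  ints <- c(p$wall_peak_intensity, p$lumen_intensity, p$background_intensity)
  if (any(ints < 0 | ints > 1))
    stop("phantom_params: invariant violated: all intensities in [0, 1]")
  if (p$speckle_scale < 0)
    stop("phantom_params: invariant violated: speckle_scale >= 0")
  if (p$lumen_radius <= 0)
    stop("phantom_params: invariant violated: lumen_radius > 0")
  invisible(p)
}

#' Multiplicative Rayleigh speckle
#'
#' Multiplies the image by `1 + scale * (R - 1)` where `R` is a unit-mean
#' Rayleigh variate (Rayleigh scale `sqrt(2/pi)`, so `E[R] = 1`); the result is
#' clipped to `[0, 1]`. At `scale = 1` the multiplier is exactly Rayleigh
#' distributed; at `scale = 0` the image is returned unchanged. The unit-mean
#' normalisation keeps expected brightness independent of speckle strength.
#'
#' @param image numeric matrix in `[0, 1]`
#' @param scale speckle strength, non-negative
#' @param seed integer RNG seed
#' @return speckled image, same shape
#' @export
apply_speckle <- function(image, scale, seed) {
  if (scale < 0) stop("apply_speckle: scale must be non-negative")
  if (scale == 0) return(image)
  m <- with_seed(seed, {
    u <- runif(length(image))
    sqrt(2 / pi) * sqrt(-2 * log(u))   # Rayleigh with mean 1
  })
  mult <- 1 + scale * (m - 1)
  out <- image * array(mult, dim = dim(image))
  pmin(pmax(out, 0), 1)
}

phantom_profile <- function(p) {
  # deterministic noise-free intensity as a function of centre distance
  n <- p$image_size
  xs <- matrix(rep(0:(n - 1), each = n), n, n)   # x = column coord
  ys <- matrix(rep(0:(n - 1), times = n), n, n)  # y = row coord
  d <- sqrt((xs - p$lumen_center[1])^2 + (ys - p$lumen_center[2])^2)
  rim <- p$lumen_radius + p$wall_thickness / 2
  img <- matrix(p$background_intensity, n, n)
  img[d <= p$lumen_radius] <- p$lumen_intensity
  ramp <- d > p$lumen_radius & d <= rim
  frac <- (d[ramp] - p$lumen_radius) / (p$wall_thickness / 2)
  img[ramp] <- p$lumen_intensity + frac * (p$wall_peak_intensity - p$lumen_intensity)
  outer_zone <- d > rim
  img[outer_zone] <- p$background_intensity +
    (p$wall_peak_intensity - p$background_intensity) *
    exp(-(d[outer_zone] - rim) / p$wall_thickness)
  if (!is.null(p$shadow_sector)) {
    ang <- atan2(ys - p$lumen_center[2], xs - p$lumen_center[1]) * 180 / pi
    a0 <- p$shadow_sector[1]; wd <- p$shadow_sector[2]
    rel <- (ang - a0) %% 360
    in_sector <- rel <= wd & d > p$lumen_radius
    img[in_sector] <- img[in_sector] * 0.35
  }
  list(image = img, dist = d)
}

#' Generate one phantom frame with its ground-truth lumen mask
#'
#' The geometry is deterministic in `params`; only the speckle draw uses
#' `seed`, so identical `(params, seed)` give bit-identical output and the
#' mask is independent of the seed.
#'
#' @param params a [phantom_params()] object
#' @param seed integer RNG seed for the speckle field
#' @return `list(image =, mask =)`, both `image_size x image_size` matrices;
#'   the mask is 1 inside `lumen_radius` of `lumen_center`
#' @export
generate_phantom <- function(params, seed = 0L) {
  validate_phantom_params(params)
  pr <- phantom_profile(params)
  mask <- (pr$dist <= params$lumen_radius) * 1
  img <- apply_speckle(pr$image, params$speckle_scale, seed)
  list(image = img, mask = mask)
}
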