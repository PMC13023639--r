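# Dataset generation and PNG I/O. Phantom datasets are written as filename
# matched 8-bit grayscale pairs (case_0001.png / case_0001_mask.png) with a
# JSON manifest recording split membership, per-case seeds and parameters.

read_gray_png <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

write_gray_png <- function(img, path) {
  ok <- try(png::writePNG(pmin(pmax(img, 0), 1), target = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write image: ", path)
  invisible(path)
}

#' Default phantom parameter sampling ranges
#'
#' Ranges are relative to `image_size` so phantoms keep the same class
#' imbalance at any resolution: the lumen radius fraction range keeps the
#' lumen between roughly 0.6% and 2.5% of the image area.
#'
#' @param image_size square image side in pixels
#' @return named list of ranges consumed by [make_dataset()]
#' @export
default_params_ranges <- function(image_size = 512L) {
  list(image_size = as.integer(image_size),
       radius_frac = c(0.045, 0.09),
       wall_frac = c(0.04, 0.07),
       center_jitter_frac = 0.05,
       wall_peak = c(0.7, 0.95),
       lumen_int = c(0.02, 0.10),
       background = c(0.10, 0.20),
       speckle = c(1.0, 1.0))
}

sample_phantom_params <- function(rg) {
  n <- rg$image_size
  c0 <- (n - 1) / 2
  jit <- rg$center_jitter_frac * n
  phantom_params(
    image_size = n,
    lumen_center = c(c0 + runif(1, -jit, jit), c0 + runif(1, -jit, jit)),
    lumen_radius = runif(1, rg$radius_frac[1], rg$radius_frac[2]) * n,
    wall_thickness = runif(1, rg$wall_frac[1], rg$wall_frac[2]) * n,
    wall_peak_intensity = runif(1, rg$wall_peak[1], rg$wall_peak[2]),
    lumen_intensity = runif(1, rg$lumen_int[1], rg$lumen_int[2]),
    speckle_scale = runif(1, rg$speckle[1], rg$speckle[2]),
    background_intensity = runif(1, rg$background[1], rg$background[2]))
}

#' Write a phantom dataset to disk
#'
#' Generates `n_images` seeded phantoms, writes filename-matched image/mask
#' PNG pairs and a JSON manifest with deterministic train/validation split
#' membership (split by phantom identity).
#'
#' @param n_images number of phantoms
#' @param params_ranges sampling ranges as from [default_params_ranges()]
#' @param out_dir output directory (created if missing)
#' @param split training fraction
#' @param seed integer seed controlling parameters, speckle and the split
#' @return the manifest (invisibly also written to `manifest.json`)
#' @export
make_dataset <- function(n_images, params_ranges = default_params_ranges(),
                         out_dir, split = 0.8, seed = 0L) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("make_dataset: cannot create output directory: ", out_dir)
  items <- list()
  if (n_images > 0) {
    assign_train <- with_seed(seed, {
      n_train <- round(n_images * split)
      ord <- sample.int(n_images)
      seq_len(n_images) %in% ord[seq_len(n_train)]
    })
    for (i in seq_len(n_images)) {
      pars <- with_seed(seed + 1000L + i, sample_phantom_params(params_ranges))
      ph <- generate_phantom(pars, seed = seed + 2000L + i)
      id <- sprintf("case_%04d", i)
      img_file <- paste0(id, ".png"); msk_file <- paste0(id, "_mask.png")
      write_gray_png(ph$image, file.path(out_dir, img_file))
      write_gray_png(ph$mask, file.path(out_dir, msk_file))
      items[[i]] <- list(id = id, image = img_file, mask = msk_file,
                         split = if (assign_train[i]) "train" else "val",
                         seed = seed + 2000L + i,
                         params = unclass(pars))
    }
  }
  manifest <- list(seed = as.integer(seed), split = split,
                   n_images = as.integer(n_images), items = items)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Load a dataset manifest and its images
#' @param dir dataset directory containing `manifest.json`
#' @return list with `manifest` and per-item loader closures
#' @export
load_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
  items <- lapply(mf$items, function(it) {
    list(id = it$id, split = it$split,
         load = local({
           ipath <- file.path(dir, it$image); mpath <- file.path(dir, it$mask)
           function() list(image = read_gray_png(ipath),
                           mask = (read_gray_png(mpath) > 0.5) * 1)
         }))
  })
  list(manifest = mf, items = items)
}
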