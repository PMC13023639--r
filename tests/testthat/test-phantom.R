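test_that("phantom geometry respects the class-imbalance prior and determinism", {
  pp <- phantom_params()
  ph0 <- generate_phantom(pp, seed = 0)
  expect_lt(mean(ph0$mask), 0.03)
  expect_gt(mean(ph0$mask), 0.003)
  # seed changes speckle, never geometry
  ph1 <- generate_phantom(pp, seed = 1)
  expect_identical(ph0$mask, ph1$mask)
  expect_false(identical(ph0$image, ph1$image))
  # bit-identical reproduction
  expect_identical(generate_phantom(pp, seed = 0)$image, ph0$image)
  # mask is exactly the lumen disk
  d <- sqrt(outer((0:(pp$image_size - 1) - pp$lumen_center[2])^2,
                  (0:(pp$image_size - 1) - pp$lumen_center[1])^2, "+"))
  expect_identical(ph0$mask, (d <= pp$lumen_radius) * 1)
})

test_that("zero speckle returns the deterministic radial profile", {
  pp <- phantom_params(image_size = 64, speckle_scale = 0)
  ph <- generate_phantom(pp, seed = 5)
  prof <- octseg:::phantom_profile(pp)
  expect_identical(ph$image, prof$image)
  # dark lumen, bright wall, decaying background
  expect_equal(ph$image[33, 33], pp$lumen_intensity)
  rim <- pp$lumen_radius + pp$wall_thickness / 2
  expect_equal(max(ph$image), pp$wall_peak_intensity, tolerance = 0.05)
})

test_that("invalid phantom parameters name the violated invariant", {
  expect_error(phantom_params(image_size = 64, lumen_radius = 20, wall_thickness = 20),
               "lumen_radius \\+ wall_thickness")
  expect_error(phantom_params(lumen_intensity = 0.9, wall_peak_intensity = 0.8),
               "lumen_intensity < wall_peak_intensity")
  expect_error(phantom_params(background_intensity = 1.4), "intensities in \\[0, 1\\]")
})

test_that("speckle multiplier is unit-mean Rayleigh and degenerates correctly", {
  img <- matrix(0.2, 512, 512)   # low enough that clipping never binds
  out <- apply_speckle(img, scale = 1, seed = 3)
  mult <- out / img
  # closed-form Rayleigh mean sigma*sqrt(pi/2) normalised to 1
  expect_lt(abs(mean(mult) - 1), 0.02)
  expect_identical(apply_speckle(img, scale = 0, seed = 3), img)
  z <- matrix(0, 16, 16)
  expect_identical(apply_speckle(z, scale = 1.5, seed = 3), z)
  expect_error(apply_speckle(img, scale = -1, seed = 0), "non-negative")
  # coarse goodness of fit of the multiplier against the Rayleigh density
  u <- apply_speckle(matrix(1e-9, 400, 400), 1, seed = 11) / 1e-9
  sr <- sqrt(2 / pi)  # Rayleigh scale with unit mean
  th <- stats::pweibull(seq(0, 3, by = 0.5), shape = 2, scale = sr * sqrt(2))
  emp <- stats::ecdf(u)(seq(0, 3, by = 0.5))
  expect_lt(max(abs(th - emp)), 0.02)
})

test_that("augmentation transforms image and mask congruently", {
  pp <- phantom_params(image_size = 64)
  ph <- generate_phantom(pp, seed = 2)
  # identity configuration
  cfg0 <- augment_config(apply_prob = 0)
  a0 <- augment_pair(ph$image, ph$mask, cfg0, seed = 9)
  expect_identical(a0$image, ph$image)
  expect_identical(a0$mask, ph$mask)
  # 180-degree rotation maps a centred disk onto itself
  w <- warp_pair(ph$image, ph$mask, angle = 180)
  expect_equal(mean(w$mask != ph$mask), 0, tolerance = 1e-3)
  # mask/image registration: warp the mask as an image, re-binarise, compare
  wi <- warp_pair(ph$mask, ph$mask, angle = 33, scale = 1.05, translate = c(3, -2))
  expect_lt(mean((wi$image > 0.5) != (wi$mask > 0.5)), 0.01)
  # mask stays binary under every augmentation
  for (sd in 1:5) {
    aa <- augment_pair(ph$image, ph$mask, augment_config(apply_prob = 1), seed = sd)
    expect_true(all(aa$mask %in% c(0, 1)))
    expect_true(all(aa$image >= 0 & aa$image <= 1))
  }
  expect_error(augment_pair(ph$image, ph$mask[1:32, 1:32], seed = 1), "shape")
})

test_that("elastic deformation approximately preserves disk area", {
  n <- 256
  msk <- disk_mask(n, (n - 1) / 2, (n - 1) / 2, 40)
  rel <- sapply(1:20, function(sd) {
    f <- octseg:::with_seed(sd, {
      dx <- 50 * octseg:::smooth_field(matrix(runif(n * n, -1, 1), n), 5)
      dy <- 50 * octseg:::smooth_field(matrix(runif(n * n, -1, 1), n), 5)
      warp_pair(msk, msk, elastic_dx = dx, elastic_dy = dy)$mask
    })
    sum(f) / sum(msk)
  })
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("make_dataset writes deterministic filename-matched splits", {
  td <- withr::local_tempdir()
  mf <- make_dataset(10, default_params_ranges(48), file.path(td, "a"), split = 0.8,
                     seed = 4)
  expect_equal(sum(sapply(mf$items, function(i) i$split == "train")), 8)
  expect_equal(sum(sapply(mf$items, function(i) i$split == "val")), 2)
  expect_true(all(file.exists(file.path(td, "a", sapply(mf$items, `[[`, "image")))))
  expect_true(all(file.exists(file.path(td, "a", sapply(mf$items, `[[`, "mask")))))
  mf2 <- make_dataset(10, default_params_ranges(48), file.path(td, "b"), split = 0.8,
                      seed = 4)
  expect_identical(lapply(mf$items, `[`, c("id", "split", "seed")),
                   lapply(mf2$items, `[`, c("id", "split", "seed")))
  # round-trip through PNG keeps the mask binary and the image 8-bit close
  ds <- load_dataset(file.path(td, "a"))
  d <- ds$items[[1]]$load()
  expect_true(all(d$mask %in% c(0, 1)))
  # empty dataset
  mf0 <- make_dataset(0, default_params_ranges(48), file.path(td, "c"), seed = 1)
  expect_length(mf0$items, 0)
})
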