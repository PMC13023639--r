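test_that("polar grid coordinates satisfy the normalisation identities", {
  g <- build_polar_grid(64, 64, n_theta = 720)
  cx <- g$center[1]; cy <- g$center[2]; D <- g$diameter
  # unit-radius point on the +x axis
  pc <- polar_coords(cx + (D - 1) / 2, cy, g)
  expect_equal(pc$r, 1)
  expect_equal(pc$theta, 0)
  # centre maps to r = 0
  expect_equal(polar_coords(cx, cy, g)$r, 0)
  # straight "down" in the y-down convention: theta = +0.5 at r = 0.5
  pc2 <- polar_coords(cx, cy + (D - 1) / 4, g)
  expect_equal(pc2$r, 0.5)
  expect_equal(pc2$theta, 0.5)
  # grid invariants
  expect_true(all(diff(g$r) > 0))
  expect_equal(diff(g$theta), rep(2 / 720, 719))
  expect_true(all(abs(g$sample_x[, 1] - cx) < 1e-12))
  expect_true(all(abs(g$sample_y[, 1] - cy) < 1e-12))
  expect_error(build_polar_grid(64, 64, diameter = 1), "diameter")
  expect_error(build_polar_grid(64, 64, center = c(100, 0)), "center")
})

test_that("cartesian_to_polar matches rotational symmetry and linearity", {
  n <- 129
  g <- build_polar_grid(n, n, n_theta = 360, n_r = 48)
  cx <- g$center[1]; cy <- g$center[2]
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
  # constant map stays constant
  cst <- cartesian_to_polar(matrix(0.7, n, n), g)
  expect_equal(max(abs(cst - 0.7)), 0)
  # smooth annulus is constant along theta at fixed r (away from ring edges)
  ann <- exp(-((dist - 30) / 8)^2)
  fp <- cartesian_to_polar(ann, g)[, , 1]
  rowvar <- apply(fp, 2, stats::var)
  rowmean2 <- apply(fp, 2, mean)^2
  keep <- rowmean2 > (0.3 * max(fp))^2
  expect_lt(max(rowvar[keep] / rowmean2[keep]), 1e-4)
  # all r = 0 bins sample the centre pixel
  img <- matrix(0, n, n); img[65, 65] <- 1
  fp2 <- cartesian_to_polar(img, g)[, , 1]
  expect_true(all(abs(fp2[, 1] - 1) < 1e-12))
  # exact linearity
  f1 <- matrix(runif(n * n), n, n); f2 <- matrix(runif(n * n), n, n)
  expect_equal(cartesian_to_polar(2 * f1 - 3 * f2, g),
               2 * cartesian_to_polar(f1, g) - 3 * cartesian_to_polar(f2, g))
  expect_error(cartesian_to_polar(matrix(0, 10, 10), g), "shape")
})

test_that("rotating the input cyclically shifts the polar map", {
  n <- 129
  n_theta <- 720
  g <- build_polar_grid(n, n, n_theta = n_theta, n_r = 32)
  cx <- g$center[1]; cy <- g$center[2]
  make_img <- function(delta_rad) {
    xs <- matrix(rep(0:(n - 1), each = n), n, n)
    ys <- matrix(rep(0:(n - 1), times = n), n, n)
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    th <- atan2(ys - cy, xs - cx) - delta_rad
    exp(-((r - 20) / 8)^2) * (1 + 0.5 * cos(3 * th))
  }
  step <- 2 * pi / n_theta              # one angular bin = 0.5 degrees
  for (k in c(1, 5)) {
    f0 <- cartesian_to_polar(make_img(0), g)[, , 1]
    fk <- cartesian_to_polar(make_img(k * step), g)[, , 1]
    shifted <- f0[((seq_len(n_theta) - 1 - k) %% n_theta) + 1, ]
    rng <- diff(range(f0))
    expect_lt(max(abs(fk - shifted)) / rng, 0.02)
  }
})

test_that("polar round trip reconstructs smooth radial images", {
  n <- 65
  g <- build_polar_grid(n, n, n_theta = 720, n_r = 32)
  cx <- g$center[1]; cy <- g$center[2]
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
  img <- 0.2 + 0.6 * exp(-((dist - 14) / 10)^2)
  rec <- polar_to_cartesian(cartesian_to_polar(img, g), g)[, , 1]
  inside <- dist <= 0.9 * (g$diameter - 1) / 2
  rel <- sqrt(sum((rec[inside] - img[inside])^2)) / sqrt(sum(img[inside]^2))
  expect_lt(rel, 0.05)
  # constant polar map -> constant disk
  cst <- polar_to_cartesian(array(0.3, c(720, 32, 1)), g)[, , 1]
  expect_equal(max(abs(cst[inside] - 0.3)), 0, tolerance = 1e-12)
  expect_error(polar_to_cartesian(array(0, c(720, 32, 1)), g, out_shape = c(0, 5)),
               "out_shape")
})

test_that("theta seam reconstructs without wrap-around artifacts", {
  n <- 65
  g <- build_polar_grid(n, n, n_theta = 360, n_r = 32)
  cx <- g$center[1]; cy <- g$center[2]
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)
  th <- atan2(ys - cy, xs - cx)
  # feature centred on theta = pi (the theta = +-1 seam)
  img <- exp(-((r - 16) / 6)^2) * exp(-((abs(abs(th) - pi)) / 0.4)^2)
  rec <- polar_to_cartesian(cartesian_to_polar(img, g), g)[, , 1]
  # rotate the scene 180 degrees so the seam moves to theta = 0
  img2 <- exp(-((r - 16) / 6)^2) * exp(-((abs(th)) / 0.4)^2)
  rec2 <- polar_to_cartesian(cartesian_to_polar(img2, g), g)[, , 1]
  inside <- r <= 0.9 * (g$diameter - 1) / 2
  err1 <- max(abs(rec - img)[inside])
  err2 <- max(abs(rec2 - img2)[inside])
  expect_lt(abs(err1 - err2), 0.05)
  expect_lt(err1, 0.1)
})

test_that("DCT attention recovers single frequencies and degenerate cases", {
  n_theta <- 64
  dk <- dct_matrix(16, n_theta)
  # constant profile: only the DC coefficient is nonzero
  cst <- dk %*% rep(2, n_theta)
  expect_lt(max(abs(cst[-1])), 1e-12)
  # pure cosine at frequency m excites exactly coefficient m
  for (m in c(3, 9)) {
    v <- cos(pi * (2 * (0:(n_theta - 1)) + 1) * m / (2 * n_theta))
    coef <- as.numeric(dk %*% v)
    expect_equal(coef, oracle_dct2(v, 16), tolerance = 1e-12)
    expect_gt(abs(coef[m + 1]), 1)
    expect_lt(max(abs(coef[-(m + 1)])), 1e-10)
  }
  # zero-weight MLP gives sigma(0) = 0.5 per channel
  mod <- octseg:::with_seed(1, rim_new(4, rim_params(dct_k = 8), n_theta = 32, n_r = 8))
  mod$mlp1$w$value[] <- 0; mod$mlp1$b$value[] <- 0
  mod$mlp2$w$value[] <- 0; mod$mlp2$b$value[] <- 0
  fp <- array(runif(32 * 8 * 4), c(32, 8, 4))
  expect_equal(dct_attention(fp, mod), rep(0.5, 4))
  # retained frequencies must not exceed n_theta
  bad <- octseg:::with_seed(1, rim_new(2, rim_params(dct_k = 64), n_theta = 32, n_r = 4))
  expect_error(dct_attention(array(0, c(32, 4, 2)), bad), "exceed")
})

test_that("rim_forward reduces to f + round_trip(f) with identity settings", {
  n <- 64
  mod <- octseg:::with_seed(2, rim_new(2, rim_params(kernel_theta = 7, dct_k = 8),
                                       n_theta = 360, n_r = 24))
  # delta kernel is already the init; force attention to one
  cx <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  dist <- sqrt((xs - cx)^2 + (ys - cx)^2)
  f <- array(0.2 + 0.6 * exp(-((dist - 12) / 8)^2), c(n, n, 2))
  out <- nodeval(mod$fwd(ad_const(f), force_attention_one = TRUE))
  g <- build_polar_grid(n, n, n_theta = 360, n_r = 24)
  rt <- polar_to_cartesian(cartesian_to_polar(f, g), g)
  inside <- array(rep(dist <= 0.9 * (g$diameter - 1) / 2, 2), dim(f))
  rel <- sqrt(sum(((out - f) - rt)[inside]^2)) / sqrt(sum(f[inside]^2))
  expect_lt(rel, 1e-10)   # identical round trip path
  rel2 <- sqrt(sum((out[inside] - 2 * f[inside])^2)) / sqrt(sum(f[inside]^2))
  expect_lt(rel2, 0.05)
  # zero input -> zero output
  z <- array(0, c(n, n, 2))
  expect_equal(max(abs(rim_forward(z, mod))), 0)
  # gradients flow through the module
  p <- ad_param(f)
  ad_with_tape({
    loss <- ad_sum(octseg:::ad_pow_const(mod$fwd(p), 2))
    ad_backward(loss)
  })
  expect_true(all(is.finite(p$grad)))
  expect_gt(max(abs(p$grad)), 0)
})

test_that("dark-centroid centre estimator finds an off-centre lumen", {
  pp <- phantom_params(image_size = 96, lumen_center = c(40, 58),
                       speckle_scale = 0.3)
  ph <- generate_phantom(pp, seed = 1)
  est <- estimate_lumen_center(ph$image)
  expect_lt(sqrt(sum((est - c(40, 58))^2)), 6)
})
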