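test_that("dice loss identities and worked example", {
  g <- matrix(0, 8, 8); g[3:4, 3:4] <- 1          # |Y| = 4
  p <- matrix(0, 8, 8); p[4:5, 3:4] <- 1          # |X| = 4, overlap 2
  expect_equal(dice_loss(p, g), 0.5, tolerance = 1e-6)
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-9)
  expect_equal(dice_loss(matrix(0, 8, 8), g), 1, tolerance = 1e-5)
  expect_error(dice_loss(matrix(0, 0, 0), matrix(0, 0, 0)), "empty")
  expect_error(dice_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "shapes")
})

test_that("focal tversky loss: identities, worked counts, dice reduction", {
  g <- matrix(0, 6, 6); g[2:4, 2:4] <- 1
  expect_equal(focal_tversky_loss(g, g), 0, tolerance = 1e-8)
  # counts TP = 8, FP = 2, FN = 2 -> TI = 0.8, loss = 0.2^(4/3)
  g2 <- matrix(0, 5, 5); g2[1:2, 1:5] <- 1        # 10 positives
  p2 <- matrix(0, 5, 5); p2[1:2, 1:4] <- 1        # 8 TP, 2 FN
  p2[3, 1:2] <- 1                                 # 2 FP
  expect_equal(focal_tversky_loss(p2, g2, alpha = 0.3, beta = 0.7, gamma = 4 / 3),
               0.2^(4 / 3), tolerance = 1e-6)
  expect_equal(0.2^(4 / 3), 0.1169607, tolerance = 1e-6)
  # alpha = beta = 0.5, gamma = 1 reduces to dice on binary inputs
  expect_equal(focal_tversky_loss(p2, g2, alpha = 0.5, beta = 0.5, gamma = 1),
               dice_loss(p2, g2), tolerance = 1e-6)
  expect_error(focal_tversky_loss(p2, g2, alpha = -1), "alpha")
  expect_error(focal_tversky_loss(p2, g2, gamma = 0), "gamma")
})

test_that("boundary bands match the brute-force morphology oracle", {
  set.seed(30)
  # single pixel: Chebyshev radius-2 neighbourhood of 25 pixels
  m1 <- matrix(0, 9, 9); m1[5, 5] <- 1
  b1 <- boundary_extract(m1, 2)
  expect_equal(sum(b1), 25)
  expect_equal(b1, oracle_boundary_band(m1, 2))
  # full-image mask: band hugs the border
  mf <- matrix(1, 12, 12)
  bf <- boundary_extract(mf, 2)
  expect_equal(bf, oracle_boundary_band(mf, 2))
  expect_equal(bf[5:8, 5:8], matrix(0, 4, 4))
  expect_true(all(bf[1, ] == 1))
  # random masks against the oracle
  for (k in 1:25) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.1, 0.6)), 32, 32)
    expect_identical(boundary_extract(m, 2), oracle_boundary_band(m, 2))
  }
})

test_that("boundary bands agree with EBImage morphology", {
  skip_if_not_installed("EBImage")
  set.seed(31)
  kern <- EBImage::makeBrush(3, shape = "box")
  zero_border_erode <- function(m) {
    mp <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    mp[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    EBImage::erode(mp, kern)[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  }
  for (k in 1:25) {
    m <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    inner <- m - zero_border_erode(m)
    want <- EBImage::dilate(EBImage::dilate(inner, kern), kern)
    expect_identical(boundary_extract(m, 2), matrix(as.numeric(want), 32, 32))
  }
})

test_that("boundary IoU loss identities and band geometry", {
  g <- disk_mask(24, 11.5, 11.5, 6)
  expect_equal(boundary_iou_loss(g, g), 0, tolerance = 1e-6)
  # two single pixels >= 6 apart: disjoint radius-2 bands, loss 1
  a <- matrix(0, 16, 16); a[3, 3] <- 1
  b <- matrix(0, 16, 16); b[12, 12] <- 1
  expect_equal(boundary_iou_loss(a, b), 1, tolerance = 1e-5)
  # translating a square by one pixel strictly increases the loss from 0
  sq <- matrix(0, 20, 20); sq[6:12, 6:12] <- 1
  sq1 <- matrix(0, 20, 20); sq1[7:13, 6:12] <- 1
  expect_gt(boundary_iou_loss(sq1, sq), 0)
  # empty-band convention: two empty masks are perfect
  expect_equal(boundary_iou_loss(matrix(0, 8, 8), matrix(0, 8, 8)), 0)
})

test_that("soft boundary band converges to the hard band as p binarises", {
  g <- disk_mask(24, 11.5, 11.5, 6)
  hard <- boundary_extract(g, 2)
  for (sharp in c(2, 8, 32)) {
    p <- 1 / (1 + exp(-sharp * (g - 0.5)))
    soft <- boundary_extract(p, 2)
    dev <- max(abs(soft - hard))
    if (sharp == 2) dev2 <- dev
    if (sharp == 32) expect_lt(dev, dev2)
  }
  p <- 1 / (1 + exp(-200 * (g - 0.5)))
  expect_lt(max(abs(boundary_extract(p, 2) - hard)), 1e-10)
})

test_that("oct_loss combines components with the 0.5/0.3/0.2 weights", {
  set.seed(32)
  g <- disk_mask(32, 15.5, 15.5, 7)
  p <- pmin(pmax(g + matrix(rnorm(32 * 32, sd = 0.2), 32, 32), 0), 1)
  l <- oct_loss(p, g)
  expect_equal(l$total, 0.5 * l$dice + 0.3 * l$biou + 0.2 * l$ft, tolerance = 1e-12)
  lp <- oct_loss(g, g)
  expect_equal(lp$total, 0, tolerance = 1e-6)
  l1 <- oct_loss(p, g, loss_weights(1, 0, 0))
  expect_equal(l1$total, dice_loss(p, g), tolerance = 1e-12)
  # all components stay within [0, 1]
  expect_true(all(unlist(l) >= 0 & unlist(l) <= 1))
})

test_that("losses provide finite nonzero gradients on non-degenerate inputs", {
  set.seed(33)
  g <- disk_mask(20, 9.5, 9.5, 5)
  garr <- ad_const(array(g, c(20, 20, 1)))
  p0 <- array(runif(400, 0.2, 0.8), c(20, 20, 1))
  for (lf in list(function(p) dice_loss(p, garr),
                  function(p) boundary_iou_loss(p, garr),
                  function(p) focal_tversky_loss(p, garr),
                  function(p) oct_loss(p, garr)$total)) {
    p <- ad_param(p0)
    ad_with_tape({ ad_backward(lf(p)) })
    expect_true(all(is.finite(p$grad)))
    expect_gt(max(abs(p$grad)), 0)
  }
})
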