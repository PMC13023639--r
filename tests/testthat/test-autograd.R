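# Finite-difference verification of the reverse-mode tape on the operations
# the model relies on most. Each check compares the tape gradient of a scalar
# functional against central differences.

num_grad_at <- function(f, x, idx, eps = 1e-6) {
  sapply(idx, function(i) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  })
}

expect_gradcheck <- function(build, x0, tol = 1e-5, n_idx = 12) {
  p <- ad_param(x0)
  ad_with_tape({
    loss <- build(p)
    ad_backward(loss)
  })
  idx <- octseg:::with_seed(99, sample(length(x0), min(n_idx, length(x0))))
  ng <- num_grad_at(function(x) nodeval(build(ad_param(x))), x0, idx)
  scale <- max(1, max(abs(ng)))
  expect_lt(max(abs(p$grad[idx] - ng)) / scale, tol)
}

sq_sum <- function(x) ad_sum(octseg:::ad_pow_const(x, 2))

test_that("convolution, padding and pooling gradients match finite differences", {
  set.seed(50)
  x0 <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  w0 <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b0 <- rnorm(3)
  for (mode in c("zero", "reflect", "replicate")) {
    expect_gradcheck(function(p) sq_sum(octseg:::ad_conv2d(
      octseg:::ad_pad(p, 1, 1, 1, 1, mode), ad_const(w0), ad_const(b0))), x0)
  }
  expect_gradcheck(function(p) sq_sum(octseg:::ad_conv2d(
    octseg:::ad_pad(ad_const(x0), 1, 1, 1, 1, "zero"), p, ad_const(b0))), w0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_conv2d(
    octseg:::ad_pad(p, 1, 1, 1, 1, "zero"), ad_const(w0), NULL, 2L)), x0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_maxpool3(p)), x0)
  x1 <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  expect_gradcheck(function(p) sq_sum(octseg:::ad_avgpool(p, 2L)), x1)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_upsample_bilinear(p, 9, 13)), x1)
})

test_that("grid sampling gradients flow to features and to coordinates", {
  set.seed(51)
  x0 <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  gy <- matrix(runif(12, 0.4, 4.5), 3, 4)
  gx <- matrix(runif(12, 0.4, 5.5), 3, 4)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_grid_sample(p, gy, gx)), x0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_grid_sample(p, gy * 2, gx,
                                                              wrap_rows = TRUE)), x0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_grid_sample(ad_const(x0), p,
                                                              ad_const(gx))), gy,
                   tol = 1e-4)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_grid_sample(ad_const(x0),
                                                              ad_const(gy), p)), gx,
                   tol = 1e-4)
})

test_that("attention building blocks have exact gradients", {
  set.seed(52)
  m0 <- matrix(rnorm(12), 3, 4)
  g0 <- rnorm(4)
  cg <- rnorm(4); cb <- rnorm(4)
  cm <- matrix(rnorm(20), 5, 4)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_softmax_rows(p)), m0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_layernorm(p, ad_const(cg),
                                                            ad_const(cb))), m0,
                   tol = 1e-4)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_layernorm(ad_const(m0), p,
                                                            ad_const(cb))), g0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_matmul(p, ad_const(cm), tb = TRUE)),
                   m0)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_add_rowvec(ad_const(m0), p)), g0)
})

test_that("angular depthwise convolution gradients match finite differences", {
  set.seed(53)
  xt <- array(rnorm(8 * 3 * 2), c(8, 3, 2))
  wt <- matrix(rnorm(7 * 2), 7, 2)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_dwconv_theta(p, ad_const(wt))), xt)
  expect_gradcheck(function(p) sq_sum(octseg:::ad_dwconv_theta(ad_const(xt), p)), wt)
  # delta kernel acts as the identity
  wd <- matrix(0, 7, 2); wd[4, ] <- 1
  expect_equal(nodeval(octseg:::ad_dwconv_theta(ad_const(xt), ad_const(wd))), xt)
})
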