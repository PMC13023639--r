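# Layer constructors. Each returns a list with parameter nodes and a $fwd
# closure; parameters anywhere inside a nested module list are discovered by
# collect_params(). Weight initialisation draws from the caller's RNG stream
# so a single seed fixes the whole model.

he_init <- function(fan_in, dims, gain = 1) {
  array(rnorm(prod(dims), sd = gain * sqrt(2 / fan_in)), dims)
}

#' 2-D convolution layer
#' @keywords internal
nn_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                      pad_mode = "zero", bias = TRUE, zero_init = FALSE,
                      bias_init = 0) {
  w <- ad_param(if (zero_init) array(0, c(k, k, cin, cout))
                else he_init(k * k * cin, c(k, k, cin, cout)))
  b <- if (bias) ad_param(rep(bias_init, cout)) else NULL
  lay <- list(w = w, b = b, k = k, stride = stride, pad = pad, pad_mode = pad_mode)
  lay$fwd <- function(x) {
    ad_conv2d(x, lay$w, lay$b, lay$stride, lay$pad, lay$pad_mode)
  }
  lay
}

#' Fully connected layer on (n, d) token matrices
#' @keywords internal
nn_linear <- function(din, dout, bias = TRUE, zero_init = FALSE) {
  w <- ad_param(if (zero_init) matrix(0, din, dout)
                else matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout))
  b <- if (bias) ad_param(rep(0, dout)) else NULL
  lay <- list(w = w, b = b)
  lay$fwd <- function(x) ad_linear(x, lay$w, lay$b)
  lay
}

#' Layer normalisation over the feature axis of (n, d) matrices
#' @keywords internal
nn_layernorm <- function(d) {
  lay <- list(gamma = ad_param(rep(1, d)), beta = ad_param(rep(0, d)))
  lay$fwd <- function(x) ad_layernorm(x, lay$gamma, lay$beta)
  lay
}

#' Collect every parameter node in a nested module list
#' @keywords internal
collect_params <- function(m) {
  out <- list()
  walk <- function(x) {
    if (is_node(x) && isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    else if (is.list(x) && !is_node(x)) for (el in x) walk(el)
  }
  walk(m)
  out
}

#' Total number of trainable scalar parameters in a model
#'
#' @param model a model as built by [build_model()] (or any nested module list)
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), numeric(1)))
}

get_state <- function(model) lapply(collect_params(model), function(p) p$value)

set_state <- function(model, state) {
  ps <- collect_params(model)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$value) == length(state[[i]]))
    v <- state[[i]]
    dim(v) <- dim(ps[[i]]$value)
    ps[[i]]$value <- v
  }
  invisible(model)
}

# -- AdamW -------------------------------------------------------------------

#' AdamW optimizer over a list of parameter nodes
#' @keywords internal
opt_adamw <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.01, clip = 1.0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps; st$wd <- weight_decay
  st$clip <- clip
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st$v <- st$m
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

opt_zero_grad <- function(opt) {
  for (p in opt$params) p$grad <- NULL
  invisible(NULL)
}

#' Clip gradients of a parameter list to a maximum global norm
#' @keywords internal
clip_grad_norm <- function(params, max_norm) {
  tot <- 0
  for (p in params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
  tot <- sqrt(tot)
  if (is.finite(tot) && tot > max_norm) {
    sc <- max_norm / tot
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(tot)
}

opt_step <- function(opt) {
  if (!is.null(opt$clip)) clip_grad_norm(opt$params, opt$clip)
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g * g
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$value <- p$value - opt$lr * (upd + opt$wd * p$value)
  }
  invisible(NULL)
}
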