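#' @useDynLib octseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd
NULL

# Reverse-mode automatic differentiation on a linear tape.
#
# A node is an environment holding $value (numeric array), $grad (accumulated
# gradient or NULL), $backward (closure propagating $grad to parents) and
# $requires (whether any ancestor is a trainable parameter). Operations record
# nodes on the active tape in execution order; ad_backward() replays the tape
# in reverse. Parameters are leaf nodes created with ad_param(); they are never
# recorded but receive gradients through accumulation.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

tape_active <- function() !is.null(.ad$tape)

#' Run an expression while recording operations for backpropagation
#'
#' @param expr expression building a computation graph
#' @return the value of `expr`
#' @keywords internal
ad_with_tape <- function(expr) {
  old <- .ad$tape
  .ad$tape <- new.env(parent = emptyenv())
  .ad$tape$nodes <- vector("list", 256L)
  .ad$tape$n <- 0L
  on.exit(.ad$tape <- old)
  expr
}

tape_record <- function(node) {
  tp <- .ad$tape
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- node
  tp$n <- n
  node
}

new_node <- function(value, parents = list(), backward = NULL, requires = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$requires <- requires
  nd$is_param <- FALSE
  class(nd) <- "ad_node"
  if (requires && tape_active()) tape_record(nd)
  nd
}

#' Create a trainable parameter node
#' @param value initial numeric array
#' @keywords internal
ad_param <- function(value) {
  nd <- new_node(value, requires = FALSE)
  nd$requires <- TRUE   # not tape-recorded: leaf
  nd$is_param <- TRUE
  nd
}

ad_const <- function(value) new_node(value)

is_node <- function(x) inherits(x, "ad_node")

as_node <- function(x) if (is_node(x)) x else ad_const(x)

val <- function(x) if (is_node(x)) x$value else x

node_requires <- function(...) {
  if (!tape_active()) return(FALSE)
  for (p in list(...)) if (is_node(p) && p$requires) return(TRUE)
  FALSE
}

acc_grad <- function(node, g) {
  if (!is_node(node) || !node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the active tape
#' @param loss scalar node
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_node(loss), tape_active())
  loss$grad <- if (is.null(dim(loss$value))) rep(1, length(loss$value))
               else array(1, dim = dim(loss$value))
  tp <- .ad$tape
  for (k in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

#' Evaluate a seeded expression without disturbing the caller's RNG stream
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
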