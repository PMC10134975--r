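# Minimal reverse-mode neural-net kernel used by the backbone, detector and
# mask heads. Feature maps are base-R arrays dim c(H, W, C); one image at a
# time (batching is gradient accumulation in the training loop). Every layer
# is an environment with $forward(x), $backward(dy), $params (named list of
# fs_parameter environments); gradients accumulate into p$grad until
# zero_grad() is called.

#' Create a trainable parameter
#'
#' @param value numeric array/vector with the initial value.
#' @param decay logical; if FALSE the optimizer applies no weight decay
#'   (biases, norm gains, attention/scale parameters).
#' @return an environment of class `fs_parameter` with fields `value`,
#'   `grad` (same shape, zero-initialized) and `decay`.
#' @keywords internal
fs_parameter <- function(value, decay = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = if (is.null(dim(value))) length(value) else dim(value))
  p$decay <- decay
  class(p) <- "fs_parameter"
  p
}

fs_module <- function(type, params = list(), submodules = list()) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- params
  m$submodules <- submodules
  class(m) <- "fs_module"
  m
}

#' Collect all parameters of a module tree
#'
#' @param module an `fs_module`.
#' @param prefix name prefix used during recursion.
#' @return named list of `fs_parameter` environments.
#' @export
module_parameters <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$params)) {
    out[[paste0(prefix, nm)]] <- module$params[[nm]]
  }
  for (nm in names(module$submodules)) {
    out <- c(out, module_parameters(module$submodules[[nm]],
                                    prefix = paste0(prefix, nm, ".")))
  }
  out
}

#' Number of trainable scalars in a module tree
#'
#' @param module an `fs_module`.
#' @return integer-valued count.
#' @export
module_n_parameters <- function(module) {
  sum(vapply(module_parameters(module), function(p) length(p$value), numeric(1)))
}

#' Zero all accumulated gradients
#' @param module an `fs_module`.
#' @return invisibly, the module.
#' @export
zero_grad <- function(module) {
  for (p in module_parameters(module)) p$grad[] <- 0
  invisible(module)
}

# --- weight init -------------------------------------------------------------

init_trunc_normal <- function(dims, sd = 0.02) {
  n <- prod(dims)
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  array(x, dim = dims)
}

init_he <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# --- optimizer ---------------------------------------------------------------

#' AdamW optimizer with decoupled weight decay
#'
#' Moment buffers live alongside each parameter. Weight decay is applied only
#' to parameters created with `decay = TRUE` (matrix/kernel weights), never to
#' biases, norm gains or attention scales.
#'
#' @param params named list of `fs_parameter`s (see [module_parameters()]).
#' @param lr base learning rate (default 5e-4).
#' @param weight_decay decoupled decay coefficient (default 0.05).
#' @param beta1,beta2 moment decay rates (defaults 0.9, 0.999).
#' @param eps numerical floor.
#' @return an optimizer environment with `$step(lr_scale)`.
#' @export
adamw <- function(params, lr = 5e-4, weight_decay = 0.05,
                  beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$wd <- weight_decay
  opt$b1 <- beta1
  opt$b2 <- beta2
  opt$eps <- eps
  opt$t <- 0L
  for (p in params) {
    p$m <- p$grad * 0
    p$v <- p$grad * 0
  }
  opt$step <- function(lr_scale = 1) {
    opt$t <- opt$t + 1L
    lr_t <- opt$lr * lr_scale
    bc1 <- 1 - opt$b1^opt$t
    bc2 <- 1 - opt$b2^opt$t
    for (p in opt$params) {
      p$m <- opt$b1 * p$m + (1 - opt$b1) * p$grad
      p$v <- opt$b2 * p$v + (1 - opt$b2) * p$grad^2
      upd <- (p$m / bc1) / (sqrt(p$v / bc2) + opt$eps)
      if (isTRUE(p$decay)) upd <- upd + opt$wd * p$value
      p$value <- p$value - lr_t * upd
    }
    invisible(NULL)
  }
  opt
}

# --- sequential container ----------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "fs_module")) {
    layers <- layers[[1]]
  }
  names(layers) <- sprintf("l%02d", seq_along(layers))
  m <- fs_module("sequential", submodules = layers)
  m$forward <- function(x) {
    for (l in m$submodules) x <- l$forward(x)
    x
  }
  m$backward <- function(dy) {
    for (l in rev(m$submodules)) dy <- l$backward(dy)
    dy
  }
  m
}

# state_dict-style (de)serialization: named list of numeric arrays ------------

#' Extract all parameter values as a named list
#' @param module an `fs_module`.
#' @return named list of numeric arrays.
#' @export
state_dict <- function(module) {
  lapply(module_parameters(module), function(p) p$value)
}

#' Load parameter values saved by [state_dict()]
#' @param module an `fs_module`.
#' @param state named list as returned by [state_dict()].
#' @return invisibly, the module.
#' @export
load_state_dict <- function(module, state) {
  ps <- module_parameters(module)
  missing <- setdiff(names(ps), names(state))
  if (length(missing)) stop("state is missing parameters: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  for (nm in names(ps)) {
    if (length(ps[[nm]]$value) != length(state[[nm]])) {
      stop("shape mismatch for parameter ", nm)
    }
    ps[[nm]]$value[] <- state[[nm]]
  }
  invisible(module)
}
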