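# Parameterized layers and module plumbing. A "module" is a plain nested
# list whose leaves of class ad_tensor with requires_grad = TRUE are the
# trainable parameters; nn_params() flattens them with stable dotted names
# so the optimizer and serialization see a deterministic ordering.

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Create a convolution layer
#'
#' @param in_c,out_c channel counts.
#' @param K kernel side length.
#' @param stride stride.
#' @param bias include a bias term?
#' @param zero_init initialize weights (and bias) to zero; used for
#'   residual-branch output layers so a freshly built block is the identity.
#' @return a module list with a \code{$fwd(x)} closure.
#' @export
nn_conv <- function(in_c, out_c, K = 3L, stride = 1L, bias = TRUE,
                    zero_init = FALSE) {
  fan_in <- K * K * in_c
  Wv <- if (zero_init) matrix(0, fan_in, out_c) else
    .he_init(fan_in, out_c, fan_in)
  m <- list(W = ad_tensor(Wv, TRUE),
            K = K, stride = stride, pad = (K - 1L) %/% 2L)
  if (bias) m$b <- ad_tensor(numeric(out_c), TRUE)
  m$fwd <- function(x) ad_conv2d(x, m$W, m$b, K = m$K, stride = m$stride,
                                 pad = m$pad)
  class(m) <- c("nn_module", "list")
  m
}

#' Create a dense (token-wise affine) layer
#' @param in_d,out_d feature dimensions.
#' @param bias include a bias term?
#' @param zero_init zero-initialize (identity-at-init residual branches).
#' @return module list with \code{$fwd(z)}.
#' @export
nn_dense <- function(in_d, out_d, bias = TRUE, zero_init = FALSE) {
  Wv <- if (zero_init) matrix(0, in_d, out_d) else
    .he_init(in_d, out_d, in_d)
  m <- list(W = ad_tensor(Wv, TRUE))
  if (bias) m$b <- ad_tensor(numeric(out_d), TRUE)
  m$fwd <- function(z) ad_linear(z, m$W, m$b)
  class(m) <- c("nn_module", "list")
  m
}

#' Create an instance-normalization layer (per-channel, affine)
#' @param C channel count.
#' @return module list with \code{$fwd(x)}.
#' @export
nn_instnorm <- function(C) {
  m <- list(gamma = ad_tensor(rep(1, C), TRUE),
            beta = ad_tensor(numeric(C), TRUE))
  m$fwd <- function(x) ad_instnorm(x, m$gamma, m$beta)
  class(m) <- c("nn_module", "list")
  m
}

#' Create a token layer-normalization layer
#' @param S feature dimension.
#' @return module list with \code{$fwd(z)}.
#' @export
nn_layernorm <- function(S) {
  m <- list(gamma = ad_tensor(rep(1, S), TRUE),
            beta = ad_tensor(numeric(S), TRUE))
  m$fwd <- function(z) ad_layernorm_rows(z, m$gamma, m$beta)
  class(m) <- c("nn_module", "list")
  m
}

#' Collect trainable parameters of a module tree
#' @param module nested list containing \code{ad_tensor} leaves.
#' @param prefix internal; name prefix for recursion.
#' @return named list of parameter tensors, depth-first, stable order.
#' @export
nn_params <- function(module, prefix = "") {
  out <- list()
  if (is_ad(module)) {
    if (module$requires_grad) {
      out[[prefix]] <- module
    }
    return(out)
  }
  if (!is.list(module)) return(out)
  nms <- names(module)
  for (k in seq_along(module)) {
    el <- module[[k]]
    if (is.function(el)) next
    nm <- if (!is.null(nms) && nzchar(nms[k])) nms[k] else as.character(k)
    child <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    out <- c(out, nn_params(el, child))
  }
  out
}

#' Count trainable parameters
#' @param module a module tree.
#' @return integer total number of scalar parameters.
#' @export
nn_n_params <- function(module) {
  sum(vapply(nn_params(module), function(p) length(p$value), numeric(1)))
}

#' Extract parameter values as plain arrays
#' @param module a module tree.
#' @return named list of numeric arrays.
#' @export
nn_state_dict <- function(module) {
  lapply(nn_params(module), function(p) p$value)
}

#' Load parameter values into a module tree (in place)
#' @param module a module tree.
#' @param state named list from \code{\link{nn_state_dict}}.
#' @export
nn_load_state <- function(module, state) {
  ps <- nn_params(module)
  stopifnot(setequal(names(ps), names(state)))
  for (nm in names(ps)) {
    stopifnot(length(ps[[nm]]$value) == length(state[[nm]]))
    v <- state[[nm]]
    if (!is.null(dim(ps[[nm]]$value))) dim(v) <- dim(ps[[nm]]$value)
    ps[[nm]]$value <- v
  }
  invisible(module)
}

#' Stochastic gradient descent with momentum and weight decay
#'
#' Classical momentum: \code{v <- mu * v + grad + wd * w; w <- w - lr * v}.
#' Weight decay is skipped for biases and normalization affine parameters
#' (1-D parameters), the usual convention.
#'
#' @param params named list from \code{\link{nn_params}}.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 coefficient applied to matrix-shaped weights.
#' @return optimizer object with a \code{$step()} method.
#' @export
sgd_optimizer <- function(params, lr = 0.001, momentum = 0.9,
                          weight_decay = 1e-4) {
  vel <- lapply(params, function(p) p$value * 0)
  obj <- new.env(parent = emptyenv())
  obj$lr <- lr
  obj$step <- function() {
    for (nm in names(params)) {
      p <- params[[nm]]
      if (is.null(p$grad)) next
      g <- p$grad
      if (!is.null(dim(p$value)) && weight_decay > 0)
        g <- g + weight_decay * p$value
      vel[[nm]] <<- momentum * vel[[nm]] + g
      p$value <- p$value - obj$lr * vel[[nm]]
    }
    invisible(NULL)
  }
  obj
}

#' Adam optimizer
#'
#' Adaptive-moment estimation; the adaptive alternative to
#' \code{\link{sgd_optimizer}} for small-sample experiments where SGD's
#' single global step size converges slowly. Decoupled weight decay on
#' matrix-shaped weights.
#'
#' @param params named list from \code{\link{nn_params}}.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps denominator stabilizer.
#' @param weight_decay decoupled L2 coefficient.
#' @return optimizer object with a \code{$step()} method.
#' @export
adam_optimizer <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 1e-4) {
  m1 <- lapply(params, function(p) p$value * 0)
  m2 <- lapply(params, function(p) p$value * 0)
  obj <- new.env(parent = emptyenv())
  obj$lr <- lr
  obj$t <- 0L
  obj$step <- function() {
    obj$t <- obj$t + 1L
    bc1 <- 1 - beta1^obj$t
    bc2 <- 1 - beta2^obj$t
    for (nm in names(params)) {
      p <- params[[nm]]
      if (is.null(p$grad)) next
      g <- p$grad
      m1[[nm]] <<- beta1 * m1[[nm]] + (1 - beta1) * g
      m2[[nm]] <<- beta2 * m2[[nm]] + (1 - beta2) * g * g
      upd <- (m1[[nm]] / bc1) / (sqrt(m2[[nm]] / bc2) + eps)
      if (!is.null(dim(p$value)) && weight_decay > 0)
        upd <- upd + weight_decay * p$value
      p$value <- p$value - obj$lr * upd
    }
    invisible(NULL)
  }
  obj
}
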