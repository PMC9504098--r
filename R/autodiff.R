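# Reverse-mode automatic differentiation on a dynamic tape.
#
# Tensors are environments holding a numeric value (vector, matrix or 3D
# array), an optional gradient, and the backward closure that distributes an
# incoming gradient to the node's parents. Feature maps use the (H, W, C)
# layout; token sequences are N x S matrices with tokens ordered
# column-major over the patch grid (grid row index fastest).

.ad_env <- new.env(parent = emptyenv())
.ad_env$id <- 0L
.ad_env$record <- TRUE

#' Create an autodiff tensor
#'
#' Wraps a numeric array as a leaf node of the computation graph. Leaves
#' with \code{requires_grad = TRUE} (model parameters) receive accumulated
#' gradients when \code{\link{ad_backward}} is called on a downstream scalar.
#'
#' @param value numeric vector, matrix or array.
#' @param requires_grad should gradients be accumulated into this leaf?
#' @return an object of class \code{ad_tensor}.
#' @export
ad_tensor <- function(value, requires_grad = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$backfn <- NULL
  node$needs <- isTRUE(requires_grad)
  node$requires_grad <- isTRUE(requires_grad)
  node$id <- (.ad_env$id <- .ad_env$id + 1L)
  class(node) <- "ad_tensor"
  node
}

#' @export
print.ad_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ad_tensor", if (is.null(d)) paste0("len=", length(x$value)) else
    paste(d, collapse = "x"),
    if (x$requires_grad) "param" else "", ">\n")
  invisible(x)
}

is_ad <- function(x) inherits(x, "ad_tensor")

#' Extract the numeric value of a tensor
#' @param x an \code{ad_tensor} or plain numeric.
#' @return the underlying numeric array.
#' @export
ad_value <- function(x) if (is_ad(x)) x$value else x

.as_ad <- function(x) if (is_ad(x)) x else ad_tensor(x)

# Internal node constructor. When recording is off, or no parent needs a
# gradient, the node is detached (constant folding for evaluation mode).
.ad_op <- function(value, parents, backfn) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  needs <- .ad_env$record &&
    any(vapply(parents, function(p) isTRUE(p$needs), logical(1)))
  if (needs) {
    node$parents <- parents
    node$backfn <- backfn
  } else {
    node$parents <- list()
    node$backfn <- NULL
  }
  node$needs <- needs
  node$requires_grad <- FALSE
  node$id <- (.ad_env$id <- .ad_env$id + 1L)
  class(node) <- "ad_tensor"
  node
}

#' Evaluate an expression without recording the tape
#'
#' Used for inference: the graph is not built, which saves time and memory.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
ad_no_grad <- function(expr) {
  old <- .ad_env$record
  .ad_env$record <- FALSE
  on.exit(.ad_env$record <- old)
  expr
}

.accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Backpropagate gradients from a scalar loss
#'
#' Walks the tape in reverse topological order and accumulates gradients
#' into every reachable leaf created with \code{requires_grad = TRUE}.
#'
#' @param loss an \code{ad_tensor} holding a scalar.
#' @export
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  # collect reachable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack) > 0) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) if (isTRUE(p$needs)) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  loss$grad <- 1
  for (n in nodes) {
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (isTRUE(p$needs) && !is.null(gs[[k]])) .accum(p, gs[[k]])
    }
    if (!n$requires_grad) n$grad <- NULL   # free intermediate grads
  }
  invisible(loss)
}

#' Reset gradients of a list of parameters
#' @param params list of \code{ad_tensor} leaves.
#' @export
ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementwise ops -------------------------------------------------------

#' @rdname ad_ops
#' @param a,b tensors or plain numerics of identical shape.
#' @export
ad_add <- function(a, b) {
  a <- .as_ad(a); b <- .as_ad(b)
  .ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

#' @rdname ad_ops
#' @export
ad_sub <- function(a, b) {
  a <- .as_ad(a); b <- .as_ad(b)
  .ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

#' @rdname ad_ops
#' @export
ad_mul <- function(a, b) {
  a <- .as_ad(a); b <- .as_ad(b)
  av <- a$value; bv <- b$value
  .ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' Elementwise and linear-algebra operations on tensors
#'
#' The \code{ad_*} family mirrors the usual array operations while recording
#' the tape needed for reverse-mode differentiation.
#' @name ad_ops
#' @param x a tensor.
#' @param k a plain numeric scalar.
#' @return an \code{ad_tensor}.
NULL

#' @rdname ad_ops
#' @export
ad_smul <- function(x, k) {
  x <- .as_ad(x)
  .ad_op(x$value * k, list(x), function(g) list(g * k))
}

#' @rdname ad_ops
#' @export
ad_sadd <- function(x, k) {
  x <- .as_ad(x)
  .ad_op(x$value + k, list(x), function(g) list(g))
}

#' @rdname ad_ops
#' @export
ad_relu <- function(x) {
  x <- .as_ad(x)
  mask <- x$value > 0
  .ad_op(x$value * mask, list(x), function(g) list(g * mask))
}

#' @rdname ad_ops
#' @export
ad_gelu <- function(x) {
  x <- .as_ad(x)
  xv <- x$value
  ph <- stats::pnorm(xv)
  .ad_op(xv * ph, list(x),
         function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

#' @rdname ad_ops
#' @export
ad_sigmoid <- function(x) {
  x <- .as_ad(x)
  s <- stats::plogis(x$value)
  .ad_op(s, list(x), function(g) list(g * s * (1 - s)))
}

# inverted dropout; draws from the current RNG stream
ad_dropout <- function(x, rate, training = TRUE) {
  x <- .as_ad(x)
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  keep <- array(keep, dim = if (is.null(dim(x$value))) NULL else dim(x$value))
  .ad_op(x$value * keep, list(x), function(g) list(g * keep))
}

## ---- matrix ops ------------------------------------------------------------

#' @rdname ad_ops
#' @param A,B matrices (tensors).
#' @export
ad_matmul <- function(A, B) {
  A <- .as_ad(A); B <- .as_ad(B)
  Av <- A$value; Bv <- B$value
  .ad_op(Av %*% Bv, list(A, B),
         function(g) list(g %*% t(Bv), crossprod(Av, g)))
}

# A %*% t(B)
ad_matmul_bt <- function(A, B) {
  A <- .as_ad(A); B <- .as_ad(B)
  Av <- A$value; Bv <- B$value
  .ad_op(tcrossprod(Av, Bv), list(A, B),
         function(g) list(g %*% Bv, crossprod(g, Av)))
}

#' Affine map over token rows: \code{Z \%*\% W + b}
#' @param Z N x S matrix tensor.
#' @param W S x D weight tensor.
#' @param b optional length-D bias tensor.
#' @return N x D tensor.
#' @export
ad_linear <- function(Z, W, b = NULL) {
  Z <- .as_ad(Z); W <- .as_ad(W)
  Zv <- Z$value; Wv <- W$value
  out <- Zv %*% Wv
  if (is.null(b)) {
    .ad_op(out, list(Z, W),
           function(g) list(g %*% t(Wv), crossprod(Zv, g)))
  } else {
    b <- .as_ad(b)
    out <- sweep(out, 2L, b$value, "+")
    .ad_op(out, list(Z, W, b),
           function(g) list(g %*% t(Wv), crossprod(Zv, g), colSums(g)))
  }
}

#' Row-wise softmax with tape support
#' @param Z N x K matrix tensor of scores.
#' @return N x K tensor of row-stochastic weights.
#' @export
ad_softmax_rows <- function(Z) {
  Z <- .as_ad(Z)
  zv <- Z$value
  m <- apply(zv, 1L, max)
  e <- exp(zv - m)
  y <- e / rowSums(e)
  .ad_op(y, list(Z), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

#' Layer normalization over the feature (column) dimension of each row
#' @param Z N x S tensor.
#' @param gamma,beta length-S affine tensors.
#' @param eps variance stabilizer.
#' @return normalized N x S tensor.
#' @export
ad_layernorm_rows <- function(Z, gamma, beta, eps = 1e-5) {
  Z <- .as_ad(Z); gamma <- .as_ad(gamma); beta <- .as_ad(beta)
  zv <- Z$value
  S <- ncol(zv)
  mu <- rowMeans(zv)
  xc <- zv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  .ad_op(y, list(Z, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gamma$value, "*")
    dz <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dz, colSums(g * xhat), colSums(g))
  })
}

## ---- reductions ------------------------------------------------------------

#' @rdname ad_ops
#' @export
ad_mean_all <- function(x) {
  x <- .as_ad(x)
  n <- length(x$value)
  dm <- dim(x$value)
  .ad_op(mean(x$value), list(x), function(g) {
    gv <- array(g / n, dim = if (is.null(dm)) n else dm)
    list(gv)
  })
}

#' Mean squared error against a fixed target
#' @param pred tensor.
#' @param target plain numeric array of the same shape.
#' @return scalar tensor.
#' @export
ad_mse <- function(pred, target) {
  pred <- .as_ad(pred)
  d <- pred$value - ad_value(target)
  n <- length(d)
  .ad_op(mean(d * d), list(pred), function(g) list(2 * g * d / n))
}

#' Mean absolute error against a fixed target
#' @param pred tensor.
#' @param target plain numeric array of the same shape.
#' @return scalar tensor.
#' @export
ad_mae <- function(pred, target) {
  pred <- .as_ad(pred)
  d <- pred$value - ad_value(target)
  n <- length(d)
  .ad_op(mean(abs(d)), list(pred), function(g) list(g * sign(d) / n))
}

## ---- image (H, W, C) ops ---------------------------------------------------

.pad3 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

# im2col: (H,W,Cin) -> (Ho*Wo) x (K*K*Cin); column block for kernel offset
# (ki,kj) and channel c sits at (c-1)*K^2 + (kj-1)*K + ki.
.im2col <- function(x, K, stride, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- (H + 2 * pad - K) %/% stride + 1L
  Wo <- (W + 2 * pad - K) %/% stride + 1L
  xp <- .pad3(x, pad)
  cols <- matrix(0, Ho * Wo, K * K * C)
  for (kj in seq_len(K)) {
    cs <- seq.int(kj, by = stride, length.out = Wo)
    for (ki in seq_len(K)) {
      rs <- seq.int(ki, by = stride, length.out = Ho)
      blk <- xp[rs, cs, , drop = FALSE]
      o <- (kj - 1L) * K + ki
      cols[, (seq_len(C) - 1L) * (K * K) + o] <- matrix(blk, Ho * Wo, C)
    }
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

.col2im <- function(dcols, H, W, C, K, stride, pad, Ho, Wo) {
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  for (kj in seq_len(K)) {
    cs <- seq.int(kj, by = stride, length.out = Wo)
    for (ki in seq_len(K)) {
      rs <- seq.int(ki, by = stride, length.out = Ho)
      o <- (kj - 1L) * K + ki
      blk <- array(dcols[, (seq_len(C) - 1L) * (K * K) + o], c(Ho, Wo, C))
      xp[rs, cs, ] <- xp[rs, cs, ] + blk
    }
  }
  if (pad == 0) xp else xp[(pad + 1):(pad + H), (pad + 1):(pad + W), , drop = FALSE]
}

#' 2D convolution on an (H, W, C) feature map
#'
#' Weights are stored flattened as a (K*K*Cin) x Cout matrix (im2col layout).
#' Padding defaults to "same" for stride 1 and odd kernels.
#'
#' @param x input tensor, dim (H, W, Cin).
#' @param Wmat flattened kernel tensor, dim (K*K*Cin, Cout).
#' @param b optional length-Cout bias tensor.
#' @param K kernel side length.
#' @param stride stride (1 or 2).
#' @param pad zero padding; default \code{(K - 1) / 2}.
#' @return tensor of dim (Ho, Wo, Cout).
#' @export
ad_conv2d <- function(x, Wmat, b = NULL, K = 3L, stride = 1L,
                      pad = (K - 1L) %/% 2L) {
  x <- .as_ad(x); Wmat <- .as_ad(Wmat)
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; Cin <- d[3]
  Cout <- ncol(Wmat$value)
  if (K == 1L && stride == 1L && pad == 0L) {
    cols <- matrix(xv, H * W, Cin)
    Ho <- H; Wo <- W
  } else {
    ic <- .im2col(xv, K, stride, pad)
    cols <- ic$cols; Ho <- ic$Ho; Wo <- ic$Wo
  }
  out <- cols %*% Wmat$value
  Wv <- Wmat$value
  if (is.null(b)) {
    .ad_op(array(out, c(Ho, Wo, Cout)), list(x, Wmat), function(g) {
      gm <- matrix(g, Ho * Wo, Cout)
      dcols <- gm %*% t(Wv)
      dx <- if (K == 1L && stride == 1L && pad == 0L)
        array(dcols, c(H, W, Cin))
      else .col2im(dcols, H, W, Cin, K, stride, pad, Ho, Wo)
      list(dx, crossprod(cols, gm))
    })
  } else {
    b <- .as_ad(b)
    out <- sweep(out, 2L, b$value, "+")
    .ad_op(array(out, c(Ho, Wo, Cout)), list(x, Wmat, b), function(g) {
      gm <- matrix(g, Ho * Wo, Cout)
      dcols <- gm %*% t(Wv)
      dx <- if (K == 1L && stride == 1L && pad == 0L)
        array(dcols, c(H, W, Cin))
      else .col2im(dcols, H, W, Cin, K, stride, pad, Ho, Wo)
      list(dx, crossprod(cols, gm), colSums(gm))
    })
  }
}

#' Instance normalization: each channel standardized over its H x W plane
#' @param x (H, W, C) tensor.
#' @param gamma,beta length-C affine tensors.
#' @param eps variance stabilizer.
#' @return normalized (H, W, C) tensor.
#' @export
ad_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- .as_ad(x); gamma <- .as_ad(gamma); beta <- .as_ad(beta)
  xv <- x$value
  d <- dim(xv)
  n <- d[1] * d[2]
  xm <- matrix(xv, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  .ad_op(array(y, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, n, d[3])
    dxhat <- sweep(gm, 2L, gamma$value, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dz <- sweep(dxhat - rep(m1, each = n) - xhat * rep(m2, each = n),
                2L, inv, "*")
    list(array(dz, d), colSums(gm * xhat), colSums(gm))
  })
}

#' Nearest-neighbour 2x upsampling
#' @param x (H, W, C) tensor.
#' @return (2H, 2W, C) tensor.
#' @export
ad_upsample2 <- function(x) {
  x <- .as_ad(x)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  ri <- rep(seq_len(H), each = 2L)
  ci <- rep(seq_len(W), each = 2L)
  y <- x$value[ri, ci, , drop = FALSE]
  .ad_op(y, list(x), function(g) {
    o <- seq.int(1L, 2L * H, by = 2L)
    gr <- g[o, , , drop = FALSE] + g[o + 1L, , , drop = FALSE]
    oc <- seq.int(1L, 2L * W, by = 2L)
    list(gr[, oc, , drop = FALSE] + gr[, oc + 1L, , drop = FALSE])
  })
}

#' Concatenate feature maps along the channel axis
#' @param xs list of (H, W, C_k) tensors.
#' @return (H, W, sum C_k) tensor.
#' @export
ad_concat_c <- function(xs) {
  xs <- lapply(xs, .as_ad)
  vals <- lapply(xs, function(t) t$value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs)))
  at <- 0L
  for (v in vals) {
    nc <- dim(v)[3]
    out[, , (at + 1L):(at + nc)] <- v
    at <- at + nc
  }
  .ad_op(out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      nc <- cs[k]
      res[[k]] <- g[, , (at + 1L):(at + nc), drop = FALSE]
      at <- at + nc
    }
    res
  })
}

#' Channel-wise mean map (average pooling along channels)
#' @param x (H, W, C) tensor.
#' @return (H, W, 1) tensor.
#' @export
ad_chan_mean <- function(x) {
  x <- .as_ad(x)
  d <- dim(x$value)
  C <- d[3]
  xm <- matrix(x$value, d[1] * d[2], C)
  y <- array(rowMeans(xm), c(d[1], d[2], 1L))
  .ad_op(y, list(x), function(g) {
    gv <- as.vector(g) / C
    list(array(rep(gv, C), d))
  })
}

#' Channel-wise max map (max pooling along channels)
#' @param x (H, W, C) tensor.
#' @return (H, W, 1) tensor.
#' @export
ad_chan_max <- function(x) {
  x <- .as_ad(x)
  d <- dim(x$value)
  n <- d[1] * d[2]
  xm <- matrix(x$value, n, d[3])
  idx <- max.col(xm, ties.method = "first")
  y <- array(xm[cbind(seq_len(n), idx)], c(d[1], d[2], 1L))
  .ad_op(y, list(x), function(g) {
    dm <- matrix(0, n, d[3])
    dm[cbind(seq_len(n), idx)] <- as.vector(g)
    list(array(dm, d))
  })
}

#' Global average pooling to a channel descriptor
#' @param x (H, W, C) tensor.
#' @return 1 x C matrix tensor.
#' @export
ad_global_avgpool <- function(x) {
  x <- .as_ad(x)
  d <- dim(x$value)
  n <- d[1] * d[2]
  y <- matrix(colMeans(matrix(x$value, n, d[3])), 1L, d[3])
  .ad_op(y, list(x), function(g) {
    list(array(rep(as.vector(g) / n, each = n), d))
  })
}

#' Rescale each channel by a scalar weight
#' @param x (H, W, C) tensor.
#' @param s 1 x C matrix tensor of channel weights.
#' @return (H, W, C) tensor.
#' @export
ad_scale_channels <- function(x, s) {
  x <- .as_ad(x); s <- .as_ad(s)
  d <- dim(x$value)
  n <- d[1] * d[2]
  sv <- as.vector(s$value)
  xv <- x$value
  y <- array(sweep(matrix(xv, n, d[3]), 2L, sv, "*"), d)
  .ad_op(y, list(x, s), function(g) {
    gm <- matrix(g, n, d[3])
    dx <- array(sweep(gm, 2L, sv, "*"), d)
    ds <- matrix(colSums(gm * matrix(xv, n, d[3])), 1L, d[3])
    list(dx, ds)
  })
}

#' Multiply a feature map by a single-channel spatial map
#' @param x (H, W, C) tensor.
#' @param m (H, W, 1) tensor broadcast over channels.
#' @return (H, W, C) tensor.
#' @export
ad_mul_map <- function(x, m) {
  x <- .as_ad(x); m <- .as_ad(m)
  d <- dim(x$value)
  C <- d[3]
  mv <- as.vector(m$value)
  xv <- x$value
  n <- d[1] * d[2]
  y <- array(matrix(xv, n, C) * mv, d)
  .ad_op(y, list(x, m), function(g) {
    gm <- matrix(g, n, C)
    dx <- array(gm * mv, d)
    dmv <- rowSums(gm * matrix(xv, n, C))
    list(dx, array(dmv, c(d[1], d[2], 1L)))
  })
}

## ---- token/grid reshaping --------------------------------------------------

#' Reshape a token sequence to a spatial grid
#'
#' Tokens are ordered column-major over the (Hg, Wg) grid (grid row fastest),
#' matching \code{\link{ad_extract_patches}}.
#' @param z N x S tensor, N = Hg * Wg.
#' @param Hg,Wg grid height and width.
#' @return (Hg, Wg, S) tensor.
#' @export
ad_tokens_to_grid <- function(z, Hg, Wg) {
  z <- .as_ad(z)
  S <- ncol(z$value)
  y <- array(z$value, c(Hg, Wg, S))
  .ad_op(y, list(z), function(g) list(matrix(g, Hg * Wg, S)))
}

#' Extract non-overlapping M x M patches as flattened rows
#'
#' Row n holds patch n (column-major over the patch grid); within a row the
#' layout is patch pixel fastest (column-major), then input channel.
#' @param x (H, W, C) tensor with H, W divisible by M.
#' @param M patch side length.
#' @return N x (M^2 * C) tensor, N = (H/M) * (W/M).
#' @export
ad_extract_patches <- function(x, M) {
  x <- .as_ad(x)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% M == 0L, W %% M == 0L)
  Hg <- H %/% M; Wg <- W %/% M
  N <- Hg * Wg
  cols <- matrix(0, N, M * M * C)
  for (pj in seq_len(M)) {
    cs <- seq.int(pj, by = M, length.out = Wg)
    for (pi in seq_len(M)) {
      rs <- seq.int(pi, by = M, length.out = Hg)
      blk <- x$value[rs, cs, , drop = FALSE]
      o <- (pj - 1L) * M + pi
      cols[, (seq_len(C) - 1L) * (M * M) + o] <- matrix(blk, N, C)
    }
  }
  .ad_op(cols, list(x), function(g) {
    dx <- array(0, d)
    for (pj in seq_len(M)) {
      cs <- seq.int(pj, by = M, length.out = Wg)
      for (pi in seq_len(M)) {
        rs <- seq.int(pi, by = M, length.out = Hg)
        o <- (pj - 1L) * M + pi
        dx[rs, cs, ] <- array(g[, (seq_len(C) - 1L) * (M * M) + o],
                              c(Hg, Wg, C))
      }
    }
    list(dx)
  })
}

#' Invert \code{ad_extract_patches} on plain arrays (testing utility)
#' @param tokens N x (M^2 * C) numeric matrix.
#' @param H,W,C,M original geometry.
#' @return (H, W, C) array.
#' @export
unpatchify <- function(tokens, H, W, C, M) {
  Hg <- H %/% M; Wg <- W %/% M
  x <- array(0, c(H, W, C))
  for (pj in seq_len(M)) {
    cs <- seq.int(pj, by = M, length.out = Wg)
    for (pi in seq_len(M)) {
      rs <- seq.int(pi, by = M, length.out = Hg)
      o <- (pj - 1L) * M + pi
      x[rs, cs, ] <- array(tokens[, (seq_len(C) - 1L) * (M * M) + o],
                           c(Hg, Wg, C))
    }
  }
  x
}

## ---- numeric gradient checking --------------------------------------------

#' Finite-difference gradient of a scalar function w.r.t. one tensor
#'
#' Central differences; used to validate analytic backpropagation.
#' @param f function taking a plain numeric array, returning a scalar.
#' @param x0 numeric array at which to differentiate.
#' @param eps step size.
#' @return array of the same shape as \code{x0}.
#' @export
num_grad <- function(f, x0, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x0))) length(x0) else dim(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
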