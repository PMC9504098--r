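# Hierarchical residual-convolution encoder. A stride-2 stem is followed by
# four stages: stage 1 widens channels at constant resolution, stages 2-4
# each halve the resolution, so the pyramid levels taken from stages 2, 3
# and 4 sit at 1/4, 1/8 and 1/16 of the input resolution — exactly the
# scales the transformer decoder emits, which the fusion module requires.

#' CNN branch configuration
#'
#' @param in_channels input (hyperspectral) channel count.
#' @param stage_channels channel widths of the four stages (nondecreasing).
#' @param blocks_per_stage residual blocks per stage.
#' @return list of class \code{cnn_config}.
#' @export
cnn_config <- function(in_channels, stage_channels = c(32L, 64L, 128L, 256L),
                       blocks_per_stage = 2L) {
  stopifnot(length(stage_channels) == 4L,
            all(diff(stage_channels) >= 0), blocks_per_stage >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage)),
            class = "cnn_config")
}

#' Residual convolution block
#'
#' Two 3x3 convolutions each followed by instance normalization, with the
#' activation applied inside the main path and an identity (or 1x1
#' projection, when the channel count or resolution changes) shortcut:
#' \code{out = act(norm(conv(act(norm(conv(f)))))) + shortcut(f)}.
#'
#' @param in_c,out_c channel counts.
#' @param stride stride of the first convolution (2 at stage entrances).
#' @return module list with \code{$fwd(x)}.
#' @export
nn_residual_block <- function(in_c, out_c, stride = 1L) {
  m <- list(conv1 = nn_conv(in_c, out_c, 3L, stride = stride),
            n1 = nn_instnorm(out_c),
            conv2 = nn_conv(out_c, out_c, 3L),
            n2 = nn_instnorm(out_c))
  if (in_c != out_c || stride != 1L)
    m$proj <- nn_conv(in_c, out_c, 1L, stride = stride, bias = FALSE)
  m$fwd <- function(x) {
    h <- ad_relu(m$n1$fwd(m$conv1$fwd(x)))
    h <- ad_relu(m$n2$fwd(m$conv2$fwd(h)))
    sc <- if (is.null(m$proj)) x else {
      if (stride == 1L) m$proj$fwd(x)
      else ad_conv2d(x, m$proj$W, NULL, K = 1L, stride = stride, pad = 0L)
    }
    ad_add(h, sc)
  }
  class(m) <- c("nn_module", "list")
  m
}

#' Build the CNN branch
#' @param cfg a \code{\link{cnn_config}}.
#' @return module with \code{$fwd(x)} returning the feature pyramid.
#' @export
nn_cnn_branch <- function(cfg) {
  ch <- cfg$stage_channels
  stage <- function(in_c, out_c, stride) {
    blocks <- vector("list", cfg$blocks_per_stage)
    blocks[[1]] <- nn_residual_block(in_c, out_c, stride)
    for (k in seq_len(cfg$blocks_per_stage - 1L))
      blocks[[k + 1L]] <- nn_residual_block(out_c, out_c, 1L)
    blocks
  }
  m <- list(stem = nn_conv(cfg$in_channels, ch[1], 3L, stride = 2L),
            stem_n = nn_instnorm(ch[1]),
            s1 = stage(ch[1], ch[1], 1L),
            s2 = stage(ch[1], ch[2], 2L),
            s3 = stage(ch[2], ch[3], 2L),
            s4 = stage(ch[3], ch[4], 2L))
  run_stage <- function(blocks, x) {
    for (b in blocks) x <- b$fwd(x)
    x
  }
  m$fwd <- function(x) {
    d <- dim(ad_value(x))
    if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
      stop("input height/width must be divisible by 16 (pad the image)",
           call. = FALSE)
    h <- ad_relu(m$stem_n$fwd(m$stem$fwd(x)))   # H/2
    h <- run_stage(m$s1, h)                      # H/2, widened
    h2 <- run_stage(m$s2, h)                     # H/4
    h1 <- run_stage(m$s3, h2)                    # H/8
    h0 <- run_stage(m$s4, h1)                    # H/16
    list(h2 = h2, h1 = h1, h0 = h0)
  }
  class(m) <- c("nn_module", "list")
  m
}

#' Encode an image with the CNN branch
#'
#' @param x (H, W, C) array or tensor, H and W divisible by 16.
#' @param branch module from \code{\link{nn_cnn_branch}}.
#' @return list with pyramid levels \code{h2} (H/4), \code{h1} (H/8),
#'   \code{h0} (H/16), coarse to fine channel widths from the config.
#' @export
cnn_encode <- function(x, branch) branch$fwd(x)
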