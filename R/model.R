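# Model assembly: the two-branch fusion network (CNN branch + transformer
# branch + multi-level parallel fusion + prediction head) and a plain
# U-net style encoder-decoder baseline with the same input/output contract.

#' Configuration of the fusion network
#'
#' The "paper" preset uses the full widths (stages 32-256, embedding 256);
#' the "small" preset scales every width down for CPU-sized experiments.
#' The patch size is fixed at 16 so the transformer grid sits at H/16,
#' matching the coarsest CNN level.
#'
#' @param in_channels input channel count C.
#' @param out_channels predicted fluorescence channels K (3 organelles).
#' @param image_size square input side, divisible by 16.
#' @param preset "small" or "paper" width ladder.
#' @param dropout transformer dropout rate.
#' @param seed seed used when the parameters are initialized.
#' @return list of class \code{mpfnet_config}.
#' @export
mpfnet_config <- function(in_channels = 10L, out_channels = 3L,
                          image_size = 64L,
                          preset = c("small", "paper"),
                          dropout = 0.1, seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(image_size %% 16L == 0L)
  if (preset == "paper") {
    stages <- c(32L, 64L, 128L, 256L)
    S0 <- 256L; dec <- c(256L, 128L, 64L); mlp <- 4; head_dim <- 32L
  } else {
    stages <- c(8L, 16L, 24L, 32L)
    S0 <- 32L; dec <- c(24L, 16L, 16L); mlp <- 2; head_dim <- 16L
  }
  h_dims <- stages[c(4L, 3L, 2L)]       # h0 (H/16), h1 (H/8), h2 (H/4)
  structure(list(
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    image_size = as.integer(image_size),
    preset = preset, seed = as.integer(seed),
    head_dim = head_dim,
    cnn = cnn_config(in_channels, stages),
    trans = transformer_config(in_channels, patch = 16L, S0 = S0,
                               L = 8L, heads = 4L, mlp_ratio = mlp,
                               dropout = dropout, decoder_dims = dec),
    fusion = fusion_config(s_dims = dec, h_dims = h_dims)),
    class = "mpfnet_config")
}

#' Build the fusion network
#'
#' Parameter initialization draws from the RNG seeded with
#' \code{cfg$seed}, so identical configs build identical networks.
#'
#' @param cfg a \code{\link{mpfnet_config}}.
#' @return model module with \code{$fwd(x, training, ablate_level)}.
#' @export
build_mpfnet <- function(cfg) {
  .with_seed(cfg$seed, {
    F2 <- cfg$fusion$f_dims[3]
    hd <- cfg$head_dim
    m <- list(cfg = cfg,
              cnn = nn_cnn_branch(cfg$cnn),
              trans = nn_transformer_branch(cfg$trans, cfg$image_size),
              fus = nn_mpf_fusion(cfg$fusion),
              head1 = nn_conv(F2, hd, 3L),
              head2 = nn_conv(hd, hd, 3L),
              # zero-init final layer: predictions start at sigmoid(0) = 0.5
              out = nn_conv(hd, cfg$out_channels, 1L, zero_init = TRUE))
    m$fwd <- function(x, training = FALSE, ablate_level = NULL) {
      pyr <- m$cnn$fwd(x)
      maps <- m$trans$fwd(x, training)
      f <- m$fus$fwd(pyr, maps, ablate_level = ablate_level)   # H/4
      h <- ad_relu(m$head1$fwd(ad_upsample2(f)))               # H/2
      h <- ad_relu(m$head2$fwd(ad_upsample2(h)))               # H
      ad_sigmoid(m$out$fwd(h))
    }
    class(m) <- c("mpfnet_model", "nn_module", "list")
    m
  })
}

#' Forward pass of the fusion network
#'
#' @param x (H, W, C) array, H and W divisible by 16.
#' @param model module from \code{\link{build_mpfnet}}.
#' @param training enable dropout (training mode).
#' @param ablate_level optionally zero one fusion level (1 = coarsest).
#' @return (H, W, K) prediction array in [0, 1].
#' @export
mpfnet_forward <- function(x, model, training = FALSE, ablate_level = NULL) {
  if (training) ad_value(model$fwd(x, training = TRUE,
                                   ablate_level = ablate_level))
  else ad_no_grad(ad_value(model$fwd(x, ablate_level = ablate_level)))
}

#' Configuration of the plain encoder-decoder baseline
#'
#' @param in_channels,out_channels input/output channel counts.
#' @param widths encoder widths of the four levels.
#' @param seed initialization seed.
#' @return list of class \code{unet_config}.
#' @export
unet_config <- function(in_channels = 10L, out_channels = 3L,
                        widths = c(8L, 16L, 24L, 32L), seed = 1L) {
  stopifnot(length(widths) == 4L)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 widths = as.integer(widths), seed = as.integer(seed)),
            class = "unet_config")
}

# conv - instance norm - relu, twice
.unet_block <- function(in_c, out_c) {
  m <- list(c1 = nn_conv(in_c, out_c, 3L), n1 = nn_instnorm(out_c),
            c2 = nn_conv(out_c, out_c, 3L), n2 = nn_instnorm(out_c))
  m$fwd <- function(x)
    ad_relu(m$n2$fwd(m$c2$fwd(ad_relu(m$n1$fwd(m$c1$fwd(x))))))
  class(m) <- c("nn_module", "list")
  m
}

#' Build the U-net style baseline
#'
#' Standard 4-level encoder-decoder: double-convolution blocks, stride-2
#' convolution downsampling, nearest-upsample + convolution decoding with
#' skip concatenations, 1x1 sigmoid head. Same contract as the fusion
#' network.
#'
#' @param cfg a \code{\link{unet_config}}.
#' @return model module with \code{$fwd(x, training)}.
#' @export
build_unet <- function(cfg) {
  .with_seed(cfg$seed, {
    w <- cfg$widths
    m <- list(cfg = cfg,
              e1 = .unet_block(cfg$in_channels, w[1]),
              d1 = nn_conv(w[1], w[2], 3L, stride = 2L),
              e2 = .unet_block(w[2], w[2]),
              d2 = nn_conv(w[2], w[3], 3L, stride = 2L),
              e3 = .unet_block(w[3], w[3]),
              d3 = nn_conv(w[3], w[4], 3L, stride = 2L),
              bott = .unet_block(w[4], w[4]),
              u3 = nn_conv(w[4], w[3], 3L),
              r3 = .unet_block(w[3] * 2L, w[3]),
              u2 = nn_conv(w[3], w[2], 3L),
              r2 = .unet_block(w[2] * 2L, w[2]),
              u1 = nn_conv(w[2], w[1], 3L),
              r1 = .unet_block(w[1] * 2L, w[1]),
              out = nn_conv(w[1], cfg$out_channels, 1L, zero_init = TRUE))
    m$fwd <- function(x, training = FALSE, ...) {
      d <- dim(ad_value(x))
      if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
        stop("input height/width must be divisible by 16 (pad the image)",
             call. = FALSE)
      s1 <- m$e1$fwd(x)                       # H
      s2 <- m$e2$fwd(m$d1$fwd(s1))            # H/2
      s3 <- m$e3$fwd(m$d2$fwd(s2))            # H/4
      b <- m$bott$fwd(m$d3$fwd(s3))           # H/8
      h <- m$r3$fwd(ad_concat_c(list(m$u3$fwd(ad_upsample2(b)), s3)))
      h <- m$r2$fwd(ad_concat_c(list(m$u2$fwd(ad_upsample2(h)), s2)))
      h <- m$r1$fwd(ad_concat_c(list(m$u1$fwd(ad_upsample2(h)), s1)))
      ad_sigmoid(m$out$fwd(h))
    }
    class(m) <- c("unet_model", "nn_module", "list")
    m
  })
}

#' Forward pass of the baseline network
#' @inheritParams mpfnet_forward
#' @param model module from \code{\link{build_unet}}.
#' @return (H, W, K) prediction array in [0, 1].
#' @export
unet_baseline_forward <- function(x, model, training = FALSE) {
  if (training) ad_value(model$fwd(x, training = TRUE))
  else ad_no_grad(ad_value(model$fwd(x)))
}

#' Build a model from its configuration object
#' @param cfg an \code{mpfnet_config} or \code{unet_config}.
#' @return a model module.
#' @export
build_model <- function(cfg) {
  if (inherits(cfg, "mpfnet_config")) build_mpfnet(cfg)
  else if (inherits(cfg, "unet_config")) build_unet(cfg)
  else stop("unknown model configuration", call. = FALSE)
}

#' Save a model checkpoint (config + weights)
#' @param model a built model.
#' @param path output path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$cfg, state = nn_state_dict(model)), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path path written by \code{\link{save_checkpoint}}.
#' @return the rebuilt model with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  nn_load_state(model, ck$state)
  model
}
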