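# Multiple parallel fusion: at each pyramid level the transformer map s_i
# passes through squeeze-excitation channel attention, the CNN map h_i
# through pyramid-kernel spatial attention, a bilinear Hadamard term
# couples the two branches, and the three results are fused by a residual
# concat-convolution. The fused levels are then cascaded coarse-to-fine
# through attention-gated skip connections.

#' Fusion module configuration
#'
#' @param s_dims channel widths of the transformer maps (s0, s1, s2).
#' @param h_dims channel widths of the CNN maps (h0, h1, h2).
#' @param l_dims common projection widths L_i of the bilinear term.
#' @param f_dims fused widths F_i per level.
#' @param se_ratio squeeze-excitation reduction ratio (divides s_dims).
#' @param gate_dim intermediate width of the attention gate.
#' @param spatial_kernels pyramid kernel sides (2k - 1 for k = 1..3).
#' @param normalize_spatial divide the spatial attention map (a sum of
#'   three sigmoids, range (0, 3)) by 3; off by default.
#' @return list of class \code{fusion_config}.
#' @export
fusion_config <- function(s_dims, h_dims, l_dims = pmin(s_dims, h_dims),
                          f_dims = h_dims, se_ratio = 4L, gate_dim = 16L,
                          spatial_kernels = c(1L, 3L, 5L),
                          normalize_spatial = FALSE) {
  stopifnot(length(s_dims) == 3L, length(h_dims) == 3L,
            all(s_dims %% se_ratio == 0L),
            all(spatial_kernels %% 2L == 1L))
  structure(list(s_dims = as.integer(s_dims), h_dims = as.integer(h_dims),
                 l_dims = as.integer(l_dims), f_dims = as.integer(f_dims),
                 se_ratio = as.integer(se_ratio),
                 gate_dim = as.integer(gate_dim),
                 spatial_kernels = as.integer(spatial_kernels),
                 normalize_spatial = normalize_spatial),
            class = "fusion_config")
}

#' Build a squeeze-excitation channel attention block
#' @param C channel count of the map it rescales.
#' @param ratio reduction ratio (C divisible by ratio).
#' @return module with \code{$fwd(v)}.
#' @export
nn_channel_attention <- function(C, ratio = 4L) {
  if (C %% ratio != 0L)
    stop("channel count must be divisible by the SE ratio", call. = FALSE)
  m <- list(fc1 = nn_dense(C, C %/% ratio),
            fc2 = nn_dense(C %/% ratio, C))
  m$fwd <- function(v) channel_attention(v, m)
  class(m) <- c("nn_module", "list")
  m
}

#' Squeeze-excitation channel attention
#'
#' Global average pooling squeezes each channel to a descriptor z; the
#' excitation MLP with a sigmoid gate produces per-channel scales
#' \code{s = sigmoid(W2 relu(W1 z))} in (0, 1), which rescale the input
#' channels. With all weights zero every scale is 0.5 (input halved).
#'
#' @param v (H, W, C) tensor or array.
#' @param block module from \code{\link{nn_channel_attention}}.
#' @return rescaled (H, W, C) tensor.
#' @export
channel_attention <- function(v, block) {
  v <- .as_ad(v)
  z <- ad_global_avgpool(v)
  s <- ad_sigmoid(block$fc2$fwd(ad_relu(block$fc1$fwd(z))))
  ad_scale_channels(v, s)
}

#' Build a pyramid-kernel spatial attention block
#' @param kernels odd kernel sides of the pyramid convolutions.
#' @param normalize divide the attention map by the number of kernels.
#' @return module with \code{$fwd(f)}.
#' @export
nn_spatial_attention <- function(kernels = c(1L, 3L, 5L),
                                 normalize = FALSE) {
  m <- list(convs = lapply(kernels, function(K) nn_conv(2L, 1L, K)),
            normalize = normalize, n_k = length(kernels))
  m$fwd <- function(f) spatial_attention(f, m)
  class(m) <- c("nn_module", "list")
  m
}

#' Pyramid-kernel spatial attention
#'
#' Channel-wise mean and max maps are concatenated into a 2-channel stack,
#' convolved at each pyramid scale, and the sigmoids of the results are
#' summed into the spatial attention map (elementwise range (0, n_kernels)),
#' which multiplies the input. With all weights zero the map is a constant
#' 1.5 for the default three kernels.
#'
#' @param f (H, W, C) tensor or array.
#' @param block module from \code{\link{nn_spatial_attention}}.
#' @param return_map also return the attention map value.
#' @return weighted (H, W, C) tensor (or list with \code{out}, \code{map}).
#' @export
spatial_attention <- function(f, block, return_map = FALSE) {
  f <- .as_ad(f)
  pooled <- ad_concat_c(list(ad_chan_mean(f), ad_chan_max(f)))
  acc <- NULL
  for (cv in block$convs) {
    sg <- ad_sigmoid(cv$fwd(pooled))
    acc <- if (is.null(acc)) sg else ad_add(acc, sg)
  }
  if (isTRUE(block$normalize)) acc <- ad_smul(acc, 1 / block$n_k)
  out <- ad_mul_map(f, acc)
  if (return_map) list(out = out, map = ad_value(acc)) else out
}

#' Build a bilinear Hadamard fusion block
#' @param s_dim,h_dim channel widths of the transformer and CNN maps.
#' @param l_dim common projection width.
#' @return module with \code{$fwd(s, h)}.
#' @export
nn_bilinear_hadamard <- function(s_dim, h_dim, l_dim) {
  m <- list(W1 = nn_conv(s_dim, l_dim, 1L, bias = FALSE),
            W2 = nn_conv(h_dim, l_dim, 1L, bias = FALSE),
            conv = nn_conv(l_dim, l_dim, 3L))
  m$fwd <- function(s, h) bilinear_hadamard(s, h, m)
  class(m) <- c("nn_module", "list")
  m
}

#' Bilinear Hadamard coupling of the two branches
#'
#' Channel-wise linear projections of the transformer map (W1) and the CNN
#' map (W2) to a common width, elementwise product, then a 3x3 convolution:
#' the fusion term is bilinear in the two branch activations.
#'
#' @param s transformer map (H, W, D) tensor or array.
#' @param h CNN map (H, W, C) tensor or array at the same spatial size.
#' @param block module from \code{\link{nn_bilinear_hadamard}}.
#' @return (H, W, L) tensor.
#' @export
bilinear_hadamard <- function(s, h, block) {
  s <- .as_ad(s); h <- .as_ad(h)
  ds <- dim(ad_value(s)); dh <- dim(ad_value(h))
  if (!identical(ds[1:2], dh[1:2]))
    stop("branch maps must share spatial size", call. = FALSE)
  block$conv$fwd(ad_mul(block$W1$fwd(s), block$W2$fwd(h)))
}

#' Build a residual fusion block (concat + conv with projection shortcut)
#' @param in_dims channel widths of the three fused inputs.
#' @param out_dim fused output width.
#' @return module with \code{$fwd(b, s, h)}.
#' @export
nn_residual_fuse <- function(in_dims, out_dim) {
  tot <- sum(in_dims)
  m <- list(conv = nn_conv(tot, out_dim, 3L),
            proj = nn_conv(tot, out_dim, 1L, bias = FALSE),
            norm = nn_instnorm(out_dim))
  m$fwd <- function(b, s, h) residual_fuse(b, s, h, m)
  class(m) <- c("nn_module", "list")
  m
}

#' Residual fusion of the bilinear, channel- and spatial-attended maps
#'
#' Concatenates the three inputs (in this order), applies a 3x3
#' convolution to the fused width, adds a 1x1 projection shortcut of the
#' concatenation, and instance-normalizes the sum. The normalization
#' keeps the fused scale comparable across levels: the bilinear term
#' grows quadratically in the branch activations, and without it the
#' cascade saturates the prediction head.
#'
#' @param b,s,h (H, W, *) tensors at one spatial size.
#' @param block module from \code{\link{nn_residual_fuse}}.
#' @return (H, W, out_dim) tensor.
#' @export
residual_fuse <- function(b, s, h, block) {
  cat_ <- ad_concat_c(list(.as_ad(b), .as_ad(s), .as_ad(h)))
  block$norm$fwd(ad_add(block$conv$fwd(cat_), block$proj$fwd(cat_)))
}

#' Build an attention gate
#' @param s_dim skip-map channel width.
#' @param g_dim gating-map channel width.
#' @param int_dim shared intermediate width.
#' @return module with \code{$fwd(s, g)}.
#' @export
nn_attention_gate <- function(s_dim, g_dim, int_dim = 16L) {
  m <- list(Wx = nn_conv(s_dim, int_dim, 1L, bias = FALSE),
            Wg = nn_conv(g_dim, int_dim, 1L, bias = TRUE),
            psi = nn_conv(int_dim, 1L, 1L, bias = TRUE))
  m$fwd <- function(s, g) attention_gate(s, g, m)
  class(m) <- c("nn_module", "list")
  m
}

#' Attention-gated skip connection
#'
#' \code{q = psi' relu(Wx' s + Wg' g + b); alpha = sigmoid(q); s_hat =
#' s * alpha}: the coarser gating signal decides, pixel by pixel, how much
#' of the skip map passes. alpha lies in (0, 1); with zero weights and
#' biases it is exactly 0.5 (skip halved).
#'
#' @param s skip map (H, W, C) tensor or array.
#' @param g gating map at the same spatial size.
#' @param gate module from \code{\link{nn_attention_gate}}.
#' @param return_alpha also return the attention coefficient map.
#' @return gated (H, W, C) tensor (or list with \code{out}, \code{alpha}).
#' @export
attention_gate <- function(s, g, gate, return_alpha = FALSE) {
  s <- .as_ad(s); g <- .as_ad(g)
  q <- gate$psi$fwd(ad_relu(ad_add(gate$Wx$fwd(s), gate$Wg$fwd(g))))
  alpha <- ad_sigmoid(q)
  out <- ad_mul_map(s, alpha)
  if (return_alpha) list(out = out, alpha = ad_value(alpha)) else out
}

#' Build the full multi-level fusion module
#' @param cfg a \code{\link{fusion_config}}.
#' @return module with \code{$fwd(pyramid, maps)}.
#' @export
nn_mpf_fusion <- function(cfg) {
  lvl <- function(i) {
    list(se = nn_channel_attention(cfg$s_dims[i], cfg$se_ratio),
         spa = nn_spatial_attention(cfg$spatial_kernels,
                                    cfg$normalize_spatial),
         bil = nn_bilinear_hadamard(cfg$s_dims[i], cfg$h_dims[i],
                                    cfg$l_dims[i]),
         fuse = nn_residual_fuse(c(cfg$l_dims[i], cfg$s_dims[i],
                                   cfg$h_dims[i]), cfg$f_dims[i]))
  }
  m <- list(levels = lapply(1:3, lvl),
            gate1 = nn_attention_gate(cfg$f_dims[2], cfg$f_dims[1],
                                      cfg$gate_dim),
            cas1 = nn_conv(cfg$f_dims[1] + cfg$f_dims[2], cfg$f_dims[2], 3L),
            cas1_n = nn_instnorm(cfg$f_dims[2]),
            gate2 = nn_attention_gate(cfg$f_dims[3], cfg$f_dims[2],
                                      cfg$gate_dim),
            cas2 = nn_conv(cfg$f_dims[2] + cfg$f_dims[3], cfg$f_dims[3], 3L),
            cas2_n = nn_instnorm(cfg$f_dims[3]))
  m$fwd <- function(pyramid, maps, debug = FALSE, ablate_level = NULL)
    mpf_fuse(pyramid, maps, m, debug = debug, ablate_level = ablate_level)
  class(m) <- c("nn_module", "list")
  m
}

#' Multi-level parallel fusion with gated coarse-to-fine cascade
#'
#' Per level i (0 = coarsest, H/16): \code{s_hat = ChannelAttn(s_i)},
#' \code{h_hat = SpatialAttn(h_i)}, \code{b_hat = Conv(s_i W1 . h_i W2)},
#' \code{f_i = Residual(b_hat, s_hat, h_hat)}. The cascade then combines
#' \code{f_hat_{i+1} = Conv([Up(f_i), AG(f_{i+1}, g = Up(f_i))])},
#' upsampling the coarse fusion and using it as the gating context for the
#' finer level, ending at the H/4 map.
#'
#' @param pyramid list with CNN maps \code{h0}, \code{h1}, \code{h2}.
#' @param maps list with transformer maps \code{s0}, \code{s1}, \code{s2}.
#' @param fusion module from \code{\link{nn_mpf_fusion}}.
#' @param debug return per-level intermediates as plain arrays.
#' @param ablate_level if 1, 2 or 3, zero that level's branch inputs
#'   (coarsest first) before fusing.
#' @return finest fused tensor (H/4), or a list when \code{debug = TRUE}.
#' @export
mpf_fuse <- function(pyramid, maps, fusion, debug = FALSE,
                     ablate_level = NULL) {
  ss <- list(.as_ad(maps$s0), .as_ad(maps$s1), .as_ad(maps$s2))
  hh <- list(.as_ad(pyramid$h0), .as_ad(pyramid$h1), .as_ad(pyramid$h2))
  for (i in 1:3) {
    dsi <- dim(ad_value(ss[[i]])); dhi <- dim(ad_value(hh[[i]]))
    if (!identical(dsi[1:2], dhi[1:2]))
      stop("pyramid and decoder maps are misaligned at level ", i - 1L,
           call. = FALSE)
  }
  if (!is.null(ablate_level)) {
    z <- function(t) ad_tensor(ad_value(t) * 0)
    ss[[ablate_level]] <- z(ss[[ablate_level]])
    hh[[ablate_level]] <- z(hh[[ablate_level]])
  }
  f <- vector("list", 3L)
  lv <- vector("list", 3L)
  for (i in 1:3) {
    L <- fusion$levels[[i]]
    s_hat <- channel_attention(ss[[i]], L$se)
    h_hat <- spatial_attention(hh[[i]], L$spa)
    b_hat <- bilinear_hadamard(ss[[i]], hh[[i]], L$bil)
    f[[i]] <- residual_fuse(b_hat, s_hat, h_hat, L$fuse)
    if (debug)
      lv[[i]] <- list(s_hat = ad_value(s_hat), h_hat = ad_value(h_hat),
                      b_hat = ad_value(b_hat), f = ad_value(f[[i]]))
  }
  up0 <- ad_upsample2(f[[1]])
  f1h <- fusion$cas1_n$fwd(fusion$cas1$fwd(ad_concat_c(list(up0,
    attention_gate(f[[2]], up0, fusion$gate1)))))
  up1 <- ad_upsample2(f1h)
  f2h <- fusion$cas2_n$fwd(fusion$cas2$fwd(ad_concat_c(list(up1,
    attention_gate(f[[3]], up1, fusion$gate2)))))
  if (debug) list(out = f2h, levels = lv, f1_hat = ad_value(f1h)) else f2h
}
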