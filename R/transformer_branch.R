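# Patch-embedding transformer encoder with a progressive-upsampling
# decoder. The input stack is cut into M x M patches, linearly embedded,
# summed with a learnable positional table and passed through L pre-norm
# transformer layers (multi-head self-attention + MLP, both with residual
# connections). The decoder reshapes the token sequence back onto the H/16
# grid and recovers H/8 and H/16 -> H/4 maps by upsample-convolution, so
# the three output maps align with the CNN feature pyramid.

#' Transformer branch configuration
#'
#' @param in_channels input channel count C.
#' @param patch patch side length M (input size must be divisible by it).
#' @param S0 token embedding dimension.
#' @param L number of transformer layers.
#' @param heads number of attention heads m (S0 divisible by m; per-head
#'   dimension d = S0 / m).
#' @param mlp_ratio MLP hidden width as a multiple of S0.
#' @param dropout dropout rate inside MSA output and MLP (training only).
#' @param decoder_dims channel widths (C0, D1, D2) of the decoder maps at
#'   H/16, H/8 and H/4.
#' @return list of class \code{transformer_config}.
#' @export
transformer_config <- function(in_channels, patch = 16L, S0 = 256L, L = 8L,
                               heads = 4L, mlp_ratio = 4L, dropout = 0.1,
                               decoder_dims = c(256L, 128L, 64L)) {
  stopifnot(S0 %% heads == 0L, L >= 1L, length(decoder_dims) == 3L)
  structure(list(in_channels = as.integer(in_channels),
                 patch = as.integer(patch), S0 = as.integer(S0),
                 L = as.integer(L), heads = as.integer(heads),
                 d = as.integer(S0 %/% heads),
                 mlp_ratio = mlp_ratio, dropout = dropout,
                 decoder_dims = as.integer(decoder_dims)),
            class = "transformer_config")
}

#' Patch embedding
#'
#' Cuts the image into non-overlapping M x M patches, flattens each and
#' maps it linearly (bias-free) to S0 dimensions, then adds the learnable
#' positional table: \code{z0 = x0 + pos}.
#'
#' @param x (H, W, C) array or tensor.
#' @param embed module with the embedding matrix and positional table.
#' @return N x S0 token tensor.
#' @export
patch_embed <- function(x, embed) embed$fwd(x)

#' Build a patch-embedding module
#' @param cfg a \code{\link{transformer_config}}.
#' @param image_size input side length (fixes the token count N).
#' @return module with \code{$fwd(x)}; fields \code{E} (M^2 C x S0) and
#'   \code{pos} (N x S0).
#' @export
nn_patch_embed <- function(cfg, image_size) {
  M <- cfg$patch
  stopifnot(image_size %% M == 0L)
  Hg <- image_size %/% M
  N <- Hg * Hg
  pdim <- M * M * cfg$in_channels
  m <- list(E = ad_tensor(.he_init(pdim, cfg$S0, pdim), TRUE),
            pos = ad_tensor(matrix(stats::rnorm(N * cfg$S0, sd = 0.02),
                                   N, cfg$S0), TRUE),
            M = M, N = N)
  m$fwd <- function(x) {
    tok <- ad_extract_patches(.as_ad(x), m$M)
    if (nrow(ad_value(tok)) != m$N)
      stop("input size does not match the positional table", call. = FALSE)
    ad_add(ad_matmul(tok, m$E), m$pos)
  }
  class(m) <- c("nn_module", "list")
  m
}

#' Scaled dot-product self-attention for one head
#'
#' \code{SA(z) = softmax(q k' / sqrt(d)) v} with \code{q = z Wq},
#' \code{k = z Wk}, \code{v = z Wv}.
#'
#' @param z N x S token matrix (tensor or plain).
#' @param Wq,Wk,Wv S x d projection matrices (tensors or plain).
#' @param return_attn also return the attention matrix (plain value).
#' @return N x d tensor (or list with \code{out} and \code{attn}).
#' @export
self_attention <- function(z, Wq, Wk, Wv, return_attn = FALSE) {
  z <- .as_ad(z)
  q <- ad_matmul(z, .as_ad(Wq))
  k <- ad_matmul(z, .as_ad(Wk))
  v <- ad_matmul(z, .as_ad(Wv))
  d <- ncol(ad_value(q))
  attn <- ad_softmax_rows(ad_smul(ad_matmul_bt(q, k), 1 / sqrt(d)))
  out <- ad_matmul(attn, v)
  if (return_attn) list(out = out, attn = ad_value(attn)) else out
}

#' Build a multi-head self-attention module
#' @param S token dimension.
#' @param heads number of heads (d = S / heads per head).
#' @param dropout dropout on the output projection.
#' @return module with \code{$fwd(z, training)}.
#' @export
nn_msa <- function(S, heads, dropout = 0) {
  d <- S %/% heads
  hs <- lapply(seq_len(heads), function(h)
    list(Wq = ad_tensor(.he_init(S, d, S), TRUE),
         Wk = ad_tensor(.he_init(S, d, S), TRUE),
         Wv = ad_tensor(.he_init(S, d, S), TRUE)))
  m <- list(heads = hs,
            Wo = ad_tensor(.he_init(heads * d, S, heads * d), TRUE),
            bo = ad_tensor(numeric(S), TRUE),
            rate = dropout)
  m$fwd <- function(z, training = FALSE) {
    outs <- lapply(m$heads, function(h)
      self_attention(z, h$Wq, h$Wk, h$Wv))
    cat_ <- if (length(outs) == 1L) outs[[1]] else {
      # concatenate head outputs along columns
      vals <- lapply(outs, ad_value)
      conc <- do.call(cbind, vals)
      widths <- vapply(vals, ncol, numeric(1))
      .ad_op(conc, outs, function(g) {
        res <- vector("list", length(outs))
        at <- 0L
        for (k in seq_along(outs)) {
          res[[k]] <- g[, (at + 1L):(at + widths[k]), drop = FALSE]
          at <- at + widths[k]
        }
        res
      })
    }
    out <- ad_linear(cat_, m$Wo, m$bo)
    ad_dropout(out, m$rate, training)
  }
  class(m) <- c("nn_module", "list")
  m
}

#' Multi-head self-attention (functional form)
#' @param z N x S token matrix or tensor.
#' @param msa_module module from \code{\link{nn_msa}}.
#' @param training apply dropout?
#' @return N x S tensor.
#' @export
msa <- function(z, msa_module, training = FALSE) msa_module$fwd(.as_ad(z), training)

#' Build one pre-norm transformer layer
#'
#' \code{a = z + MSA(LN(z)); z' = a + MLP(LN(a))} with
#' MLP = linear - GELU - dropout - linear.
#'
#' @param cfg a \code{\link{transformer_config}}.
#' @return module with \code{$fwd(z, training)}.
#' @export
nn_transformer_layer <- function(cfg) {
  S <- cfg$S0
  hid <- as.integer(round(cfg$mlp_ratio * S))
  m <- list(ln1 = nn_layernorm(S),
            msa = nn_msa(S, cfg$heads, cfg$dropout),
            ln2 = nn_layernorm(S),
            fc1 = nn_dense(S, hid),
            fc2 = nn_dense(hid, S),
            rate = cfg$dropout)
  m$fwd <- function(z, training = FALSE) {
    a <- ad_add(z, m$msa$fwd(m$ln1$fwd(z), training))
    h <- ad_dropout(ad_gelu(m$fc1$fwd(m$ln2$fwd(a))), m$rate, training)
    ad_add(a, m$fc2$fwd(h))
  }
  class(m) <- c("nn_module", "list")
  m
}

#' Apply one transformer layer
#' @param z N x S token tensor.
#' @param layer module from \code{\link{nn_transformer_layer}}.
#' @param training apply dropout?
#' @return N x S tensor.
#' @export
transformer_layer <- function(z, layer, training = FALSE)
  layer$fwd(.as_ad(z), training)

#' Build the full transformer branch (encoder + progressive decoder)
#' @param cfg a \code{\link{transformer_config}}.
#' @param image_size input side length.
#' @return module with \code{$fwd(x, training)} returning decoder maps
#'   \code{s0} (H/16), \code{s1} (H/8), \code{s2} (H/4).
#' @export
nn_transformer_branch <- function(cfg, image_size) {
  dd <- cfg$decoder_dims
  m <- list(embed = nn_patch_embed(cfg, image_size),
            layers = lapply(seq_len(cfg$L), function(i)
              nn_transformer_layer(cfg)),
            dec0 = nn_conv(cfg$S0, dd[1], 3L),
            dec0_n = nn_instnorm(dd[1]),
            dec1 = nn_conv(dd[1], dd[2], 3L),
            dec1_n = nn_instnorm(dd[2]),
            dec2 = nn_conv(dd[2], dd[3], 3L),
            dec2_n = nn_instnorm(dd[3]),
            Hg = image_size %/% cfg$patch,
            patch = cfg$patch)
  m$fwd <- function(x, training = FALSE) {
    z <- m$embed$fwd(x)
    for (ly in m$layers) z <- ly$fwd(z, training)
    grid <- ad_tokens_to_grid(z, m$Hg, m$Hg)     # H/16 when M = 16
    s0 <- ad_relu(m$dec0_n$fwd(m$dec0$fwd(grid)))
    s1 <- ad_relu(m$dec1_n$fwd(m$dec1$fwd(ad_upsample2(s0))))
    s2 <- ad_relu(m$dec2_n$fwd(m$dec2$fwd(ad_upsample2(s1))))
    list(s0 = s0, s1 = s1, s2 = s2, tokens = z)
  }
  class(m) <- c("nn_module", "list")
  m
}

#' Decode a token sequence to the multi-scale maps
#' @param x input image array/tensor.
#' @param branch module from \code{\link{nn_transformer_branch}}.
#' @param training apply dropout?
#' @return list with \code{s0}, \code{s1}, \code{s2} (and final tokens).
#' @export
progressive_decode <- function(x, branch, training = FALSE)
  branch$fwd(x, training)

#' Zero the residual-branch output projections of a transformer branch
#'
#' Sets every MSA output projection and every MLP second linear layer
#' (weights and biases) to zero, which makes each pre-norm layer — and
#' therefore the whole encoder — the identity map on tokens.
#'
#' @param branch module from \code{\link{nn_transformer_branch}}, modified
#'   in place.
#' @export
nn_zero_residual_out <- function(branch) {
  for (ly in branch$layers) {
    ly$msa$Wo$value[] <- 0
    ly$msa$bo$value[] <- 0
    ly$fc2$W$value[] <- 0
    ly$fc2$b$value[] <- 0
  }
  invisible(branch)
}
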