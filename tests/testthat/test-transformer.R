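# Transformer branch: patch embedding, attention oracles, layer algebra,
# decoder geometry.

test_that("patch embedding: token count, bias-free zero map, round trip", {
  cfg <- transformer_config(2L, patch = 16L, S0 = 8L, L = 1L, heads = 2L,
                            decoder_dims = c(4L, 4L, 4L))
  set.seed(1)
  emb <- nn_patch_embed(cfg, 64L)
  expect_equal(emb$N, 16L)                       # (64/16)^2 tokens
  z0 <- ad_value(patch_embed(array(0, c(64, 64, 2)), emb))
  expect_equal(z0, ad_value(emb$pos))            # bias-free: only pos left
  emb$pos$value[] <- 0
  expect_true(all(ad_value(patch_embed(array(0, c(64, 64, 2)), emb)) == 0))
  # identity embedding round-trips the image exactly
  cfg_id <- transformer_config(1L, patch = 4L, S0 = 16L, L = 1L, heads = 2L,
                               decoder_dims = c(4L, 4L, 4L))
  set.seed(2)
  emb_id <- nn_patch_embed(cfg_id, 8L)
  emb_id$E$value <- diag(16)
  emb_id$pos$value[] <- 0
  x <- rand_arr(c(8, 8, 1), 3)
  tok <- ad_value(patch_embed(x, emb_id))
  expect_equal(unpatchify(tok, 8, 8, 1, 4), x)
  expect_error(patch_embed(array(0, c(32, 32, 2)), emb), "positional")
})

test_that("self-attention matches an explicit two-loop oracle", {
  set.seed(5)
  z <- matrix(rnorm(3 * 4), 3, 4)
  Wq <- matrix(rnorm(8), 4, 2); Wk <- matrix(rnorm(8), 4, 2)
  Wv <- matrix(rnorm(8), 4, 2)
  got <- self_attention(z, Wq, Wk, Wv, return_attn = TRUE)
  q <- z %*% Wq; k <- z %*% Wk; v <- z %*% Wv
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) {
    sc <- numeric(3)
    for (j in 1:3) sc[j] <- sum(q[i, ] * k[j, ]) / sqrt(2)
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (j in 1:3) oracle[i, ] <- oracle[i, ] + w[j] * v[j, ]
  }
  expect_lt(max(abs(ad_value(got$out) - oracle)), 1e-6)
  expect_equal(rowSums(got$attn), rep(1, 3), tolerance = 1e-9)
  # single token: weight exactly 1, output = v1
  z1 <- matrix(rnorm(4), 1, 4)
  o1 <- self_attention(z1, Wq, Wk, Wv, return_attn = TRUE)
  expect_equal(o1$attn, matrix(1, 1, 1))
  expect_equal(ad_value(o1$out), z1 %*% Wv, tolerance = 1e-12)
  # identical tokens: uniform weights, output = mean of values
  zr <- matrix(rep(rnorm(4), each = 5), 5, 4)
  or_ <- self_attention(zr, Wq, Wk, Wv, return_attn = TRUE)
  expect_equal(or_$attn, matrix(0.2, 5, 5), tolerance = 1e-12)
})

test_that("multi-head attention equals the loop-over-heads reference", {
  set.seed(7)
  S <- 8L
  ms <- nn_msa(S, heads = 2L, dropout = 0)
  z <- matrix(rnorm(4 * S), 4, S)
  got <- ad_value(msa(z, ms))
  heads <- lapply(ms$heads, function(h) {
    q <- z %*% ad_value(h$Wq); k <- z %*% ad_value(h$Wk)
    v <- z %*% ad_value(h$Wv)
    sc <- q %*% t(k) / sqrt(ncol(q))
    w <- exp(sc - apply(sc, 1, max)); w <- w / rowSums(w)
    w %*% v
  })
  ref <- sweep(do.call(cbind, heads) %*% ad_value(ms$Wo), 2L,
               ad_value(ms$bo), "+")
  expect_lt(max(abs(got - ref)), 1e-6)
  # m = 1 reduces to SA followed by the output projection
  set.seed(8)
  m1 <- nn_msa(S, heads = 1L, dropout = 0)
  g1 <- ad_value(msa(z, m1))
  sa <- ad_value(self_attention(z, m1$heads[[1]]$Wq, m1$heads[[1]]$Wk,
                                m1$heads[[1]]$Wv))
  r1 <- sweep(sa %*% ad_value(m1$Wo), 2L, ad_value(m1$bo), "+")
  expect_lt(max(abs(g1 - r1)), 1e-12)
})

test_that("the encoder is permutation-equivariant when positions are zero", {
  cfg <- transformer_config(2L, patch = 16L, S0 = 8L, L = 3L, heads = 2L,
                            dropout = 0, decoder_dims = c(4L, 4L, 4L))
  set.seed(9)
  br <- nn_transformer_branch(cfg, 64L)
  z <- matrix(rnorm(16 * 8), 16, 8)
  run_layers <- function(zz) {
    t <- ad_tensor(zz)
    for (ly in br$layers) t <- ly$fwd(t)
    ad_value(t)
  }
  perm <- sample(16)
  expect_equal(run_layers(z)[perm, ], run_layers(z[perm, ]),
               tolerance = 1e-9)
})

test_that("attention rows sum to one through all layers and heads", {
  cfg <- transformer_config(2L, patch = 16L, S0 = 8L, L = 2L, heads = 4L,
                            dropout = 0, decoder_dims = c(4L, 4L, 4L))
  set.seed(11)
  br <- nn_transformer_branch(cfg, 32L)
  z <- matrix(rnorm(4 * 8), 4, 8)
  for (ly in br$layers) {
    zin <- ad_value(ly$ln1$fwd(ad_tensor(z)))
    for (h in ly$msa$heads) {
      at <- self_attention(zin, h$Wq, h$Wk, h$Wv, return_attn = TRUE)$attn
      expect_equal(rowSums(at), rep(1, 4), tolerance = 1e-6)
    }
    z <- ad_value(ly$fwd(ad_tensor(z)))
  }
})

test_that("zeroed residual projections make the 8-layer encoder the identity", {
  cfg <- transformer_config(2L, patch = 16L, S0 = 16L, L = 8L, heads = 4L,
                            dropout = 0, decoder_dims = c(4L, 4L, 4L))
  set.seed(13)
  br <- nn_transformer_branch(cfg, 64L)
  nn_zero_residual_out(br)
  z <- matrix(rnorm(16 * 16) * 3, 16, 16)
  t <- ad_tensor(z)
  for (ly in br$layers) t <- ly$fwd(t)
  expect_lt(max(abs(ad_value(t) - z)), 1e-6)
})

test_that("progressive decoder emits aligned multi-scale maps", {
  cfg <- transformer_config(3L, patch = 16L, S0 = 8L, L = 1L, heads = 2L,
                            dropout = 0, decoder_dims = c(6L, 5L, 4L))
  set.seed(15)
  br <- nn_transformer_branch(cfg, 64L)
  x <- rand_arr(c(64, 64, 3), 16)
  maps <- ad_no_grad(progressive_decode(x, br))
  expect_equal(dim(ad_value(maps$s0)), c(4, 4, 6))
  expect_equal(dim(ad_value(maps$s1)), c(8, 8, 5))
  expect_equal(dim(ad_value(maps$s2)), c(16, 16, 4))
  # matches the CNN pyramid scales for the same input
  set.seed(17)
  pyr <- ad_no_grad(cnn_encode(x, nn_cnn_branch(
    cnn_config(3L, c(4L, 4L, 4L, 4L), 1L))))
  expect_equal(dim(ad_value(maps$s0))[1:2], dim(ad_value(pyr$h0))[1:2])
  expect_equal(dim(ad_value(maps$s1))[1:2], dim(ad_value(pyr$h1))[1:2])
  expect_equal(dim(ad_value(maps$s2))[1:2], dim(ad_value(pyr$h2))[1:2])
  # layer norm keeps large-magnitude inputs finite
  big <- ad_value(progressive_decode(rand_arr(c(64, 64, 3), 18) * 1e3,
                                     br)$s2)
  expect_true(all(is.finite(big)))
})
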