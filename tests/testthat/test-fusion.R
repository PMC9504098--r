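# Fusion module: attention-block oracles, zero-weight closed forms,
# bilinearity, bounds, differentiability of the full fusion path.

test_that("channel attention: pooled descriptor oracle, zero-weight halving, bound", {
  set.seed(1)
  x <- rand_arr(c(8, 8, 4), 2)
  z <- ad_value(ad_global_avgpool(ad_tensor(x)))
  oracle <- vapply(1:4, function(c) {
    s <- 0
    for (i in 1:8) for (j in 1:8) s <- s + x[i, j, c]
    s / 64
  }, numeric(1))
  expect_equal(as.vector(z), oracle, tolerance = 1e-12)
  se <- nn_channel_attention(4L, ratio = 4L)
  zero_all_params(se)
  out <- ad_value(channel_attention(x, se))
  expect_equal(out, x / 2, tolerance = 1e-12)
  set.seed(3)
  se2 <- nn_channel_attention(4L, ratio = 2L)
  out2 <- ad_value(channel_attention(x, se2))
  for (c in 1:4)
    expect_lte(max(abs(out2[, , c])), max(abs(x[, , c])))  # s_c < 1
  expect_error(nn_channel_attention(5L, ratio = 4L), "divisible")
})

test_that("spatial attention: pooling oracle, zero-weight 1.5x, (0,3) bound", {
  set.seed(5)
  x <- rand_arr(c(6, 6, 3), 6)
  mean_map <- ad_value(ad_chan_mean(ad_tensor(x)))[, , 1]
  max_map <- ad_value(ad_chan_max(ad_tensor(x)))[, , 1]
  for (i in 1:6) for (j in 1:6) {
    expect_equal(mean_map[i, j], mean(x[i, j, ]), tolerance = 1e-12)
    expect_equal(max_map[i, j], max(x[i, j, ]), tolerance = 1e-12)
  }
  sp <- nn_spatial_attention()
  zero_all_params(sp)
  got <- spatial_attention(x, sp, return_map = TRUE)
  expect_equal(ad_value(got$out), 1.5 * x, tolerance = 1e-12)
  expect_true(all(got$map == 1.5))
  set.seed(7)
  sp2 <- nn_spatial_attention()
  m2 <- spatial_attention(x, sp2, return_map = TRUE)$map
  expect_true(all(m2 > 0 & m2 < 3))
})

test_that("bilinear Hadamard: annihilator, bilinearity, per-pixel loop oracle", {
  set.seed(9)
  bl <- nn_bilinear_hadamard(3L, 2L, 2L)
  s <- rand_arr(c(2, 2, 3), 10)
  h <- rand_arr(c(2, 2, 2), 11)
  zero <- ad_value(bilinear_hadamard(array(0, c(2, 2, 3)), h, bl))
  bias_map <- array(rep(ad_value(bl$conv$b), each = 4), c(2, 2, 2))
  expect_equal(zero, bias_map, tolerance = 1e-12)
  # scaling one operand scales the pre-conv product linearly
  f1 <- ad_value(bilinear_hadamard(s, h, bl)) - bias_map
  f3 <- ad_value(bilinear_hadamard(3 * s, h, bl)) - bias_map
  expect_equal(f3, 3 * f1, tolerance = 1e-9)
  # explicit per-pixel projection loop for the pre-conv product
  W1 <- ad_value(bl$W1$W); W2 <- ad_value(bl$W2$W)
  prod_oracle <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2)
    prod_oracle[i, j, ] <- (s[i, j, ] %*% W1) * (h[i, j, ] %*% W2)
  got_prod <- ad_value(ad_mul(bl$W1$fwd(ad_tensor(s)),
                              bl$W2$fwd(ad_tensor(h))))
  expect_lt(max(abs(got_prod - prod_oracle)), 1e-9)
  expect_error(bilinear_hadamard(rand_arr(c(4, 4, 3), 1), h, bl), "spatial")
})

test_that("residual fuse: zero maps to zero, fixed output width, order matters", {
  set.seed(13)
  rf <- nn_residual_fuse(c(2L, 3L, 4L), 5L)
  # zero inputs give a constant pre-norm map, which the affine instance
  # norm sends to its (zero-initialized) shift
  zed <- ad_value(residual_fuse(array(0, c(3, 3, 2)), array(0, c(3, 3, 3)),
                                array(0, c(3, 3, 4)), rf))
  expect_equal(zed, array(0, c(3, 3, 5)), tolerance = 1e-12)
  b <- rand_arr(c(3, 3, 3), 14); s <- rand_arr(c(3, 3, 3), 15)
  h <- rand_arr(c(3, 3, 3), 16)
  rf3 <- nn_residual_fuse(c(3L, 3L, 3L), 5L)
  expect_equal(dim(ad_value(residual_fuse(b, s, h, rf3))), c(3, 3, 5))
  expect_false(isTRUE(all.equal(ad_value(residual_fuse(b, s, h, rf3)),
                                ad_value(residual_fuse(s, b, h, rf3)))))
})

test_that("attention gate: zero-weight halving, bounds, open-gate limit", {
  set.seed(17)
  g8 <- nn_attention_gate(3L, 2L, 4L)
  s <- rand_arr(c(4, 4, 3), 18)
  g <- rand_arr(c(4, 4, 2), 19)
  zero_all_params(g8)
  expect_equal(ad_value(attention_gate(s, g, g8)), s / 2, tolerance = 1e-12)
  set.seed(20)
  g9 <- nn_attention_gate(3L, 2L, 4L)
  al <- attention_gate(s, g, g9, return_alpha = TRUE)$alpha
  expect_true(all(al > 0 & al < 1))
  g9$psi$b$value[] <- 50                          # saturate the gate open
  expect_equal(ad_value(attention_gate(s, g, g9)), s, tolerance = 1e-6)
})

test_that("composed fusion with zero weights follows the analytic constants", {
  fus <- tiny_fusion_module(21)
  zero_all_params(fus)
  fx <- tiny_fusion_inputs(22)
  got <- mpf_fuse(fx$pyramid, fx$maps, fus, debug = TRUE)
  for (i in 1:3) {
    expect_equal(got$levels[[i]]$s_hat,
                 ad_value(fx$maps[[paste0("s", i - 1)]]) / 2,
                 tolerance = 1e-12)
    expect_equal(got$levels[[i]]$h_hat,
                 1.5 * ad_value(fx$pyramid[[paste0("h", i - 1)]]),
                 tolerance = 1e-12)
    expect_true(all(got$levels[[i]]$b_hat == 0))
    expect_true(all(got$levels[[i]]$f == 0))
  }
  expect_true(all(got$f1_hat == 0))               # conv of zero cascade
  expect_true(all(ad_value(got$out) == 0))
})

test_that("fusion cascade geometry and level ablation", {
  fus <- tiny_fusion_module(23)
  fx <- tiny_fusion_inputs(24)
  out <- ad_value(mpf_fuse(fx$pyramid, fx$maps, fus))
  expect_equal(dim(out), c(8, 8, 4))              # finest level, F_2 width
  for (lvl in 1:3) {
    ab <- ad_value(mpf_fuse(fx$pyramid, fx$maps, fus, ablate_level = lvl))
    expect_false(isTRUE(all.equal(out, ab)))      # every level contributes
  }
  bad <- fx$maps; bad$s1 <- rand_arr(c(8, 8, 4), 25)
  expect_error(mpf_fuse(fx$pyramid, bad, fus), "misaligned")
})

test_that("backprop through the full fusion path matches finite differences", {
  fus <- tiny_fusion_module(27)
  fx <- tiny_fusion_inputs(28)
  run <- function(h2v) {
    pyr <- fx$pyramid; pyr$h2 <- h2v
    ad_value(ad_mean_all(mpf_fuse(pyr, fx$maps, fus)))
  }
  h2t <- ad_tensor(ad_value(fx$pyramid$h2), requires_grad = TRUE)
  pyr <- fx$pyramid; pyr$h2 <- h2t
  ad_backward(ad_mean_all(mpf_fuse(pyr, fx$maps, fus)))
  ng <- num_grad(run, ad_value(fx$pyramid$h2), eps = 1e-4)
  expect_lt(rel_err(h2t$grad, ng), 1e-4)
  # and w.r.t. the coarsest transformer map (through SE + cascade)
  run_s <- function(s0v) {
    mp <- fx$maps; mp$s0 <- s0v
    ad_value(ad_mean_all(mpf_fuse(fx$pyramid, mp, fus)))
  }
  s0t <- ad_tensor(ad_value(fx$maps$s0), requires_grad = TRUE)
  mp <- fx$maps; mp$s0 <- s0t
  ad_backward(ad_mean_all(mpf_fuse(fx$pyramid, mp, fus)))
  expect_lt(rel_err(s0t$grad,
                    num_grad(run_s, ad_value(fx$maps$s0), eps = 1e-4)),
            1e-4)
})
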