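# Quality-metric suite against hand-counted fixtures and independent
# brute-force oracles.

test_that("class accuracy: identity, total disagreement, hand-counted OA", {
  set.seed(1)
  img <- matrix(sample(0:2, 36, TRUE), 6, 6)
  ca <- class_accuracy(img, img)
  expect_true(all(ca$per_class == 1, na.rm = TRUE))
  expect_equal(ca$overall, 1)
  bin <- matrix(rep(0:1, 8), 4, 4)
  expect_equal(class_accuracy(1L - bin, bin)$overall, 0)
  # 4x4 two-class fixture with exactly 12 of 16 pixels correct
  truth <- matrix(c(rep(0L, 8), rep(1L, 8)), 4, 4)
  pred <- truth
  pred[c(1, 2, 9, 10)] <- 1L - pred[c(1, 2, 9, 10)]
  expect_equal(class_accuracy(pred, truth)$overall, 0.75)
  expect_error(class_accuracy(matrix(0, 2, 2), matrix(0, 3, 3)), "dimension")
  # class absent from truth -> NA, excluded
  t2 <- matrix(0L, 3, 3); p2 <- matrix(0L, 3, 3); p2[1] <- 1L
  expect_true(is.na(class_accuracy(p2, t2, num_classes = 2L)$per_class["1"]))
})

test_that("mean IoU matches a brute-force set-intersection oracle", {
  expect_equal(mean_iou(rand_mask(8, 8, 0.5, 2), rand_mask(8, 8, 0.5, 2))$miou, 1)
  # disjoint nonempty binary masks: foreground IoU 0
  a <- matrix(0L, 4, 4); a[1:4] <- 1L
  b <- matrix(0L, 4, 4); b[13:16] <- 1L
  expect_equal(mean_iou(a, b, 2L)$per_class[["1"]], 0)
  # 3-class 8x8 fixture vs per-pixel set computation
  set.seed(7)
  truth <- matrix(sample(0:2, 64, TRUE), 8, 8)
  pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
  got <- mean_iou(pred, truth, 3L)
  for (cl in 0:2) {
    inter <- length(intersect(which(pred == cl), which(truth == cl)))
    uni <- length(union(which(pred == cl), which(truth == cl)))
    expect_equal(got$per_class[[as.character(cl)]], inter / uni)
  }
  expect_equal(got$miou, mean(got$per_class))
})

test_that("Pearson correlation: trivial cases and direct-summation oracle", {
  set.seed(11)
  t <- matrix(rnorm(64), 8, 8)
  expect_equal(pearson_cc(t, t), 1)
  expect_equal(pearson_cc(-t + 3, t), -1)
  expect_equal(pearson_cc(2 * t + 5, t), 1)
  p <- matrix(rnorm(256), 16, 16)
  q <- matrix(rnorm(256), 16, 16)
  pv <- as.vector(p); qv <- as.vector(q)
  oracle <- sum((pv - mean(pv)) * (qv - mean(qv))) /
    sqrt(sum((pv - mean(pv))^2) * sum((qv - mean(qv))^2))
  expect_equal(pearson_cc(p, q), oracle, tolerance = 1e-12)
  expect_error(pearson_cc(matrix(1, 3, 3), t[1:3, 1:3]), "variance")
})

test_that("NRMSE closed forms and scale invariance", {
  t <- matrix(rep(c(0, 1), 8), 4, 4)        # checkerboard-ish {0,1}
  p <- t + 0.5
  got <- nrmse(p, t)
  expect_equal(got$mse, 0.25)
  expect_equal(got$rmse, 0.5)
  expect_equal(got$nrmse, 0.5)
  expect_equal(nrmse(t, t)$nrmse, 0)
  set.seed(5)
  a <- matrix(runif(25), 5); b <- matrix(runif(25), 5)
  expect_equal(nrmse(3.7 * a, 3.7 * b)$nrmse, nrmse(a, b)$nrmse,
               tolerance = 1e-12)
  expect_error(nrmse(a, matrix(1, 5, 5)), "constant")
})

test_that("PSNR arithmetic identities", {
  t <- matrix(runif(64), 8, 8)
  expect_equal(psnr(t + 1, t, v_max = 1), 0)    # MSE = v_max^2
  expect_identical(psnr(t, t), Inf)
  # 8-bit example: MSE 65.025 with peak 255 gives exactly 30 dB
  p255 <- t * 0 + sqrt(65.025)
  expect_equal(psnr(p255, t * 0, v_max = 255), 30)
  # doubling MSE costs 10*log10(2) dB
  d <- matrix(1, 8, 8)
  expect_equal(psnr(t + d, t, 1) - psnr(t + sqrt(2) * d, t, 1),
               10 * log10(2), tolerance = 1e-10)
})

test_that("SSIM: identity, constant-image closed form, bounds", {
  set.seed(13)
  t <- matrix(runif(16 * 16), 16, 16)
  prm <- ssim_params(L = 1)
  expect_equal(ssim(t, t, prm), 1)
  a <- 0.3; b <- 0.8
  lum <- (2 * a * b + prm$C1) / (a^2 + b^2 + prm$C1)
  expect_equal(ssim(matrix(a, 16, 16), matrix(b, 16, 16), prm), lum,
               tolerance = 1e-12)
  expect_lt(lum, 1)
  for (s in 1:5) {
    p <- matrix(runif(256), 16, 16)
    q <- matrix(runif(256), 16, 16)
    v <- ssim(p, q, prm)
    expect_gte(v, -1); expect_lte(v, 1)
    expect_equal(v, ssim(q, p, prm), tolerance = 1e-12)  # symmetry
  }
  expect_error(ssim(t[1:4, 1:4], t[1:4, 1:4], prm), "window")
})

test_that("Dice: trivial cases, counting oracle, empty-mask convention", {
  m <- rand_mask(10, 10, 0.5, 3)
  expect_equal(dice(m, m), 1)
  a <- matrix(0L, 4, 4); a[1:3] <- 1L
  b <- matrix(0L, 4, 4); b[13:16] <- 1L
  expect_equal(dice(a, b), 0)
  # |T| = 100, |P| = 80, overlap 60 on a 20x20 grid
  T_ <- matrix(0L, 20, 20); T_[1:100] <- 1L
  P_ <- matrix(0L, 20, 20); P_[41:120] <- 1L
  expect_equal(dice(P_, T_), 2 * 60 / 180)
  expect_equal(dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
})

test_that("binarize: fixed threshold and Otsu vs exhaustive search", {
  bin <- matrix(rep(0:1, 8), 4, 4)
  expect_equal(binarize(bin), bin)
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(sum(binarize(ramp)), 8)          # exactly the upper half
  expect_warning(out <- binarize(matrix(2, 3, 3)), "constant")
  expect_true(all(out == 0L))
  # Gaussian-blob fixture: package Otsu vs brute-force between-class
  # variance maximization over all 256 candidate thresholds
  set.seed(17)
  g <- expand.grid(x = 1:24, y = 1:24)
  img <- matrix(exp(-((g$x - 12)^2 + (g$y - 12)^2) / 18), 24, 24) +
    matrix(runif(576, 0, 0.08), 24, 24)
  img <- (img - min(img)) / (max(img) - min(img))
  cand <- (1:255) / 256
  bcv <- vapply(cand, function(th) {
    lo <- img[img * 256 < th * 256]
    hi <- img[img * 256 >= th * 256]
    if (!length(lo) || !length(hi)) return(0)
    w0 <- length(lo) / length(img); w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  brute <- cand[which.max(bcv)]
  expect_lte(abs(otsu_threshold(img) - brute), 2 / 256)
})

test_that("relative change reproduces published comparison statements", {
  expect_equal(relative_change(0.879, 0.716, "higher_is_better"), 22.77)
  expect_equal(relative_change(0.192, 0.201, "lower_is_better"), 4.48)
  expect_equal(relative_change(0.5, 0.5, "higher_is_better"), 0)
  expect_error(relative_change(1, 0, "higher_is_better"), "zero")
})

test_that("report equals metric ops applied one by one, with zero sd on replicates", {
  set.seed(23)
  truth <- array(runif(32 * 32 * 3), c(32, 32, 3))
  rep1 <- build_report(truth, truth)
  expect_equal(rep1$nrmse, rep(0, 3))
  expect_equal(rep1$ssim, rep(1, 3))
  expect_equal(rep1$pcc, rep(1, 3))
  expect_equal(rep1$dice, rep(1, 3))
  expect_equal(rep1$miou, rep(1, 3))
  pred <- pmin(pmax(truth + array(rnorm(length(truth), 0, 0.1),
                                  dim(truth)), 0), 1)
  rep2 <- build_report(list(pred, pred), list(truth, truth))
  expect_equal(rep2$pcc[1], pearson_cc(pred[, , 1], truth[, , 1]),
               tolerance = 1e-12)
  expect_equal(rep2$nrmse[2], nrmse(pred[, , 2], truth[, , 2])$nrmse,
               tolerance = 1e-12)
  expect_equal(rep2$dice[3],
               dice(binarize(pred[, , 3]), binarize(truth[, , 3])),
               tolerance = 1e-12)
  expect_true(all(rep2$pcc_sd == 0))            # replicated test image
  expect_error(build_report(list(), list()), "empty")
})

test_that("metric symmetry and the Dice-IoU identity on random masks", {
  set.seed(29)
  for (s in 1:20) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    expect_equal(pearson_cc(a, b), pearson_cc(b, a), tolerance = 1e-14)
    expect_equal(mean((a - b)^2), mean((b - a)^2))
    ma <- rand_mask(8, 8, runif(1, 0.2, 0.8), s)
    mb <- rand_mask(8, 8, runif(1, 0.2, 0.8), s + 100)
    expect_equal(dice(ma, mb), dice(mb, ma))
    iou <- mean_iou(ma, mb, 2L)$per_class[["1"]]
    if (!is.na(iou))
      expect_equal(dice(ma, mb), 2 * iou / (1 + iou), tolerance = 1e-14)
  }
})
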