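# Synthetic paired-data generator: determinism, morphology, the linear
# forward model, and the train/test split protocol.

test_that("scene rendering is deterministic and respects its contract", {
  cfg <- scene_config(image_size = 64)
  a <- render_scene(cfg, seed = 5)
  b <- render_scene(cfg, seed = 5)
  expect_identical(a, b)
  c_ <- render_scene(cfg, seed = 6)
  expect_false(identical(a$truth, c_$truth))
  expect_equal(dim(a$truth), c(64, 64, 3))
  expect_true(all(a$truth >= 0 & a$truth <= 1))
  expect_true(all(a$masks %in% 0:1))
  # organelle supports are disjoint from the nucleus by construction
  expect_equal(sum(a$masks[, , 2] & a$masks[, , 1]), 0)
  expect_equal(sum(a$masks[, , 3] & a$masks[, , 1]), 0)
  # zero cells -> empty scene
  e <- render_scene(scene_config(image_size = 64, n_cells = 0L), seed = 1)
  expect_true(all(e$truth == 0) && all(e$masks == 0))
})

test_that("organelle pixel fractions stay within shape-derived bounds", {
  cfg <- scene_config(image_size = 64, n_cells = 2L)
  # nucleus upper bound: n_cells * pi * a * b pixels (ellipse areas),
  # lower bound: one successfully placed ellipse at half nominal area
  ab <- cfg$nucleus_axes * 64
  upper <- cfg$n_cells * pi * ab[1] * ab[2] / 64^2
  fr <- vapply(1:25, function(s)
    mean(render_scene(cfg, seed = s)$masks[, , 1]), numeric(1))
  expect_true(all(fr <= upper * 1.05))
  expect_true(all(fr >= pi * ab[1] * ab[2] / 64^2 * 0.5))
})

test_that("mixing is linear with exact least-squares unmixing at zero noise", {
  cfg <- scene_config(image_size = 64, noise_sd = 0, poisson_gain = 0,
                      background = 0)
  sc <- render_scene(cfg, seed = 9)
  x <- mix_to_input(sc$truth, cfg, seed = 10)
  M <- cfg$mixing_matrix
  X <- matrix(x, ncol = dim(x)[3])
  Tm <- matrix(sc$truth, ncol = 3)
  rec <- t(qr.solve(M, t(X)))            # least-squares unmixing oracle
  expect_lt(max(abs(rec - Tm)), 1e-9)
  # identity-like mixing: C = 3, M = I, zero noise -> input equals truth
  cfg3 <- scene_config(image_size = 64, n_channels = 3L,
                       mixing_matrix = diag(3), noise_sd = 0,
                       poisson_gain = 0, background = 0)
  x3 <- mix_to_input(sc$truth, cfg3, seed = 2)
  expect_equal(x3, sc$truth, tolerance = 1e-12)
  # zero truth, zero background -> pure Gaussian noise, mean near 0
  cfg_n <- scene_config(image_size = 64, background = 0, poisson_gain = 0)
  xn <- mix_to_input(array(0, c(64, 64, 3)), cfg_n, seed = 3)
  expect_lt(abs(mean(xn)), 0.01)
  expect_error(mix_to_input(sc$truth,
    scene_config(image_size = 64,
                 mixing_matrix = -default_mixing_matrix()), 1),
    "nonnegative")
})

test_that("spectral overlap is real: no input channel mirrors one organelle", {
  cfg <- scene_config(image_size = 64)
  worst <- 0
  for (s in c(31, 32, 33)) {
    smp <- make_paired_sample(cfg, s)
    for (ch in seq_len(dim(smp$input)[3])) for (k in 1:3) {
      r <- suppressWarnings(stats::cor(as.vector(smp$input[, , ch]),
                                       as.vector(smp$truth[, , k])))
      if (is.finite(r)) worst <- max(worst, r)
    }
  }
  expect_lt(worst, 0.99)
})

test_that("the task is linearly solvable at zero noise (PCC > 0.8)", {
  cfg <- scene_config(image_size = 64, noise_sd = 0, poisson_gain = 0)
  smp <- make_paired_sample(cfg, 77)
  X <- cbind(1, matrix(smp$input, ncol = dim(smp$input)[3]))
  pcc <- vapply(1:3, function(k) {
    y <- as.vector(smp$truth[, , k])
    fit <- stats::lm.fit(X, y)
    stats::cor(fit$fitted.values, y)
  }, numeric(1))
  expect_true(all(pcc > 0.8))
})

test_that("dataset generation: split protocol, manifests, round-trip I/O", {
  cfg <- scene_config(image_size = 32, n_cells = 1L, mito_count = 8L,
                      er_walks = 4L)
  dir1 <- file.path(tempdir(), "ds1"); dir2 <- file.path(tempdir(), "ds2")
  m1 <- make_dataset(cfg, 10L, split = 0.8, out_dir = dir1, seed = 3)
  m2 <- make_dataset(cfg, 10L, split = 0.8, out_dir = dir2, seed = 3)
  expect_identical(m1, m2)                       # same master seed
  expect_equal(sum(m1$split == "train"), 8L)
  expect_equal(sum(m1$split == "test"), 2L)
  expect_setequal(m1$id, 1:10)                   # partition property
  tr <- load_dataset(dir1, "train")
  te <- load_dataset(dir1, "test")
  expect_length(tr, 8); expect_length(te, 2)
  # 32-bit float TIFF round trip preserves the stack
  orig <- make_paired_sample(cfg, m1$seed[1])
  back <- read_stack(file.path(dir1, m1$input[1]), m1$input_scale[1])
  expect_equal(back, orig$input, tolerance = 1e-6)
  expect_error(make_dataset(cfg, 1L, out_dir = tempdir()), "at least 2")
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("in-memory dataset splits like the on-disk one", {
  cfg <- scene_config(image_size = 32, n_cells = 1L)
  ds <- make_dataset_memory(cfg, 5L, split = 0.8, seed = 12)
  expect_length(ds$train, 4)
  expect_length(ds$test, 1)
  ds2 <- make_dataset_memory(cfg, 5L, split = 0.8, seed = 12)
  expect_identical(ds, ds2)
})
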