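# Synthetic paired-data generator. Emulates the statistical structure of
# hyperspectral SRS stacks paired with organelle fluorescence: each of the
# three organelle channels (nucleus, mitochondria, endoplasmic reticulum)
# is a distinct spatial pattern, and the C input channels are noisy
# nonnegative linear mixtures of those patterns through a spectral
# signature matrix, so no input channel maps cleanly onto one organelle
# (the spectral-overlap regime the prediction task is hard because of).

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default spectral signature matrix (C channels x 3 organelles)
#'
#' Gaussian spectral profiles centred at different points of the channel
#' sweep with a common width wide enough that neighbouring organelle
#' signatures overlap substantially, plus a small nonspecific floor.
#'
#' @param n_channels number of input channels C.
#' @param centers profile centres on the channel axis (length 3).
#' @param width Gaussian width in channel units.
#' @param floor nonspecific contribution added to every entry.
#' @return nonnegative C x 3 matrix.
#' @export
default_mixing_matrix <- function(n_channels = 10L,
                                  centers = c(0.3, 0.55, 0.8) *
                                    n_channels,
                                  width = 0.25 * n_channels,
                                  floor = 0.05) {
  ch <- seq_len(n_channels)
  M <- vapply(centers, function(mu) exp(-(ch - mu)^2 / (2 * width^2)),
              numeric(n_channels))
  M + floor
}

#' Configuration of the synthetic scene generator
#'
#' @param image_size square image side (pixels); 128 by default, 512 for
#'   paper-scale stacks.
#' @param n_channels number of hyperspectral input channels C.
#' @param n_cells cells per image.
#' @param nucleus_axes nucleus ellipse semi-axes as a fraction of the image
#'   side (length 2: major, minor).
#' @param mito_count puncta per cell.
#' @param mito_radius punctum radius in pixels.
#' @param er_walks random-walk filaments per cell seeding the reticular
#'   network at the nuclear envelope.
#' @param er_steps steps per filament walk.
#' @param mixing_matrix nonnegative C x 3 spectral signature matrix.
#' @param background nonspecific baseline added to every input channel.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param poisson_gain photons per intensity unit for shot noise
#'   (0 disables the Poisson component).
#' @param blur_sigma optical blur (Gaussian, pixels) applied to the
#'   fluorescence channels after rendering.
#' @return list of class \code{scene_config}.
#' @export
scene_config <- function(image_size = 128L, n_channels = 10L, n_cells = 3L,
                         nucleus_axes = c(0.10, 0.075),
                         mito_count = 25L, mito_radius = 1.6,
                         er_walks = 8L, er_steps = 60L,
                         mixing_matrix = default_mixing_matrix(n_channels),
                         background = 0.1, noise_sd = 0.02,
                         poisson_gain = 50,
                         blur_sigma = 1.0) {
  stopifnot(image_size >= 32L, n_channels >= 3L,
            nrow(mixing_matrix) == n_channels, ncol(mixing_matrix) == 3L)
  if (any(mixing_matrix < 0))
    stop("mixing matrix must be nonnegative", call. = FALSE)
  if (any(colSums(mixing_matrix) == 0))
    stop("every organelle needs a nonzero spectral signature", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_channels = as.integer(n_channels),
                 n_cells = as.integer(n_cells),
                 nucleus_axes = nucleus_axes,
                 mito_count = as.integer(mito_count),
                 mito_radius = mito_radius,
                 er_walks = as.integer(er_walks),
                 er_steps = as.integer(er_steps),
                 mixing_matrix = mixing_matrix,
                 background = background, noise_sd = noise_sd,
                 poisson_gain = poisson_gain, blur_sigma = blur_sigma),
            class = "scene_config")
}

# Gaussian blur via separable banded matrices, edge-renormalized.
.gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  n <- nrow(img)
  mkM <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1L & j <= n
      M[i, j[ok]] <- k[ok]
      M[i, ] <- M[i, ] / sum(M[i, ])
    }
    M
  }
  Mr <- mkM(nrow(img))
  Mc <- if (ncol(img) == nrow(img)) Mr else mkM(ncol(img))
  Mr %*% img %*% t(Mc)
}

.fill_ellipse <- function(mask, cx, cy, a, b, theta) {
  H <- nrow(mask); W <- ncol(mask)
  xs <- matrix(seq_len(H), H, W) - cx
  ys <- matrix(seq_len(W), H, W, byrow = TRUE) - cy
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  mask | ((xr / a)^2 + (yr / b)^2 <= 1)
}

#' Render fluorescence ground truth and masks for one scene
#'
#' Nuclei are filled ellipses; mitochondria are puncta scattered in the
#' cytoplasm and excluded from nuclei; the endoplasmic reticulum is a
#' reticulated network drawn by persistent random walks seeded at the
#' nuclear envelope. Masks record the pre-blur supports; the intensity
#' channels are optically blurred and normalized to [0, 1].
#'
#' @param config a \code{\link{scene_config}}.
#' @param seed integer seed; identical (config, seed) pairs render
#'   bit-identical scenes.
#' @return list with \code{truth} (H, W, 3 array in [0, 1]) and
#'   \code{masks} (H, W, 3 integer array).
#' @export
render_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  .with_seed(seed, {
    H <- config$image_size
    nuc <- matrix(FALSE, H, H)
    mito <- matrix(FALSE, H, H)
    er <- matrix(FALSE, H, H)
    a <- config$nucleus_axes[1] * H
    b <- config$nucleus_axes[2] * H
    cell_r <- 2.4 * a
    centers <- matrix(numeric(0), 0, 2)
    placed <- 0L
    tries <- 0L
    while (placed < config$n_cells && tries < 60L * config$n_cells) {
      tries <- tries + 1L
      cx <- stats::runif(1, cell_r * 0.7, H - cell_r * 0.7)
      cy <- stats::runif(1, cell_r * 0.7, H - cell_r * 0.7)
      if (placed > 0L &&
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) <
            1.6 * cell_r) next
      centers <- rbind(centers, c(cx, cy))
      placed <- placed + 1L
      theta <- stats::runif(1, 0, pi)
      nuc <- .fill_ellipse(nuc, cx, cy, a, b, theta)
      # mitochondria: puncta in the cytoplasmic annulus
      for (i in seq_len(config$mito_count)) {
        r <- stats::runif(1, 1.15 * a, cell_r)
        ang <- stats::runif(1, 0, 2 * pi)
        px <- cx + r * cos(ang)
        py <- cy + r * sin(ang)
        if (px < 2 || py < 2 || px > H - 1 || py > H - 1) next
        mito <- .fill_ellipse(mito, px, py,
                              config$mito_radius * stats::runif(1, 0.8, 1.6),
                              config$mito_radius * stats::runif(1, 0.6, 1),
                              stats::runif(1, 0, pi))
      }
      # ER: persistent random walks from the nuclear envelope
      for (w in seq_len(config$er_walks)) {
        ang <- stats::runif(1, 0, 2 * pi)
        px <- cx + 1.1 * a * cos(ang)
        py <- cy + 1.1 * b * sin(ang)
        dir <- ang
        for (s in seq_len(config$er_steps)) {
          dir <- dir + stats::rnorm(1, 0, 0.45)
          px <- px + cos(dir)
          py <- py + sin(dir)
          d <- sqrt((px - cx)^2 + (py - cy)^2)
          if (d > cell_r) {          # reflect back toward the cell
            dir <- atan2(cy - py, cx - px) + stats::rnorm(1, 0, 0.3)
            next
          }
          ix <- round(px); iy <- round(py)
          if (ix >= 1 && iy >= 1 && ix <= H && iy <= H) er[ix, iy] <- TRUE
        }
      }
    }
    if (placed < config$n_cells)
      warning(sprintf("placed %d of %d cells without overlap", placed,
                      config$n_cells))
    mito <- mito & !nuc
    er <- er & !nuc
    masks <- array(0L, c(H, H, 3L))
    masks[, , 1] <- nuc * 1L
    masks[, , 2] <- mito * 1L
    masks[, , 3] <- er * 1L
    truth <- array(0, c(H, H, 3L))
    for (k in 1:3) {
      img <- masks[, , k] * stats::runif(1, 0.8, 1)
      img <- .gblur(img, config$blur_sigma)
      mx <- max(img)
      if (mx > 0) img <- img / mx
      truth[, , k] <- img
    }
    list(truth = truth, masks = masks)
  })
}

#' Mix fluorescence truth into a noisy hyperspectral input stack
#'
#' Channel c of the stack is the spectral-signature-weighted sum of the
#' organelle channels plus a nonspecific background, degraded by Poisson
#' shot noise and Gaussian read noise and clipped to nonnegative values.
#'
#' @param truth (H, W, 3) fluorescence array in [0, 1].
#' @param config a \code{\link{scene_config}}.
#' @param seed integer seed for the noise draw.
#' @return (H, W, C) input stack.
#' @export
mix_to_input <- function(truth, config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  M <- config$mixing_matrix
  if (any(M < 0)) stop("mixing matrix must be nonnegative", call. = FALSE)
  d <- dim(truth)
  H <- d[1]; W <- d[2]
  C <- nrow(M)
  .with_seed(seed, {
    flat <- matrix(truth, H * W, 3L)
    clean <- flat %*% t(M) + config$background
    noisy <- clean
    if (config$poisson_gain > 0) {
      noisy <- matrix(stats::rpois(length(clean),
                                   config$poisson_gain * clean),
                      nrow(clean)) / config$poisson_gain
    }
    if (config$noise_sd > 0)
      noisy <- noisy + stats::rnorm(length(noisy), 0, config$noise_sd)
    noisy[noisy < 0] <- 0
    array(noisy, c(H, W, C))
  })
}

#' Generate one paired sample (input stack, truth, masks)
#' @param config a \code{\link{scene_config}}.
#' @param seed integer seed.
#' @return list with \code{input}, \code{truth}, \code{masks}, \code{seed}.
#' @export
make_paired_sample <- function(config, seed = 1L) {
  sc <- render_scene(config, seed)
  input <- mix_to_input(sc$truth, config, seed + 1L)
  list(input = input, truth = sc$truth, masks = sc$masks, seed = seed)
}

#' Write a multi-channel stack as a multi-page 32-bit TIFF
#'
#' Values are divided by the stack maximum before writing (TIFF pages hold
#' [0, 1]); the scale is returned so it can be recorded in a manifest.
#'
#' @param arr (H, W, C) array.
#' @param path output path.
#' @return the scale factor used.
#' @export
write_stack <- function(arr, path) {
  s <- max(arr)
  if (s <= 0) s <- 1
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / s)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  s
}

#' Read a multi-page TIFF as an (H, W, C) array
#' @param path TIFF path.
#' @param scale multiply pages by this factor (from the manifest).
#' @return (H, W, C) array.
#' @export
read_stack <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0, c(H, W, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr * scale
}

#' Generate a dataset on disk with a reproducible train/test split
#'
#' Renders \code{n_images} paired samples, writes input stacks as C-page
#' TIFFs, truths as 3-page TIFFs and masks as PNGs, shuffles with the
#' master seed and splits train/test, and writes a CSV manifest recording
#' file names, per-image seeds, intensity scales and split membership.
#'
#' @param config a \code{\link{scene_config}}.
#' @param n_images number of paired images (>= 2).
#' @param split training fraction (default 0.8).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; the whole dataset is a pure function of
#'   (config, seed).
#' @return the manifest data.frame (also written to manifest.csv).
#' @export
make_dataset <- function(config, n_images, split = 0.8, out_dir,
                         seed = 1L) {
  if (n_images < 2L) stop("need at least 2 images to split", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  orgs <- organelle_names()
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- make_paired_sample(config, seed + 10L * i)
    fin <- sprintf("input_%04d.tif", i)
    ftr <- sprintf("truth_%04d.tif", i)
    sc_in <- write_stack(s$input, file.path(out_dir, fin))
    sc_tr <- write_stack(s$truth, file.path(out_dir, ftr))
    for (k in 1:3) {
      png::writePNG(s$masks[, , k] * 1.0,
                    file.path(out_dir, sprintf("mask_%04d_%s.png", i,
                                               orgs[k])))
    }
    rows[[i]] <- data.frame(id = i, input = fin, truth = ftr,
                            input_scale = sc_in, truth_scale = sc_tr,
                            seed = s$seed)
  }
  manifest <- do.call(rbind, rows)
  n_train <- round(split * n_images)
  perm <- .with_seed(seed, sample.int(n_images))
  manifest$split <- "test"
  manifest$split[manifest$id %in% perm[seq_len(n_train)]] <- "train"
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Load a dataset written by \code{\link{make_dataset}} into memory
#' @param dir dataset directory containing manifest.csv.
#' @param split "train", "test" or "all".
#' @return list of samples, each with \code{input} and \code{truth}.
#' @export
load_dataset <- function(dir, split = c("all", "train", "test")) {
  split <- match.arg(split)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  if (split != "all") manifest <- manifest[manifest$split == split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    list(input = read_stack(file.path(dir, manifest$input[i]),
                            manifest$input_scale[i]),
         truth = read_stack(file.path(dir, manifest$truth[i]),
                            manifest$truth_scale[i]))
  })
}

#' Generate an in-memory dataset (no disk I/O)
#' @inheritParams make_dataset
#' @return list with \code{train} and \code{test} lists of paired samples.
#' @export
make_dataset_memory <- function(config, n_images, split = 0.8, seed = 1L) {
  if (n_images < 2L) stop("need at least 2 images to split", call. = FALSE)
  samples <- lapply(seq_len(n_images), function(i)
    make_paired_sample(config, seed + 10L * i))
  n_train <- round(split * n_images)
  perm <- .with_seed(seed, sample.int(n_images))
  list(train = samples[perm[seq_len(n_train)]],
       test = samples[perm[-seq_len(n_train)]])
}
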