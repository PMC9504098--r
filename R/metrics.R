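# Image-quality and segmentation metrics for label-free prediction:
# per-class accuracy / overall accuracy, per-class IoU / mIoU, Pearson
# correlation, MSE / RMSE / NRMSE, PSNR, SSIM, Dice, plus the binarization
# policy that turns continuous predictions into masks and the
# relative-change statistic used for model-to-model comparison tables.

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("images must have identical dimensions", call. = FALSE)
}

#' Per-class and overall pixel accuracy
#'
#' For label maps with classes \code{0..k}, the accuracy of class i is the
#' fraction of truth pixels of class i that are predicted as class i; the
#' overall accuracy (OA) is the fraction of all pixels predicted correctly.
#' Classes absent from the truth get \code{NA} accuracy and are excluded
#' from any averaging.
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param num_classes number of classes k + 1 (class values 0..k); default
#'   inferred from the data.
#' @return list with \code{per_class} (named numeric, possibly NA) and
#'   \code{overall}.
#' @export
class_accuracy <- function(pred, truth, num_classes = NULL) {
  .check_same_shape(pred, truth)
  if (is.null(num_classes)) num_classes <- max(pred, truth) + 1L
  lv <- 0:(num_classes - 1L)
  per <- vapply(lv, function(cl) {
    n_cl <- sum(truth == cl)
    if (n_cl == 0L) return(NA_real_)
    sum(pred == cl & truth == cl) / n_cl
  }, numeric(1))
  names(per) <- as.character(lv)
  list(per_class = per, overall = mean(pred == truth))
}

#' Per-class intersection-over-union and mean IoU
#'
#' IoU of class i is TP / (TP + FP + FN) on the pixel sets. A class absent
#' from both prediction and truth has undefined IoU and is excluded from
#' the mean (it carries no evidence either way).
#'
#' @inheritParams class_accuracy
#' @return list with \code{per_class} IoU (possibly NA) and \code{miou}.
#' @export
mean_iou <- function(pred, truth, num_classes = NULL) {
  .check_same_shape(pred, truth)
  if (is.null(num_classes)) num_classes <- max(pred, truth) + 1L
  lv <- 0:(num_classes - 1L)
  per <- vapply(lv, function(cl) {
    p <- pred == cl
    t <- truth == cl
    u <- sum(p | t)
    if (u == 0L) return(NA_real_)
    sum(p & t) / u
  }, numeric(1))
  names(per) <- as.character(lv)
  list(per_class = per, miou = mean(per, na.rm = TRUE))
}

#' Pearson correlation between two intensity images
#'
#' Computed over flattened pixels; invariant to affine rescaling of either
#' image. Errors if either image has zero variance.
#'
#' @param pred,truth numeric matrices/arrays of identical shape.
#' @return scalar in [-1, 1].
#' @export
pearson_cc <- function(pred, truth) {
  .check_same_shape(pred, truth)
  p <- as.vector(pred); t <- as.vector(truth)
  if (length(p) < 2L) stop("need at least 2 pixels", call. = FALSE)
  if (stats::sd(p) == 0 || stats::sd(t) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(p, t)
}

#' Mean squared error, RMSE and range-normalized RMSE
#'
#' NRMSE divides the RMSE by the dynamic range (max - min) of the reference
#' image, making the error comparable across intensity scales; a constant
#' reference has no range and raises an error.
#'
#' @param pred predicted intensity image.
#' @param truth reference intensity image.
#' @return list with \code{mse}, \code{rmse}, \code{nrmse}.
#' @export
nrmse <- function(pred, truth) {
  .check_same_shape(pred, truth)
  mse <- mean((pred - truth)^2)
  rng <- max(truth) - min(truth)
  if (rng == 0) stop("constant reference image: NRMSE undefined", call. = FALSE)
  list(mse = mse, rmse = sqrt(mse), nrmse = sqrt(mse) / rng)
}

#' Peak signal-to-noise ratio in decibels
#'
#' \code{10 * log10(v_max^2 / MSE)}; \code{Inf} for identical images.
#'
#' @inheritParams nrmse
#' @param v_max peak intensity of the reference scale (e.g. 255 for 8-bit).
#' @return scalar in dB (possibly \code{Inf}).
#' @export
psnr <- function(pred, truth, v_max = max(truth)) {
  .check_same_shape(pred, truth)
  stopifnot(v_max > 0)
  mse <- mean((pred - truth)^2)
  if (mse == 0) return(Inf)
  10 * log10(v_max^2 / mse)
}

#' SSIM parameters
#'
#' @param window odd side length of the local window (default 11).
#' @param L declared dynamic range of the images.
#' @param K1,K2 stabilization fractions; C1 = (K1 L)^2, C2 = (K2 L)^2,
#'   C3 = C2 / 2.
#' @param m,n,p exponents of the luminance, contrast and structure terms.
#' @param sigma Gaussian weighting bandwidth for the local window.
#' @return list of class \code{ssim_params}.
#' @export
ssim_params <- function(window = 11L, L = 1, K1 = 0.01, K2 = 0.03,
                        m = 1, n = 1, p = 1, sigma = 1.5) {
  stopifnot(window %% 2L == 1L, window >= 3L, L > 0)
  structure(list(window = as.integer(window), L = L,
                 C1 = (K1 * L)^2, C2 = (K2 * L)^2, C3 = (K2 * L)^2 / 2,
                 m = m, n = n, p = p, sigma = sigma),
            class = "ssim_params")
}

# Separable weighted local filtering: valid-mode windows, Gaussian weights.
.ssim_filter_mats <- function(H, W, window, sigma) {
  half <- (window - 1L) %/% 2L
  w1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  mk <- function(n) {
    nf <- n - window + 1L
    M <- matrix(0, nf, n)
    for (i in seq_len(nf)) M[i, i:(i + window - 1L)] <- w1
    M
  }
  list(R = mk(H), C = mk(W))
}

#' Structural similarity index
#'
#' Mean over local Gaussian-weighted windows of the luminance, contrast and
#' structure comparison terms raised to their exponents. With the default
#' exponents (1, 1, 1) and C3 = C2/2 this reduces to the familiar two-term
#' SSIM formula.
#'
#' @param pred,truth intensity images of identical shape, at least
#'   \code{window} pixels on each side.
#' @param params a \code{\link{ssim_params}} object.
#' @return scalar SSIM in [-1, 1].
#' @export
ssim <- function(pred, truth, params = ssim_params(L = max(truth) - min(truth))) {
  .check_same_shape(pred, truth)
  H <- nrow(pred); W <- ncol(pred)
  win <- params$window
  if (H < win || W < win)
    stop("image smaller than SSIM window", call. = FALSE)
  fm <- .ssim_filter_mats(H, W, win, params$sigma)
  loc <- function(img) fm$R %*% img %*% t(fm$C)
  mx <- loc(pred); my <- loc(truth)
  sxx <- loc(pred * pred) - mx * mx
  syy <- loc(truth * truth) - my * my
  sxy <- loc(pred * truth) - mx * my
  sxx <- pmax(sxx, 0); syy <- pmax(syy, 0)
  sx <- sqrt(sxx); sy <- sqrt(syy)
  l <- (2 * mx * my + params$C1) / (mx^2 + my^2 + params$C1)
  cc <- (2 * sx * sy + params$C2) / (sxx + syy + params$C2)
  s <- (sxy + params$C3) / (sx * sy + params$C3)
  mean(sign(l) * abs(l)^params$m *
       sign(cc) * abs(cc)^params$n *
       sign(s) * abs(s)^params$p)
}

#' Dice similarity coefficient of two binary masks
#'
#' \code{2 |T intersect P| / (|T| + |P|)}. Two empty masks agree vacuously
#' and score 1.
#'
#' @param pred,truth binary (0/1 or logical) masks of identical shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(pred, truth) {
  .check_same_shape(pred, truth)
  p <- as.logical(pred); t <- as.logical(truth)
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Otsu threshold by between-class variance maximization
#'
#' @param x numeric vector/matrix of intensities in [0, 1].
#' @param n_bins histogram resolution.
#' @return threshold in [0, 1].
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(x)
  h <- tabulate(pmin(pmax(floor(v * n_bins), 0L), n_bins - 1L) + 1L, n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / n_bins
}

#' Binarize a continuous prediction into a foreground mask
#'
#' The image is min-max normalized to [0, 1] and thresholded; the threshold
#' is either fixed (default 0.5) or chosen by Otsu's method.
#'
#' @param x numeric intensity image.
#' @param policy "fixed" or "otsu".
#' @param threshold fixed threshold on the normalized image.
#' @return integer matrix of 0 (background) / 1 (foreground).
#' @export
binarize <- function(x, policy = c("fixed", "otsu"), threshold = 0.5) {
  policy <- match.arg(policy)
  rng <- max(x) - min(x)
  if (rng == 0) {
    warning("constant image: all-background mask")
    return(array(0L, dim = dim(x)))
  }
  xn <- (x - min(x)) / rng
  thr <- if (policy == "otsu") otsu_threshold(xn) else threshold
  out <- array(0L, dim = dim(x))
  out[xn >= thr] <- 1L
  out
}

#' Relative change between two metric values, in percent
#'
#' For higher-is-better metrics this is the improvement of \code{a} over
#' the reference \code{b}: \code{100 (a - b) / b}. For lower-is-better
#' metrics (error measures) it is the reduction: \code{100 (b - a) / b}.
#' Positive values mean \code{a} outperforms \code{b}.
#'
#' @param a value of the model under study.
#' @param b value of the reference model (nonzero).
#' @param direction "higher_is_better" or "lower_is_better".
#' @param digits rounding for reporting (2 decimals by convention).
#' @return percent change, rounded.
#' @export
relative_change <- function(a, b,
                            direction = c("higher_is_better",
                                          "lower_is_better"),
                            digits = 2L) {
  direction <- match.arg(direction)
  if (b == 0) stop("reference value is zero", call. = FALSE)
  pct <- if (direction == "higher_is_better") 100 * (a - b) / b
         else 100 * (b - a) / b
  round(pct, digits)
}

#' Organelle channel names used throughout the package
#' @export
organelle_names <- function() c("nucleus", "mitochondria", "er")

# all five quality metrics for one (pred, truth) channel pair
.channel_metrics <- function(pred, truth, ssim_p = NULL) {
  if (is.null(ssim_p)) {
    L <- max(truth) - min(truth)
    ssim_p <- ssim_params(L = if (L > 0) L else 1)
  }
  pm <- binarize(pred)
  tm <- binarize(truth)
  c(nrmse = nrmse(pred, truth)$nrmse,
    ssim = ssim(pred, truth, ssim_p),
    pcc = pearson_cc(pred, truth),
    dice = dice(pm, tm),
    miou = mean_iou(pm, tm, num_classes = 2L)$miou)
}

#' Build a per-organelle metric report over a test set
#'
#' Computes NRMSE, SSIM, PCC, Dice and mIoU per organelle channel per image,
#' then the mean and standard deviation over images — the row structure of
#' a model-comparison table. Continuous metrics operate on the raw channels;
#' Dice and mIoU are computed after \code{\link{binarize}} with threshold
#' 0.5 on min-max-normalized channels.
#'
#' @param preds list of predicted (H, W, 3) arrays, or one array.
#' @param truths matching list of ground-truth arrays.
#' @param model label recorded in the report.
#' @param organelles channel names.
#' @return data.frame of class \code{metric_report} with columns model,
#'   organelle, nrmse, ssim, pcc, dice, miou, their sds, and n_images.
#' @export
build_report <- function(preds, truths, model = "model",
                         organelles = organelle_names()) {
  if (is.array(preds) && length(dim(preds)) == 3L) preds <- list(preds)
  if (is.array(truths) && length(dim(truths)) == 3L) truths <- list(truths)
  if (length(preds) == 0L) stop("empty test set", call. = FALSE)
  stopifnot(length(preds) == length(truths))
  K <- dim(preds[[1]])[3]
  stopifnot(K == length(organelles))
  rows <- list()
  for (k in seq_len(K)) {
    vals <- t(vapply(seq_along(preds), function(i) {
      .channel_metrics(preds[[i]][, , k], truths[[i]][, , k])
    }, numeric(5)))
    mn <- colMeans(vals)
    sdv <- apply(vals, 2L, stats::sd)
    sdv[is.na(sdv)] <- 0
    rows[[k]] <- data.frame(model = model, organelle = organelles[k],
                            nrmse = mn["nrmse"], ssim = mn["ssim"],
                            pcc = mn["pcc"], dice = mn["dice"],
                            miou = mn["miou"],
                            nrmse_sd = sdv["nrmse"], ssim_sd = sdv["ssim"],
                            pcc_sd = sdv["pcc"], dice_sd = sdv["dice"],
                            miou_sd = sdv["miou"],
                            n_images = length(preds),
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Write a metric report as CSV
#' @param report a \code{metric_report}.
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
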