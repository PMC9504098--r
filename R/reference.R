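# Published benchmark values used as inputs to the comparison tables.

#' Reported quality-metric means for the three benchmark predictors
#'
#' Per-organelle mean NRMSE, SSIM, PCC, Dice and mIoU reported for the
#' fusion network ("mpfnet"), the spectral U-net variant ("uwunet") and
#' the plain U-net ("unet") on a request-only SRS lung-cancer-cell
#' dataset. These printed means are the inputs to
#' \code{\link{compare_reports}} when reproducing the published
#' relative-change statements; the underlying images are not distributed,
#' so the absolute values cannot be recomputed here.
#'
#' @return data.frame in \code{metric_report} layout (means only).
#' @export
reference_metric_tables <- function() {
  rows <- rbind(
    c("mpfnet", "nucleus",      0.192, 0.913, 0.908, 0.935, 0.879),
    c("mpfnet", "er",           0.187, 0.886, 0.911, 0.936, 0.881),
    c("mpfnet", "mitochondria", 0.206, 0.915, 0.903, 0.933, 0.876),
    c("uwunet", "nucleus",      0.201, 0.892, 0.892, 0.919, 0.852),
    c("uwunet", "er",           0.225, 0.857, 0.903, 0.925, 0.861),
    c("uwunet", "mitochondria", 0.217, 0.886, 0.880, 0.921, 0.854),
    c("unet",   "nucleus",      0.442, 0.757, 0.843, 0.855, 0.716),
    c("unet",   "er",           0.454, 0.761, 0.856, 0.873, 0.771),
    c("unet",   "mitochondria", 0.511, 0.760, 0.835, 0.843, 0.731))
  out <- data.frame(model = rows[, 1], organelle = rows[, 2],
                    nrmse = as.numeric(rows[, 3]),
                    ssim = as.numeric(rows[, 4]),
                    pcc = as.numeric(rows[, 5]),
                    dice = as.numeric(rows[, 6]),
                    miou = as.numeric(rows[, 7]),
                    stringsAsFactors = FALSE)
  class(out) <- c("metric_report", "data.frame")
  out
}
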