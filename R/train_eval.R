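# Training loop (SGD with momentum, the published hyperparameter set as
# defaults), evaluation over a held-out test set, and the model-to-model
# comparison table of relative changes.

#' Training configuration
#'
#' Defaults are the published settings: momentum 0.9, batch size 8, weight
#' decay 1e-4, initial learning rate 0.001, at most 200 epochs.
#'
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay on matrix-shaped weights.
#' @param batch_size images per gradient step.
#' @param epochs maximum number of epochs.
#' @param loss "mse" or "l1".
#' @param optimizer "sgd" (momentum SGD, the published setting) or "adam"
#'   (adaptive option for small-sample experiments).
#' @param seed seed for shuffling and dropout.
#' @param clip_norm global gradient-norm ceiling per step (guards against
#'   the single oversized update that can kill a ReLU network early in
#'   training); \code{Inf} disables clipping.
#' @param target_pcc optional convergence early-exit: stop once the mean
#'   training Pearson correlation reaches this value.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(lr = 0.001, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 8L, epochs = 200L,
                         loss = c("mse", "l1"),
                         optimizer = c("sgd", "adam"), seed = 1L,
                         clip_norm = 1, target_pcc = NULL) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  stopifnot(lr >= 0, momentum >= 0, weight_decay >= 0, batch_size >= 1L,
            epochs >= 1L, clip_norm > 0)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 optimizer = optimizer,
                 seed = as.integer(seed), clip_norm = clip_norm,
                 target_pcc = target_pcc),
            class = "train_config")
}

#' Mean pixel accuracy of a continuous multi-channel prediction
#'
#' Pixels are assigned the arg-max class over [background, organelle
#' channels], where the background score is 1 minus the strongest channel;
#' a channel wins only if it exceeds the threshold. The accuracy is the
#' fraction of pixels assigned the same class in prediction and truth.
#'
#' @param pred,truth (H, W, K) arrays in [0, 1].
#' @param threshold minimum channel intensity to count as foreground.
#' @return scalar accuracy in [0, 1].
#' @export
mean_pixel_accuracy <- function(pred, truth, threshold = 0.5) {
  cls <- function(a) {
    d <- dim(a)
    m <- matrix(a, d[1] * d[2], d[3])
    top <- max.col(m, ties.method = "first")
    mx <- m[cbind(seq_len(nrow(m)), top)]
    ifelse(mx >= threshold, top, 0L)
  }
  mean(cls(pred) == cls(truth))
}

# mean over samples of the all-channel flattened Pearson correlation
.dataset_pcc <- function(preds, truths) {
  mean(vapply(seq_along(preds), function(i) {
    p <- as.vector(preds[[i]]); t <- as.vector(truths[[i]])
    if (stats::sd(p) == 0 || stats::sd(t) == 0) return(0)
    stats::cor(p, t)
  }, numeric(1)))
}

#' Train a model
#'
#' Mini-batch SGD with momentum; per-sample forward/backward passes with
#' gradients accumulated over the batch. Per-epoch training loss, mean
#' pixel accuracy and mean Pearson correlation are logged (computed from
#' the training-mode predictions made during the epoch). Aborts on a
#' non-finite loss. If validation samples are given, the state with the
#' lowest validation loss is restored into the model at the end.
#'
#' @param model a built model (modified in place).
#' @param samples list of training samples (\code{input}, \code{truth}).
#' @param cfg a \code{\link{train_config}}.
#' @param val_samples optional validation samples.
#' @param verbose print one line per epoch.
#' @return list with the \code{model} and the per-epoch \code{log}
#'   data.frame.
#' @export
train <- function(model, samples, cfg = train_config(), val_samples = NULL,
                  verbose = FALSE) {
  if (length(samples) == 0L) stop("empty training set", call. = FALSE)
  if (cfg$batch_size > length(samples))
    stop("batch size exceeds training set size", call. = FALSE)
  ps <- nn_params(model)
  opt <- if (identical(cfg$optimizer, "adam"))
    adam_optimizer(ps, cfg$lr, weight_decay = cfg$weight_decay)
  else sgd_optimizer(ps, cfg$lr, cfg$momentum, cfg$weight_decay)
  loss_fn <- if (cfg$loss == "l1") ad_mae else ad_mse
  best_val <- Inf
  best_state <- NULL
  log <- vector("list", cfg$epochs)
  .with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(samples))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      preds <- vector("list", length(samples))
      for (batch in batches) {
        ad_zero_grad(ps)
        loss <- NULL
        for (i in batch) {
          pred <- model$fwd(samples[[i]]$input, training = TRUE)
          preds[[i]] <- ad_value(pred)
          li <- loss_fn(pred, samples[[i]]$truth)
          loss <- if (is.null(loss)) li else ad_add(loss, li)
        }
        loss <- ad_smul(loss, 1 / length(batch))
        if (!is.finite(ad_value(loss)))
          stop("non-finite loss at epoch ", ep,
               "; lower the learning rate", call. = FALSE)
        ad_backward(loss)
        if (is.finite(cfg$clip_norm)) {
          gn <- sqrt(sum(vapply(ps, function(p)
            if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
          if (gn > cfg$clip_norm) {
            sc <- cfg$clip_norm / gn
            for (p in ps) if (!is.null(p$grad)) p$grad <- p$grad * sc
          }
        }
        opt$step()
        ep_loss <- ep_loss + ad_value(loss) * length(batch)
      }
      truths <- lapply(samples, `[[`, "truth")
      acc <- mean(vapply(seq_along(samples), function(i)
        mean_pixel_accuracy(preds[[i]], truths[[i]]), numeric(1)))
      pcc <- .dataset_pcc(preds, truths)
      vl <- NA_real_
      if (!is.null(val_samples)) {
        vl <- mean(vapply(val_samples, function(s) {
          p <- ad_no_grad(ad_value(model$fwd(s$input)))
          mean((p - s$truth)^2)
        }, numeric(1)))
        if (vl < best_val) {
          best_val <- vl
          best_state <- nn_state_dict(model)
        }
      }
      log[[ep]] <- data.frame(epoch = ep,
                              loss = ep_loss / length(samples),
                              pixel_acc = acc, pcc = pcc, val_loss = vl)
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  acc %.3f  pcc %.3f",
                        ep, ep_loss / length(samples), acc, pcc))
      if (!is.null(cfg$target_pcc) && pcc >= cfg$target_pcc) break
    }
  })
  if (!is.null(best_state)) nn_load_state(model, best_state)
  list(model = model, log = do.call(rbind, log[!vapply(log, is.null,
                                                       logical(1))]))
}

#' Predict fluorescence channels for one input stack
#' @param model a built model.
#' @param input (H, W, C) array.
#' @return (H, W, K) array in [0, 1].
#' @export
predict_fluorescence <- function(model, input) {
  ad_no_grad(ad_value(model$fwd(input)))
}

#' Evaluate a model over a test set
#'
#' Runs the model on every test input and builds the per-organelle metric
#' report (NRMSE, SSIM, PCC, Dice, mIoU; means and standard deviations).
#'
#' @param model a built model.
#' @param samples list of test samples (\code{input}, \code{truth}).
#' @param model_name label recorded in the report.
#' @return a \code{metric_report} data.frame.
#' @export
evaluate_model <- function(model, samples, model_name = "model") {
  if (length(samples) == 0L) stop("empty test set", call. = FALSE)
  preds <- lapply(samples, function(s) predict_fluorescence(model, s$input))
  truths <- lapply(samples, `[[`, "truth")
  build_report(preds, truths, model = model_name)
}

.metric_directions <- c(nrmse = "lower_is_better", ssim = "higher_is_better",
                        pcc = "higher_is_better", dice = "higher_is_better",
                        miou = "higher_is_better")

#' Pairwise relative-change comparison of metric reports
#'
#' For every ordered pair of models, organelle, and metric, computes the
#' percent change of the first model relative to the second with the
#' metric's own direction (error metrics: reduction; quality metrics:
#' improvement). Positive values mean the first model is better.
#'
#' @param reports list of \code{metric_report} data.frames (or one rbind).
#' @return data.frame with columns model, reference, organelle, metric,
#'   change_pct.
#' @export
compare_reports <- function(reports) {
  tab <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  models <- unique(tab$model)
  if (length(models) < 2L)
    stop("need at least two models to compare", call. = FALSE)
  rows <- list()
  for (a in models) for (b in setdiff(models, a)) {
    for (org in unique(tab$organelle)) {
      ra <- tab[tab$model == a & tab$organelle == org, ]
      rb <- tab[tab$model == b & tab$organelle == org, ]
      if (nrow(ra) != 1L || nrow(rb) != 1L) {
        warning("missing report cell for ", org, "; partial table")
        next
      }
      for (metric in names(.metric_directions)) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = a, reference = b, organelle = org, metric = metric,
          change_pct = relative_change(ra[[metric]], rb[[metric]],
                                       .metric_directions[[metric]]))
      }
    }
  }
  do.call(rbind, rows)
}
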