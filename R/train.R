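# ---------------------------------------------------------------------------
# Training recipe: Adam with a stepped learning-rate schedule and Dice loss.
# Two presets ship: "paper" reproduces the published recipe (300 epochs,
# initial LR 0.3 stepped to 1e-4 after 30 and 1e-6 after 270, batch 8,
# weight decay 1e-6); "desk" is the CPU-scale profile (30 epochs, constant
# LR 1e-3) used throughout the tests and examples.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param profile `"desk"` (default) or `"paper"`; presets for epochs and the
#'   stepped learning-rate schedule. Any explicit argument overrides the
#'   preset.
#' @param epochs number of passes over the training set; the schedule's
#'   breakpoints are epoch counts ("iterations" are read as epochs; set
#'   `unit = "step"` to step the schedule per mini-batch instead).
#' @param batch_size mini-batch size.
#' @param lr_breaks,lr_values stepped schedule: `lr_values[1]` until
#'   `lr_breaks[1]` epochs are done, then `lr_values[2]`, and so on;
#'   `length(lr_values) == length(lr_breaks) + 1`.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param unit `"epoch"` or `"step"` interpretation of the breakpoints.
#' @param seed integer seed controlling batch shuffling (weights are seeded
#'   at network construction).
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("desk", "paper"), epochs = NULL,
                         batch_size = 8L, lr_breaks = NULL, lr_values = NULL,
                         weight_decay = 1e-6, unit = c("epoch", "step"),
                         seed = 1L) {
  profile <- match.arg(profile)
  unit <- match.arg(unit)
  if (is.null(epochs)) epochs <- if (profile == "paper") 300L else 30L
  if (is.null(lr_breaks))
    lr_breaks <- if (profile == "paper") c(30L, 270L) else integer(0)
  if (is.null(lr_values))
    lr_values <- if (profile == "paper") c(0.3, 1e-4, 1e-6) else 1e-3
  if (length(lr_values) != length(lr_breaks) + 1L)
    stop("need one more lr value than breakpoints")
  if (length(lr_breaks) && (any(diff(lr_breaks) <= 0) ||
                            any(lr_breaks >= epochs)))
    stop("schedule breakpoints must be strictly increasing and below epochs")
  structure(list(profile = profile, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_breaks = as.integer(lr_breaks), lr_values = lr_values,
                 weight_decay = weight_decay, unit = unit,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch (or step) index.
#' @return the scheduled learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr_values[findInterval(epoch, cfg$lr_breaks) + 1L]
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

#' Train a segmentation network
#'
#' Seeded Dice-loss training with Adam and the stepped learning-rate
#' schedule. Tracks per-epoch train/validation loss and validation Dice; the
#' weights with the best validation Dice are restored into the network when
#' training ends (and optionally checkpointed).
#'
#' @param net a `praseg_net` (modified in place by reference and returned).
#' @param train_samples,val_samples lists of Samples with equal spatial size.
#' @param cfg a [train_config()].
#' @param checkpoint optional path where the best network is saved.
#' @param verbose print one line per epoch.
#' @return list with `net` and `record` — a data frame with one row per
#'   completed epoch (`epoch`, `lr`, `train_loss`, `val_loss`, `val_dice`).
#' @export
train_model <- function(net, train_samples, val_samples, cfg = train_config(),
                        checkpoint = NULL, verbose = FALSE) {
  params <- collect_params(net)
  ids <- vapply(params, function(p) p$id, integer(1))
  params <- params[!duplicated(ids)]
  st <- adam_init(params)
  tb <- samples_to_batch(train_samples)
  vb <- samples_to_batch(val_samples)
  n <- length(train_samples)
  rec <- NULL
  best <- list(dice = -Inf, state = NULL)
  set.seed(cfg$seed)
  step <- 0L
  for (epoch in seq_len(cfg$epochs) - 1L) {
    perm <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
      lr <- lr_at_epoch(cfg, if (cfg$unit == "epoch") epoch else step)
      xn <- pr_node(tb$x[, , , idx, drop = FALSE])
      yv <- tb$y[, , , idx, drop = FALSE]
      loss <- dice_loss(net_forward(net, xn)$prob, yv)
      if (!is.finite(loss$value))
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (learning rate ", lr, "); lower the learning rate")
      zero_grads(params)
      backward_pass(loss)
      st <- adam_step(params, st, lr, cfg$weight_decay)
      losses <- c(losses, loss$value)
      step <- step + 1L
    }
    vr <- validate_pass(net, vb)
    rec <- rbind(rec, data.frame(
      epoch = epoch, lr = lr_at_epoch(cfg, if (cfg$unit == "epoch") epoch else step),
      train_loss = mean(losses), val_loss = vr$loss, val_dice = vr$dice))
    if (vr$dice > best$dice)
      best <- list(dice = vr$dice, state = state_dict(net))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  train %.4f  val %.4f  dice %.4f",
                      epoch, rec$lr[nrow(rec)], mean(losses), vr$loss, vr$dice))
  }
  if (!is.null(best$state)) load_state_dict(net, best$state)
  if (!is.null(checkpoint)) save_checkpoint(net, checkpoint)
  list(net = net, record = rec)
}

validate_pass <- function(net, vb) {
  prob <- net_forward(net, vb$x)$prob
  loss <- dice_loss(prob, vb$y)
  n <- dim(prob)[4]
  dices <- vapply(seq_len(n), function(i) {
    m <- metric_suite(confusion_counts(prob[, , , i], vb$y[, , , i]))
    m$dc
  }, numeric(1))
  list(loss = loss, dice = mean(dices))
}

#' Evaluate a network on a dataset
#'
#' Per-image metrics at threshold 0.5, aggregated as mean +/- population
#' standard deviation (percent). Optionally also pooled PR/ROC curves.
#'
#' @param net a `praseg_net` or a checkpoint path.
#' @param samples list of Samples.
#' @param threshold binarization threshold.
#' @param curves also compute [pr_roc()] over pooled pixels.
#' @return a `metrics_report`; with `curves = TRUE`, attribute `"curves"`
#'   holds the PR/ROC output.
#' @export
evaluate_model <- function(net, samples, threshold = 0.5, curves = FALSE) {
  if (is.character(net)) net <- load_checkpoint(net)
  b <- samples_to_batch(samples)
  prob <- net_forward(net, b$x)$prob
  reports <- lapply(seq_along(samples), function(i)
    metric_suite(confusion_counts(prob[, , , i], b$y[, , , i], threshold)))
  rep <- aggregate_metrics(reports)
  if (curves) attr(rep, "curves") <- pr_roc(prob, b$y)
  rep
}

#' Render prediction overlays
#'
#' Tints the predicted lesion region pink over the input image, draws the
#' prediction contour, and writes both the overlay and the binary predicted
#' mask as PNG files. Pixels outside the predicted region are untouched.
#'
#' @param net a `praseg_net` or checkpoint path.
#' @param samples list of Samples (or image file paths).
#' @param out_dir output directory.
#' @param threshold binarization threshold.
#' @param alpha tint strength inside the predicted region.
#' @return data frame listing the written `overlay` and `mask` files.
#' @export
predict_overlay <- function(net, samples, out_dir, threshold = 0.5,
                            alpha = 0.45) {
  if (is.character(net)) net <- load_checkpoint(net)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pink <- c(1.0, 0.45, 0.75)
  rows <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (is.character(s)) {
      img <- tryCatch(ebi_to_hwc(EBImage::readImage(s)), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable input: ", s)
        next
      }
      s <- new_sample(pmin(pmax(img, 0), 1),
                      matrix(0, dim(img)[1], dim(img)[2]), source = s)
    }
    x <- array(s$image, dim = c(dim(s$image), 1L))
    pred <- (net_forward(net, x)$prob[, , 1, 1] >= threshold) * 1
    over <- s$image
    if (any(pred > 0)) {
      edge <- pred - erode_mask(pred)
      for (ch in 1:3) {
        plane <- over[, , ch]
        plane[pred == 1] <- (1 - alpha) * plane[pred == 1] + alpha * pink[ch]
        plane[edge == 1] <- pink[ch]
        over[, , ch] <- plane
      }
    }
    stem <- sprintf("pred_%04d", i)
    overlay_path <- file.path(out_dir, paste0(stem, "_overlay.png"))
    mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
    EBImage::writeImage(hwc_to_ebi(over), overlay_path)
    EBImage::writeImage(hwc_to_ebi(pred), mask_path)
    rows <- rbind(rows, data.frame(overlay = overlay_path, mask = mask_path))
  }
  rows
}

# 4-neighbour erosion; edge = mask minus its erosion.
erode_mask <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], 0)
  dn <- rbind(0, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], 0)
  rt <- cbind(0, m[, -W, drop = FALSE])
  (m * up * dn * lf * rt > 0) * 1
}

#' Loss-curve plot
#'
#' @param record the `record` data frame of [train_model()].
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
plot_loss_curves <- function(record, path) {
  grDevices::png(path, width = 700, height = 450)
  on.exit(grDevices::dev.off())
  graphics::plot(record$epoch, record$train_loss, type = "l", col = "steelblue",
                 ylim = range(c(record$train_loss, record$val_loss)),
                 xlab = "epoch", ylab = "Dice loss", main = "training curves")
  graphics::lines(record$epoch, record$val_loss, col = "firebrick")
  graphics::legend("topright", legend = c("train", "valid"),
                   col = c("steelblue", "firebrick"), lty = 1)
  invisible(path)
}
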