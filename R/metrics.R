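# ---------------------------------------------------------------------------
# Dice loss and the pixel-wise evaluation suite.
#
# Evaluation binarizes probability maps at 0.5. Degenerate denominators are
# defined as: a metric whose denominator is empty returns 1 when prediction
# and ground truth are both empty (perfect agreement on "nothing there"),
# else 0. The soft Dice loss carries epsilon = 1e-6 in numerator and
# denominator, so two empty masks give loss 0.
# ---------------------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - (2 * sum(P*G) + eps) / (sum(P) + sum(G) + eps)` with `eps = 1e-6`.
#' Accepts plain arrays (returns a number) or a graph node for `P` during
#' training (returns a scalar loss node; multi-sample batches average the
#' per-sample losses).
#'
#' @param P probability map, values in `[0, 1]`.
#' @param G binary ground-truth mask of the same shape.
#' @param eps stabilizer added to numerator and denominator.
#' @return scalar in `[0, 1]` (or a loss node).
#' @export
dice_loss <- function(P, G, eps = 1e-6) {
  if (is_node(P)) {
    gv <- if (is_node(G)) G$value else G
    if (!identical(dim(P$value), dim_or_len(gv)) &&
        length(P$value) != length(gv))
      stop("prediction and mask shapes differ")
    return(op_dice_loss(P, gv, eps))
  }
  if (length(P) != length(G)) stop("prediction and mask shapes differ")
  if (any(P < -1e-12 | P > 1 + 1e-12)) stop("P must lie in [0, 1]")
  num <- 2 * sum(P * G) + eps
  den <- sum(P) + sum(G) + eps
  1 - num / den
}

#' Pixel confusion counts
#'
#' @param pred predicted mask; probabilities are binarized at `threshold`.
#' @param gt binary ground-truth mask of the same shape.
#' @param threshold binarization threshold for `pred`.
#' @return a `confusion_counts` list with integer fields `tp, fp, tn, fn`.
#' @export
confusion_counts <- function(pred, gt, threshold = 0.5) {
  if (length(pred) != length(gt)) stop("prediction and mask shapes differ")
  p <- as.numeric(pred) >= threshold
  g <- as.numeric(gt) > 0.5
  structure(list(
    tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g)
  ), class = "confusion_counts")
}

safe_ratio <- function(num, den, both_empty) {
  if (den == 0) return(if (both_empty) 1 else 0)
  num / den
}

#' Segmentation metric suite from confusion counts
#'
#' Dice coefficient `2TP/(2TP+FP+FN)`, intersection-over-union
#' `TP/(TP+FP+FN)`, accuracy, specificity `TN/(TN+FP)` and sensitivity
#' `TP/(TP+FN)`. Empty-denominator cases return 1 when both masks are empty
#' (or both full, for specificity), else 0.
#'
#' @param c a [confusion_counts()].
#' @return named list `dc, iou, acc, sp, se`, each in `[0, 1]`.
#' @export
metric_suite <- function(c) {
  with(c, {
    total <- tp + fp + tn + fn
    both_empty <- (tp + fn == 0) && (tp + fp == 0)
    list(
      dc = safe_ratio(2 * tp, 2 * tp + fp + fn, both_empty),
      iou = safe_ratio(tp, tp + fp + fn, both_empty),
      acc = safe_ratio(tp + tn, total, TRUE),
      sp = safe_ratio(tn, tn + fp, (fn + tn == 0) && (fp + tn == 0)),
      se = safe_ratio(tp, tp + fn, both_empty)
    )
  })
}

#' Aggregate per-image metrics into a report
#'
#' Mean and population standard deviation of each metric across images,
#' reported as percentages (the `mean+/-std` style of segmentation
#' benchmarks).
#'
#' @param reports non-empty list of per-image metric lists (as returned by
#'   [metric_suite()]).
#' @return a `metrics_report` with `per_image` (data frame of fractions) and
#'   `aggregate` (data frame with `metric`, `mean`, `sd`, both in percent).
#' @export
aggregate_metrics <- function(reports) {
  if (length(reports) == 0) stop("cannot aggregate an empty report list")
  per <- do.call(rbind, lapply(reports, function(r) as.data.frame(r)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  agg <- data.frame(
    metric = names(per),
    mean = round(100 * vapply(per, mean, numeric(1)), 2),
    sd = round(100 * vapply(per, pop_sd, numeric(1)), 2),
    row.names = NULL)
  structure(list(per_image = per, aggregate = agg), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_image), "image(s):\n")
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-4s %6.2f +/- %.2f %%\n", toupper(x$aggregate$metric[i]),
                x$aggregate$mean[i], x$aggregate$sd[i]))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report a `metrics_report`.
#' @param csv,json optional output paths; `NULL` skips that format.
#' @return the report, invisibly.
#' @export
write_metrics_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$aggregate, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(per_image = report$per_image,
                              aggregate = report$aggregate),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Precision-recall and ROC curves by threshold sweep
#'
#' Pools all pixels, sweeps every distinct predicted probability as a
#' threshold (prediction positive when `prob >= t`), and reports
#' precision/recall and TPR/FPR arrays with trapezoidal areas.
#'
#' @param prob_maps numeric vector/array (or list of arrays) of predicted
#'   probabilities in `[0, 1]`.
#' @param gt_masks matching binary ground truth.
#' @return list with data frames `pr` (`recall`, `precision`), `roc` (`fpr`,
#'   `tpr`) and areas `auc_pr`, `auc_roc`, all in `[0, 1]`.
#' @export
pr_roc <- function(prob_maps, gt_masks) {
  p <- as.numeric(unlist(prob_maps))
  g <- as.numeric(unlist(gt_masks)) > 0.5
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop("probabilities must lie in [0, 1]")
  np <- sum(g); nn <- sum(!g)
  if (np == 0 || nn == 0)
    stop("ROC is undefined when the ground truth contains a single class")
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; gs <- g[ord]
  tp <- cumsum(gs); fp <- cumsum(!gs)
  keep <- c(ps[-1] != ps[-length(ps)], TRUE)   # last index of each threshold
  tp <- tp[keep]; fp <- fp[keep]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  prec <- c(1, tp / (tp + fp)); rec <- c(0, tp / np)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(pr = data.frame(recall = rec, precision = prec),
       roc = data.frame(fpr = fpr, tpr = tpr),
       auc_pr = trapz(rec, prec),
       auc_roc = trapz(fpr, tpr))
}

#' Serialize PR/ROC curves to CSV
#'
#' @param curves output of [pr_roc()].
#' @param pr_csv,roc_csv output paths; `NULL` skips that file.
#' @return the curves, invisibly.
#' @export
write_curves <- function(curves, pr_csv = NULL, roc_csv = NULL) {
  if (!is.null(pr_csv)) utils::write.csv(curves$pr, pr_csv, row.names = FALSE)
  if (!is.null(roc_csv)) utils::write.csv(curves$roc, roc_csv, row.names = FALSE)
  invisible(curves)
}

#' Plot PR and ROC curves to PNG
#'
#' @param curves output of [pr_roc()].
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
plot_pr_roc <- function(curves, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  graphics::plot(curves$roc$fpr, curves$roc$tpr, type = "l", col = "steelblue",
                 xlab = "FPR", ylab = "TPR",
                 main = sprintf("ROC (area %.3f)", curves$auc_roc))
  graphics::abline(0, 1, lty = 3)
  graphics::plot(curves$pr$recall, curves$pr$precision, type = "l",
                 col = "firebrick", xlab = "Recall", ylab = "Precision",
                 main = sprintf("PR (area %.3f)", curves$auc_pr))
  invisible(path)
}
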