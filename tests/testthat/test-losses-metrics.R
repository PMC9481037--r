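# Dice loss and the metric suite against hand-counted fixtures and an
# exhaustive threshold-enumeration oracle for the curves.

test_that("Dice loss reproduces the counted toy masks", {
  m <- matrix(0, 4, 4)
  g <- m; g[1:2, 1:2] <- 1                       # |G| = 4
  expect_lt(dice_loss(g, g), 1e-6)               # identical masks -> 0
  p_disj <- m; p_disj[3:4, 3:4] <- 1
  expect_gt(dice_loss(p_disj, g), 1 - 1e-6)      # disjoint masks -> 1
  p <- m; p[1:2, 1] <- 1; p[1, 2] <- 1           # 3 overlapping pixels
  p[3, 3:4] <- 1; p[4, 4] <- 1                   # |P| = 6
  expect_equal(dice_loss(p, g), 1 - 6 / 10, tolerance = 1e-6)
  expect_equal(dice_loss(m, m), 0)               # both empty -> 0 by epsilon
  expect_error(dice_loss(matrix(0, 2, 2), g), "shapes differ")
})

test_that("confusion counts match the hand-counted 4x4 fixture", {
  g <- matrix(0, 4, 4); g[1, 1:3] <- 1           # 3 positives
  expect_equal(unclass(confusion_counts(g, g))[c("fp", "fn")],
               list(fp = 0L, fn = 0L), ignore_attr = TRUE)
  inv <- confusion_counts(1 - g, g)
  expect_equal(inv$tp, 0L)
  expect_equal(inv$tn, 0L)
  # explicit fixture with tp=2, fp=1, fn=1, tn=12
  gt <- matrix(0, 4, 4); gt[1, 1:3] <- 1
  pr <- matrix(0, 4, 4); pr[1, 1:2] <- 1; pr[2, 1] <- 1
  cc <- confusion_counts(pr, gt)
  expect_equal(unclass(cc), list(tp = 2L, fp = 1L, tn = 12L, fn = 1L),
               ignore_attr = TRUE)
  m <- metric_suite(cc)
  expect_equal(m$dc, 4 / 6, tolerance = 1e-12)
  expect_equal(m$iou, 0.5)
  expect_equal(m$acc, 14 / 16)
  expect_equal(m$sp, 12 / 13)
  expect_equal(m$se, 2 / 3)
})

test_that("identical masks score 1 everywhere and DC = 2*IoU/(1+IoU) holds over random counts", {
  g <- matrix(0, 6, 6); g[2:4, 2:5] <- 1
  m <- metric_suite(confusion_counts(g, g))
  expect_equal(unlist(m), c(dc = 1, iou = 1, acc = 1, sp = 1, se = 1))
  set.seed(31)
  for (i in 1:200) {
    cc <- structure(as.list(stats::rpois(4, lambda = sample(0:40, 4))),
                    names = c("tp", "fp", "tn", "fn"),
                    class = "confusion_counts")
    m <- metric_suite(cc)
    expect_equal(m$dc, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("Dice loss equals 1 - DC on binary predictions and has finite gradients", {
  set.seed(32)
  for (i in 1:20) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    g <- matrix(rbinom(64, 1, 0.4), 8, 8)
    dc <- metric_suite(confusion_counts(p, g))$dc
    expect_equal(dice_loss(p, g), 1 - dc, tolerance = 1e-4)
    # flip invariance
    expect_equal(dice_loss(p[, 8:1], g[, 8:1]), dice_loss(p, g))
    mm <- metric_suite(confusion_counts(p[, 8:1], g[, 8:1]))
    expect_equal(mm$dc, dc)
  }
  ps <- array(runif(32), c(4, 4, 2, 1))
  gs <- array(rbinom(32, 1, 0.5), c(4, 4, 2, 1))
  node <- P$pr_param(ps)
  loss <- dice_loss(node, gs)
  P$backward_pass(loss)
  expect_true(all(is.finite(node$grad)))
})

test_that("aggregation reports mean and population sd in percent and is permutation-invariant", {
  one <- aggregate_metrics(list(list(dc = 0.8, iou = 0.7, acc = 0.9,
                                     sp = 0.95, se = 0.85)))
  expect_true(all(one$aggregate$sd == 0))
  two <- aggregate_metrics(list(list(dc = 0.8), list(dc = 1.0)))
  expect_equal(two$aggregate$mean[two$aggregate$metric == "dc"], 90.00)
  expect_equal(two$aggregate$sd[two$aggregate$metric == "dc"], 10.00)
  r <- list(list(dc = 0.2), list(dc = 0.5), list(dc = 0.9))
  expect_equal(aggregate_metrics(r)$aggregate,
               aggregate_metrics(rev(r))$aggregate)
  expect_error(aggregate_metrics(list()), "empty")
})

test_that("PR/ROC curves match an exhaustive threshold enumeration and pROC", {
  g <- c(1, 1, 0, 1, 0, 0, 1, 0)
  p <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.35, 0.3, 0.1)
  got <- pr_roc(p, g)
  # brute force: enumerate every threshold, trapezoid by hand
  ths <- sort(unique(p), decreasing = TRUE)
  tpr <- fpr <- numeric(0)
  for (t in ths) {
    pred <- p >= t
    tpr <- c(tpr, sum(pred & g == 1) / sum(g == 1))
    fpr <- c(fpr, sum(pred & g == 0) / sum(g == 0))
  }
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc_bf <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(got$auc_roc, auc_bf, tolerance = 1e-12)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(g, p, quiet = TRUE)))
  expect_equal(got$auc_roc, auc_ref, tolerance = 1e-9)
})

test_that("degenerate predictors hit the documented curve areas and single-class truth errors", {
  g <- matrix(c(1, 0, 1, 0, 0, 1, 0, 0), 2)
  expect_equal(pr_roc(g, g)$auc_roc, 1.0)
  expect_equal(pr_roc(matrix(0.5, 2, 4), g)$auc_roc, 0.5)
  expect_error(pr_roc(runif(4), rep(1, 4)), "single class")
})
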