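# The PRA sub-components against independent oracles: brute-force
# convolution, scalar hand-evaluation of the attention equations, and
# hand-computed group statistics.

test_that("pyramid preserves spatial size and concatenates 4 branches in kernel order", {
  set.seed(1)
  pyr <- P$new_pyramid(8L, 32L)
  x <- rand_fmap(16, 20, 8, 1)
  y <- pyramid_conv(pyr, x)
  expect_equal(dim(y), c(16L, 20L, 128L, 1L))
  # all-zero kernels and biases give an all-zero output (linearity)
  for (cv in pyr$convs) {
    cv$w$value <- cv$w$value * 0
    cv$b$value <- cv$b$value * 0
  }
  expect_true(all(pyramid_conv(pyr, x) == 0))
  # channel mismatch is a configuration error
  expect_error(pyramid_conv(pyr, rand_fmap(4, 4, 3, 1)), "channels")
})

test_that("pyramid matches a nested-loop convolution oracle on small inputs", {
  set.seed(2)
  pyr <- P$new_pyramid(1L, 2L)
  x <- array(rnorm(25), c(5, 5, 1, 1))
  y <- pyramid_conv(pyr, x)
  for (i in seq_along(pyr$convs)) {
    cv <- pyr$convs[[i]]
    ref <- naive_conv2d(x, cv$w$value, cv$b$value, cv$pad)
    expect_lt(max(abs(y[, , (i - 1) * 2 + 1:2, , drop = FALSE] - ref)), 1e-5)
  }
  # sweep all input sizes up to 7x7 and 2 channels
  for (C in 1:2) for (H in c(1, 3, 7)) for (W in c(2, 5, 7)) {
    pyr2 <- P$new_pyramid(C, 1L)
    xs <- rand_fmap(H, W, C, 1, seed = 10 * H + W + C)
    ys <- pyramid_conv(pyr2, xs)
    for (i in seq_along(pyr2$convs)) {
      cv <- pyr2$convs[[i]]
      ref <- naive_conv2d(xs, cv$w$value, cv$b$value, cv$pad)
      expect_lt(max(abs(ys[, , i, , drop = FALSE] - ref)), 1e-5)
    }
  }
})

test_that("channel attention reproduces a scalar hand evaluation on a 2-channel fixture", {
  att <- P$new_channel_attention(2L, reduction = 2L)
  # hand-chosen 2 -> 1 -> 2 weights
  att$k1$w$value <- matrix(c(0.5, -0.25), 1, 2)
  att$k1$b$value <- 0.1
  att$k2$w$value <- matrix(c(1.5, -0.5), 2, 1)
  att$k2$b$value <- c(-0.2, 0.3)
  x <- array(c(1, 2, 3, 4, -1, 0, 1, 2), c(2, 2, 2, 1))
  r <- channel_attention(att, x)
  # scalar-by-scalar: pooled descriptor = avg + max per channel
  p1 <- mean(x[, , 1, 1]) + max(x[, , 1, 1])   # 2.5 + 4
  p2 <- mean(x[, , 2, 1]) + max(x[, , 2, 1])   # 0.5 + 2
  h <- 0.5 * p1 - 0.25 * p2 + 0.1
  y1 <- 1 / (1 + exp(-(1.5 * h - 0.2)))
  y2 <- 1 / (1 + exp(-(-0.5 * h + 0.3)))
  expect_lt(max(abs(r$weights - c(y1, y2))), 1e-6)
  out_hand <- x
  out_hand[, , 1, 1] <- y1 * x[, , 1, 1] + x[, , 1, 1]
  out_hand[, , 2, 1] <- y2 * x[, , 2, 1] + x[, , 2, 1]
  expect_lt(max(abs(r$out - out_hand)), 1e-6)
})

test_that("attention gates lie strictly in (0,1), zero maps to zero, and the identity term matters", {
  set.seed(3)
  att <- P$new_channel_attention(4L)
  x0 <- array(0, c(3, 3, 4, 2))
  r0 <- channel_attention(att, x0)
  expect_true(all(r0$out == 0))
  x <- rand_fmap(3, 3, 4, 2, seed = 4)
  r <- channel_attention(att, x)
  expect_true(all(r$weights > 0 & r$weights < 1))
  # removing the "+x" term changes the output unless Y is identically 1
  gated <- r$out - x
  expect_gt(max(abs(r$out - gated)), 1e-8)
  expect_error(channel_attention(att, array(NaN, c(2, 2, 4, 1))), "finite")
})

test_that("residual unit: shape contract, degenerate-input safety, hand-computed group stats", {
  set.seed(5)
  ru <- P$new_residual_unit(3L, 64L)
  x <- rand_fmap(32, 32, 3, 1)
  expect_equal(dim(residual_unit(ru, x)), c(32L, 32L, 64L, 1L))
  # all-zero convolution weights: GN sees an all-zero map, output stays finite
  ru$conv1$w$value <- ru$conv1$w$value * 0
  ru$conv2$w$value <- ru$conv2$w$value * 0
  expect_true(all(is.finite(residual_unit(ru, x))))
  # single-group GN on a (2,2,2) tensor matches hand-computed statistics
  gn <- P$layer_groupnorm(2L, groups = 1L)
  v <- array(c(1, 2, 3, 4, 5, 6, 7, 10), c(2, 2, 2, 1))
  got <- P$fwd_groupnorm(gn, P$pr_node(v))$value
  hand <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  expect_lt(max(abs(got - hand)), 1e-5)
  expect_lt(abs(mean(got)), 1e-6)
  expect_lt(abs(mean(got^2) - 1), 1e-4)
  expect_error(P$new_residual_unit(3L, 10L, gn_groups = 4L), "divide")
})

test_that("PRA block preserves spatial size, rejects odd inputs, and reduces to branch (a) + shortcut when branch (b) is zeroed", {
  set.seed(6)
  cfg <- pra_config(3, 8, 16, 24)
  blk <- new_pra_block(cfg)
  x <- rand_fmap(16, 20, 3, 1)
  expect_equal(dim(pra_forward(blk, x))[1:2], c(16L, 20L))
  for (H in seq(2, 64, by = 14)) {
    xs <- rand_fmap(H, H + 2, 3, 1, seed = H)
    expect_equal(dim(pra_forward(blk, xs))[1:2], c(H, H + 2L),
                 label = paste("spatial preservation at H =", H))
  }
  expect_error(pra_forward(blk, rand_fmap(5, 6, 3, 1)), "divisible")
  # oracle by construction: zero branch (b)'s final projection
  blk$proj_b$w$value <- blk$proj_b$w$value * 0
  blk$proj_b$b$value <- blk$proj_b$b$value * 0
  a <- residual_unit(blk$branch_a, x)
  a <- P$fwd_conv2d(blk$proj_a, P$pr_node(a))$value
  sc <- P$fwd_conv2d(blk$shortcut, P$pr_node(x))$value
  expect_equal(pra_forward(blk, x), a + sc, tolerance = 1e-12)
})

test_that("ablation variants replace exactly one sub-component", {
  set.seed(7)
  cfg <- pra_config(3, 32, 48, 64)
  full <- new_pra_block(cfg)
  ca <- make_ablation_variant("CA", cfg)
  pm <- make_ablation_variant("PM", cfg)
  res <- make_ablation_variant("Res", cfg)
  x <- rand_fmap(8, 8, 3, 1)
  # CA: no sigmoid gating remains, output shape unchanged
  expect_s3_class(ca$attention, "pr_conv2d")
  expect_equal(dim(pra_forward(ca, x)), dim(pra_forward(full, x)))
  # PM: single-kernel path with a different parameter count
  expect_s3_class(pm$pyramid, "pr_conv2d")
  expect_false(count_trainable_parameters(pm) == count_trainable_parameters(full))
  # Res: no identity shortcut around the block body
  expect_null(res$shortcut)
  expect_s3_class(res$branch_a, "pr_conv2d")
  expect_error(make_ablation_variant("XX", cfg), "unknown")
})

test_that("parameter counting is exact and purely structural", {
  conv <- P$layer_conv2d(1L, 1L, 3L)
  expect_equal(count_trainable_parameters(conv), 10)   # 9 weights + 1 bias
  lin <- P$layer_linear(4L, 2L)
  expect_equal(count_trainable_parameters(lin), 10)    # 8 + 2
  set.seed(8)
  net <- build_pra_segmenter(width_scale = 4L, seed = 2)
  n0 <- count_trainable_parameters(net)
  invisible(net_forward(net, rand_fmap(8, 8, 3, 1)))
  expect_identical(count_trainable_parameters(net), n0)
  ps <- P$collect_params(net)
  ps[[1]]$value <- ps[[1]]$value * 3 + 1
  expect_identical(count_trainable_parameters(net), n0)
})

test_that("block configurations round-trip through YAML", {
  cfgs <- default_pra_configs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_block_configs(cfgs, path)
  back <- read_block_configs(path)
  expect_equal(names(back),
               c("left_shallow", "right_shallow", "left_middle",
                 "right_middle", "deep"))
  for (nm in names(back))
    expect_equal(unclass(back[[nm]]), unclass(cfgs[[nm]]))
})
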