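# Assembly contracts of the three-level network, the standalone levels and
# the PRA-bottleneck U-Net.

test_that("building twice with the same seed gives identical networks", {
  a <- build_pran(pran_spec(8L), seed = 7)
  b <- build_pran(pran_spec(8L), seed = 7)
  expect_identical(count_trainable_parameters(a), count_trainable_parameters(b))
  expect_identical(network_summary(a), network_summary(b))
  sa <- P$state_dict(a)
  sb <- P$state_dict(b)
  expect_identical(sa, sb)
})

test_that("forward pass emits a full-resolution probability map with the documented level traces", {
  net <- build_pran(pran_spec(8L), seed = 7)
  x <- rand_fmap(256, 320, 3, 1, seed = 1)
  r <- net_forward(net, x)
  expect_equal(dim(r$prob), c(256L, 320L, 1L, 1L))
  expect_true(all(r$prob >= 0 & r$prob <= 1))
  expect_equal(r$trace$shallow, c(256L, 320L))
  expect_equal(r$trace$middle, c(64L, 80L))
  expect_equal(r$trace$deep, c(16L, 20L))
  expect_error(net_forward(net, rand_fmap(60, 64, 3, 1)), "divisible by 16")
})

test_that("level traces scale as 1/4 and 1/16 per dimension across input sizes", {
  net <- build_pran(pran_spec(8L), seed = 2)
  for (H in c(64L, 128L, 256L)) {
    r <- net_forward(net, rand_fmap(H, 64, 3, 1, seed = H))
    expect_identical(r$trace$middle[1] * 4L, H)
    expect_identical(r$trace$deep[1] * 16L, H)
  }
  # input-size equivariance: doubling H doubles every traced H
  r1 <- net_forward(net, rand_fmap(64, 64, 3, 1))
  r2 <- net_forward(net, rand_fmap(128, 64, 3, 1))
  expect_identical(vapply(r2$trace, `[`, integer(1), 1),
                   2L * vapply(r1$trace, `[`, integer(1), 1))
})

test_that("PRAU segments 384x384 inputs and strictly extends the plain U-Net", {
  unet <- build_unet(base = 2L, seed = 3)
  prau <- build_prau(base = 2L, seed = 3)
  x <- rand_fmap(384, 384, 3, 1, seed = 9)
  r <- net_forward(prau, x)
  expect_equal(dim(r$prob), c(384L, 384L, 1L, 1L))
  expect_true(all(r$prob >= 0 & r$prob <= 1))
  # factory inverse: the plain U-Net has a two-convolution bottleneck
  expect_s3_class(unet$bott, "praseg_double_conv")
  expect_s3_class(prau$bott, "pra_block")
  expect_gt(count_trainable_parameters(prau), count_trainable_parameters(unet))
})

test_that("one optimization step on a single sample strictly decreases the loss", {
  net <- build_pra_segmenter(width_scale = 8L, seed = 4)
  s <- tiny_dataset(1, size = 32L, seed = 21L)[[1]]
  b <- P$samples_to_batch(list(s))
  params <- P$collect_params(net)
  loss0 <- dice_loss(net_forward(net, P$pr_node(b$x))$prob, b$y)
  P$zero_grads(params)
  P$backward_pass(loss0)
  st <- P$adam_init(params)
  P$adam_step(params, st, lr = 1e-3)
  loss1 <- dice_loss(net_forward(net, P$pr_node(b$x))$prob, b$y)
  expect_lt(loss1$value, loss0$value)
})

test_that("checkpoints round-trip exactly", {
  net <- build_pra_segmenter(width_scale = 8L, seed = 5)
  x <- rand_fmap(16, 16, 3, 2, seed = 2)
  before <- net_forward(net, x)$prob
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(net_forward(net2, x)$prob, before)
})

test_that("network specs round-trip through YAML", {
  spec <- pran_spec(8L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pran_spec(spec, path)
  back <- read_pran_spec(path)
  expect_equal(unclass(back), unclass(spec))
  net <- build_pran(back, seed = 1)
  expect_s3_class(net, "praseg_net")
})
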