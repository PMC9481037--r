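# Loading, resizing, augmentation and splitting. All file fixtures are
# written to a temp dir at test time.

write_pair_fixture <- function(dir, mask_values = c(0, 1)) {
  set.seed(77)
  s <- generate_sample(lesion_params(canvas = c(48L, 48L), seed = 5), 0)
  img_path <- file.path(dir, "img.png")      # png: lossless round trip
  msk_path <- file.path(dir, "img_segmentation.png")
  EBImage::writeImage(P$hwc_to_ebi(s$image), img_path)
  EBImage::writeImage(P$hwc_to_ebi(s$mask), msk_path)
  list(image = img_path, mask = msk_path, sample = s)
}

test_that("image/mask pairs round-trip through disk with a bit-equal binarized mask", {
  dir <- withr::local_tempdir()
  fx <- write_pair_fixture(dir)
  s <- load_pair(fx$image, fx$mask)
  expect_identical(s$mask, fx$sample$mask)
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_equal(dim(s$image), dim(fx$sample$image))
  expect_error(load_pair(file.path(dir, "nope.jpg"), fx$mask), "not found")
})

test_that("grayscale {0,255} masks binarize and RGB mask files are rejected", {
  dir <- withr::local_tempdir()
  m <- matrix(0L, 16, 16); m[4:9, 5:12] <- 1L
  EBImage::writeImage(P$hwc_to_ebi(m), file.path(dir, "m.png"))  # stored 0/255
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  EBImage::writeImage(P$hwc_to_ebi(img), file.path(dir, "i.png"))
  s <- load_pair(file.path(dir, "i.png"), file.path(dir, "m.png"))
  expect_identical(sort(unique(as.numeric(s$mask))), c(0, 1))
  expect_identical(s$mask, m * 1)
  # an RGB mask is a format error
  EBImage::writeImage(P$hwc_to_ebi(img), file.path(dir, "rgb_mask.png"))
  expect_error(load_pair(file.path(dir, "i.png"),
                         file.path(dir, "rgb_mask.png")), "single-channel")
  # size mismatch between image and mask
  EBImage::writeImage(P$hwc_to_ebi(array(runif(8 * 8 * 3), c(8, 8, 3))),
                      file.path(dir, "small.png"))
  expect_error(load_pair(file.path(dir, "small.png"), file.path(dir, "m.png")),
               "sizes differ")
})

test_that("resizing follows the width x height reading and keeps masks binary", {
  set.seed(78)
  img <- array(runif(540 * 720 * 3), c(540, 720, 3))   # 720x540 photograph
  msk <- matrix(0, 540, 720); msk[100:300, 200:500] <- 1
  s <- P$new_sample(img, msk)
  r <- resize_normalize(s, c(256L, 320L))              # "320x256" target
  expect_equal(dim(r$image), c(256L, 320L, 3L))
  expect_equal(dim(r$mask), c(256L, 320L))
  expect_true(all(r$mask %in% c(0, 1)))
  expect_true(all(r$image >= 0 & r$image <= 1))
  same <- resize_normalize(s, c(540L, 720L))
  expect_lt(max(abs(same$image - s$image)), 1e-7)
  expect_error(resize_normalize(s, c(0L, 10L)), "target")
})

test_that("augmentation is draw-deterministic, involutive under forced flips, and area-stable under rotation", {
  msk <- disk_mask(64)
  s <- flat_sample(msk)
  cfg <- augment_config(seed = 4)
  a1 <- augment_sample(s, cfg, draw = 9L)
  a2 <- augment_sample(s, cfg, draw = 9L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_equal(dim(a1$image), dim(s$image))
  # hflip with probability 1 (no other transform) is an involution
  cfl <- augment_config(hflip_prob = 1, vflip_prob = 0, rotation_range = 0,
                        crop_scale_range = c(1, 1), seed = 4)
  twice <- augment_sample(augment_sample(s, cfl, 1L), cfl, 1L)
  expect_identical(twice$mask, s$mask)
  expect_equal(twice$image, s$image, tolerance = 1e-12)
  # rotation-only: lesion pixel count within 10% of the original
  crot <- augment_config(hflip_prob = 0, vflip_prob = 0, rotation_range = 90,
                         crop_scale_range = c(1, 1), seed = 6)
  for (d in 1:5) {
    ar <- augment_sample(s, crot, d)
    expect_lt(abs(sum(ar$mask) - sum(msk)) / sum(msk), 0.1,
              label = paste("rotation area drift, draw", d))
  }
})

test_that("random_split is a seed-deterministic partition at the published cardinalities", {
  samples <- as.list(seq_len(1816 + 256 + 518))
  sp <- random_split(samples, c(1816, 256, 518), seed = 12)
  expect_length(sp$train, 1816)
  expect_length(sp$val, 256)
  expect_length(sp$test, 518)
  all_ids <- c(unlist(sp$train), unlist(sp$val), unlist(sp$test))
  expect_setequal(all_ids, seq_len(2590))
  expect_identical(anyDuplicated(all_ids), 0L)
  sp2 <- random_split(samples, c(1816, 256, 518), seed = 12)
  expect_identical(sp, sp2)
  expect_error(random_split(samples, c(1000, 256, 518), seed = 1), "sum")
})

test_that("pipeline outputs always satisfy the Sample invariants", {
  set.seed(80)
  cfg <- augment_config(seed = 3)
  for (i in 1:4) {
    s <- generate_sample(lesion_params(canvas = c(48L, 48L), seed = 7), i)
    a <- augment_sample(resize_normalize(s, c(32L, 32L)), cfg, i)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(all(a$image >= 0 & a$image <= 1))
    expect_equal(dim(a$image)[1:2], dim(a$mask))
    expect_equal(dim(a$image)[3], 3L)
  }
})
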