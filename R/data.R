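# ---------------------------------------------------------------------------
# Image/mask loading, resizing, augmentation and dataset splitting.
#
# A Sample is a list(image, mask, source): image is an (H, W, 3) array in
# [0, 1], mask an (H, W) matrix strictly in {0, 1}. EBImage stores images as
# (x = width, y = height [, channel]), so every EBImage call goes through the
# transpose helpers below; "320x256" in width x height convention therefore
# means tensors 256 high and 320 wide.
# ---------------------------------------------------------------------------

hwc_to_ebi <- function(a) {
  if (length(dim(a)) == 2L) EBImage::Image(t(a))
  else EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
}

ebi_to_hwc <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

new_sample <- function(image, mask, source = NA_character_) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            all(dim(mask) == dim(image)[1:2]))
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly binary")
  list(image = image, mask = mask, source = source)
}

#' Load an image/mask pair
#'
#' Reads a JPEG/PNG lesion photograph and its grayscale mask (ISIC layout),
#' scales intensities to `[0, 1]` and binarizes the mask at mid-intensity.
#'
#' @param image_path path to the RGB image.
#' @param mask_path path to the single-channel mask.
#' @return a Sample: `list(image, mask, source)`.
#' @export
load_pair <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- EBImage::readImage(image_path)
  msk <- EBImage::readImage(mask_path)
  di <- dim(img)
  if (length(di) == 2L) img <- EBImage::Image(
    array(rep(EBImage::imageData(img), 3L), dim = c(di, 3L)), colormode = "Color")
  if (length(dim(img)) == 3L && dim(img)[3] == 4L)
    img <- img[, , 1:3]  # drop alpha
  if (length(dim(msk)) == 3L && dim(msk)[3] > 1L)
    stop("mask must be a single-channel grayscale file, got a multi-channel ",
         "image: ", mask_path)
  if (!all(dim(img)[1:2] == dim(msk)[1:2]))
    stop("image (", paste(dim(img)[1:2], collapse = "x"), ") and mask (",
         paste(dim(msk)[1:2], collapse = "x"), ") sizes differ")
  mask <- (ebi_to_hwc(msk) > 0.5) * 1
  new_sample(pmin(pmax(ebi_to_hwc(img), 0), 1), mask, source = image_path)
}

#' Resize and normalize a Sample
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbor so it stays binary. `target` is in `(H, W)` convention.
#'
#' @param s a Sample.
#' @param target integer `(H, W)` of the output.
#' @return the resized Sample.
#' @export
resize_normalize <- function(s, target) {
  if (length(target) != 2L || any(target < 1)) stop("target must be (H, W) >= 1")
  H <- as.integer(target[1]); W <- as.integer(target[2])
  if (all(dim(s$mask) == c(H, W))) return(s)
  img <- EBImage::resize(hwc_to_ebi(s$image), w = W, h = H, filter = "bilinear")
  msk <- EBImage::resize(hwc_to_ebi(s$mask), w = W, h = H, filter = "none")
  new_sample(pmin(pmax(ebi_to_hwc(img), 0), 1),
             (ebi_to_hwc(msk) > 0.5) * 1, s$source)
}

#' Augmentation configuration
#'
#' @param hflip_prob,vflip_prob flip probabilities in `[0, 1]`.
#' @param rotation_range degrees; rotations are drawn uniformly in
#'   `[-rotation_range, rotation_range]`, bounded by 90.
#' @param crop_scale_range fraction interval of the random-crop window.
#' @param seed integer; together with the draw index it fully determines
#'   every augmentation.
#' @return an `augment_config` list.
#' @export
augment_config <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                           rotation_range = 90, crop_scale_range = c(0.8, 1),
                           seed = 1L) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, vflip_prob >= 0, vflip_prob <= 1,
            rotation_range >= 0, rotation_range <= 90,
            length(crop_scale_range) == 2L, crop_scale_range[1] > 0,
            crop_scale_range[2] <= 1)
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 rotation_range = rotation_range,
                 crop_scale_range = crop_scale_range, seed = as.integer(seed)),
            class = "augment_config")
}

# Run code under a private, reproducible RNG stream without disturbing the
# caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483629)
}

reflect_pad <- function(a, p) {
  ri <- c(pmin(p:1 + 1L, nrow(a)), 1:nrow(a), nrow(a) - pmin(1:p, nrow(a) - 1L))
  ci <- c(pmin(p:1 + 1L, ncol(a)), 1:ncol(a), ncol(a) - pmin(1:p, ncol(a) - 1L))
  if (length(dim(a)) == 2L) a[ri, ci, drop = FALSE] else a[ri, ci, , drop = FALSE]
}

rotate_hwc <- function(a, angle, nearest = FALSE, pad_reflect = TRUE) {
  H <- dim(a)[1]; W <- dim(a)[2]
  p <- ceiling(0.3 * max(H, W)) # corners pulled in by up to (sqrt(2)-1)/2 diag
  ap <- if (pad_reflect) reflect_pad(a, p) else {
    out <- array(0, dim = dim(a) + c(2 * p, 2 * p, if (length(dim(a)) == 3L) 0))
    if (length(dim(a)) == 2L) out[p + 1:H, p + 1:W] <- a
    else out[p + 1:H, p + 1:W, ] <- a
    out
  }
  r <- EBImage::rotate(hwc_to_ebi(ap), angle,
                       filter = if (nearest) "none" else "bilinear",
                       output.dim = dim(ap)[2:1])
  rr <- ebi_to_hwc(r)
  h0 <- (dim(rr)[1] - H) %/% 2; w0 <- (dim(rr)[2] - W) %/% 2
  if (length(dim(a)) == 2L) rr[h0 + 1:H, w0 + 1:W]
  else rr[h0 + 1:H, w0 + 1:W, , drop = FALSE]
}

#' Apply a seeded augmentation
#'
#' Horizontal/vertical flips, a random rotation and a random crop-and-resize
#' are applied with identical geometry to image and mask (mask via
#' nearest-neighbor, so it stays binary). The transform is fully determined
#' by `(cfg$seed, draw)`.
#'
#' @param s a Sample.
#' @param cfg an [augment_config()].
#' @param draw integer draw index.
#' @return the augmented Sample.
#' @export
augment_sample <- function(s, cfg, draw = 1L) {
  with_local_seed(derive_seed(cfg$seed, draw), {
    img <- s$image; msk <- s$mask
    if (stats::runif(1) < cfg$hflip_prob) {          # flip along width
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    }
    if (stats::runif(1) < cfg$vflip_prob) {          # flip along height
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
    }
    ang <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
    if (abs(ang) > 1e-9) {
      img <- rotate_hwc(img, ang, nearest = FALSE, pad_reflect = TRUE)
      msk <- rotate_hwc(msk, ang, nearest = TRUE, pad_reflect = FALSE)
    }
    scl <- stats::runif(1, cfg$crop_scale_range[1], cfg$crop_scale_range[2])
    if (scl < 1) {
      H <- dim(img)[1]; W <- dim(img)[2]
      ch <- max(1L, round(H * scl)); cw <- max(1L, round(W * scl))
      oy <- sample.int(H - ch + 1L, 1L); ox <- sample.int(W - cw + 1L, 1L)
      sub <- new_sample(img[oy + 1:ch - 1L, ox + 1:cw - 1L, , drop = FALSE],
                        (msk[oy + 1:ch - 1L, ox + 1:cw - 1L] > 0.5) * 1,
                        s$source)
      out <- resize_normalize(sub, c(H, W))
      img <- out$image; msk <- out$mask
    }
    new_sample(pmin(pmax(img, 0), 1), (msk > 0.5) * 1, s$source)
  })
}

#' Seed-deterministic three-way split
#'
#' @param samples list of Samples (or any list).
#' @param sizes integer `(n_train, n_val, n_test)`; must sum to
#'   `length(samples)`.
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` — a disjoint, exhaustive
#'   partition.
#' @export
random_split <- function(samples, sizes, seed = 1L) {
  if (length(sizes) != 3L || sum(sizes) != length(samples))
    stop("sizes (", paste(sizes, collapse = ", "), ") must sum to the number ",
         "of samples (", length(samples), ")")
  perm <- with_local_seed(seed, sample.int(length(samples)))
  i1 <- seq_len(sizes[1])
  i2 <- sizes[1] + seq_len(sizes[2])
  i3 <- sizes[1] + sizes[2] + seq_len(sizes[3])
  list(train = samples[perm[i1]], val = samples[perm[i2]],
       test = samples[perm[i3]])
}

#' Discover ISIC-layout image/mask pairs
#'
#' Matches `<stem>.jpg` images with `<stem>_segmentation.png` masks (the
#' patterns are configurable globs).
#'
#' @param images_dir,masks_dir directories.
#' @param image_glob,mask_suffix filename conventions.
#' @return data frame with columns `image` and `mask`.
#' @export
list_pairs <- function(images_dir, masks_dir, image_glob = "*.jpg",
                       mask_suffix = "_segmentation.png") {
  imgs <- Sys.glob(file.path(images_dir, image_glob))
  if (length(imgs) == 0) stop("no images matching ", image_glob, " in ",
                              images_dir)
  stems <- sub("\\.[^.]+$", "", basename(imgs))
  masks <- file.path(masks_dir, paste0(stems, mask_suffix))
  missing <- !file.exists(masks)
  if (any(missing))
    stop("missing masks for: ", paste(stems[missing], collapse = ", "))
  data.frame(image = imgs, mask = masks, stringsAsFactors = FALSE)
}

# Stack Samples into (H, W, C, N) / (H, W, 1, N) arrays for the network.
samples_to_batch <- function(samples) {
  H <- dim(samples[[1]]$image)[1]; W <- dim(samples[[1]]$image)[2]
  n <- length(samples)
  x <- array(0, dim = c(H, W, 3L, n))
  y <- array(0, dim = c(H, W, 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1L, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}
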