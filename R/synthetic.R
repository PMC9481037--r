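# ---------------------------------------------------------------------------
# Seeded generator of dermoscopy-like image/mask pairs.
#
# Emulates the three difficulty axes of real dermoscopy: (i) low lesion/skin
# contrast, (ii) irregular, variable-size lesions (a radially perturbed
# ellipse), (iii) hair/artifact occlusion (dark quadratic Bezier strokes)
# plus Gaussian pixel noise. The ground-truth mask is the exact rasterized
# lesion region recorded before hair and noise are applied.
# ---------------------------------------------------------------------------

#' Parameters of the synthetic lesion generator
#'
#' @param canvas integer `(H, W)` image size.
#' @param lesion_area_fraction interval of admissible mask foreground
#'   fractions; each draw samples a target fraction uniformly inside it.
#' @param boundary_irregularity non-negative amplitude of the smooth periodic
#'   radial perturbation (0 gives an exact ellipse).
#' @param contrast mean intensity gap between skin and lesion, in `[0, 1]`;
#'   lesion pixels are darker by exactly this amount (before hair/noise).
#' @param hair_count number of dark curved strokes drawn over the image.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param texture_sd amplitude of the smooth background skin texture.
#' @param seed integer master seed; `(seed, index)` fully determines a
#'   sample.
#' @return a `lesion_params` list.
#' @export
lesion_params <- function(canvas = c(128L, 128L),
                          lesion_area_fraction = c(0.05, 0.4),
                          boundary_irregularity = 0.15, contrast = 0.25,
                          hair_count = 6L, noise_sd = 0.02,
                          texture_sd = 0.015, seed = 1L) {
  stopifnot(length(canvas) == 2L, all(canvas >= 16),
            lesion_area_fraction[1] > 0, lesion_area_fraction[2] < 1,
            lesion_area_fraction[1] <= lesion_area_fraction[2],
            boundary_irregularity >= 0, contrast >= 0, contrast <= 1,
            hair_count >= 0, noise_sd >= 0)
  structure(list(canvas = as.integer(canvas),
                 lesion_area_fraction = lesion_area_fraction,
                 boundary_irregularity = boundary_irregularity,
                 contrast = contrast, hair_count = as.integer(hair_count),
                 noise_sd = noise_sd, texture_sd = texture_sd,
                 seed = as.integer(seed)),
            class = "lesion_params")
}

# Smooth low-frequency field in [-1, 1]: coarse white noise upsampled
# bilinearly to the canvas.
smooth_field <- function(H, W, cells = 6L) {
  coarse <- matrix(stats::runif(cells * cells, -1, 1), cells, cells)
  fine <- EBImage::resize(EBImage::Image(t(coarse)), w = W, h = H,
                          filter = "bilinear")
  t(EBImage::imageData(fine))
}

rasterize_lesion <- function(H, W, cx, cy, ra, rb, theta0, pert_coef) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- xx - cx; dy <- yy - cy
  # rotate into the ellipse frame
  u <- cos(theta0) * dx + sin(theta0) * dy
  v <- -sin(theta0) * dx + cos(theta0) * dy
  ang <- atan2(v / rb, u / ra)
  # smooth periodic radial modulation, harmonics 2..5
  mod <- matrix(1, H, W)
  for (k in seq_len(nrow(pert_coef)))
    mod <- mod + pert_coef[k, 1] * cos((k + 1) * ang) +
                 pert_coef[k, 2] * sin((k + 1) * ang)
  rho <- sqrt((u / ra)^2 + (v / rb)^2)
  (rho <= pmax(mod, 0.05)) * 1
}

#' Generate one synthetic dermoscopy-like sample
#'
#' @param p a [lesion_params()].
#' @param index integer sample index; `(p$seed, index)` fully determines the
#'   output.
#' @param with_artifacts draw hairs and pixel noise (disable to measure the
#'   clean lesion/skin contrast).
#' @return a Sample (`image`, `mask`, `source`).
#' @export
generate_sample <- function(p, index = 0L, with_artifacts = TRUE) {
  H <- p$canvas[1]; W <- p$canvas[2]
  with_local_seed(derive_seed(p$seed, index), {
    skin <- c(0.80, 0.62, 0.55) # light skin tone, RGB
    tex <- smooth_field(H, W) * p$texture_sd
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) img[, , ch] <- skin[ch] + tex
    mask <- NULL
    for (try in 1:60) {
      frac <- stats::runif(1, p$lesion_area_fraction[1], p$lesion_area_fraction[2])
      aspect <- stats::runif(1, 0.6, 1.4)
      r0 <- sqrt(frac * H * W / pi)
      ra <- r0 * sqrt(aspect); rb <- r0 / sqrt(aspect)
      if (2 * max(ra, rb) > 0.9 * min(H, W)) next
      margin_x <- min(W / 2 - 1, 1.15 * ra + 2)
      margin_y <- min(H / 2 - 1, 1.15 * rb + 2)
      cx <- stats::runif(1, 1 + margin_x, W - margin_x)
      cy <- stats::runif(1, 1 + margin_y, H - margin_y)
      pert <- matrix(stats::rnorm(8, sd = p$boundary_irregularity / 3), 4, 2)
      m <- rasterize_lesion(H, W, cx, cy, ra, rb,
                            stats::runif(1, 0, pi), pert)
      got <- mean(m)
      if (got >= p$lesion_area_fraction[1] && got <= p$lesion_area_fraction[2]) {
        mask <- m
        break
      }
    }
    if (is.null(mask))
      stop("could not fit a lesion satisfying the area fraction ",
           "constraint on a ", H, "x", W, " canvas")
    for (ch in 1:3) img[, , ch] <- img[, , ch] - p$contrast * mask
    if (with_artifacts && p$hair_count > 0) {
      for (h in seq_len(p$hair_count)) {
        pts <- bezier_stroke(H, W)
        shade <- stats::runif(1, 0.1, 0.3)
        wd <- sample(1:2, 1)
        for (i in seq_len(nrow(pts))) {
          y0 <- pts[i, 1]; x0 <- pts[i, 2]
          ys <- max(1, y0 - wd + 1):min(H, y0 + wd - 1)
          xs <- max(1, x0 - wd + 1):min(W, x0 + wd - 1)
          img[ys, xs, ] <- shade
        }
      }
    }
    if (with_artifacts && p$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = p$noise_sd), dim = dim(img))
    new_sample(pmin(pmax(img, 0), 1), mask,
               source = sprintf("synthetic:seed=%d:index=%d", p$seed, index))
  })
}

# Quadratic Bezier arc across the canvas, returned as integer (y, x) samples.
bezier_stroke <- function(H, W) {
  P <- matrix(c(stats::runif(3, 1, H), stats::runif(3, 1, W)), 3, 2)
  t <- seq(0, 1, length.out = 4L * max(H, W))
  b <- cbind((1 - t)^2 * P[1, 1] + 2 * (1 - t) * t * P[2, 1] + t^2 * P[3, 1],
             (1 - t)^2 * P[1, 2] + 2 * (1 - t) * t * P[2, 2] + t^2 * P[3, 2])
  unique(round(b))
}

#' Generate a dataset of synthetic samples
#'
#' @param p a [lesion_params()].
#' @param n number of samples; indices run `0..n-1`.
#' @return list with `samples` and `manifest` (the parameters and seed needed
#'   for exact regeneration).
#' @export
generate_dataset <- function(p, n) {
  stopifnot(n >= 1)
  samples <- lapply(seq_len(n) - 1L, function(i) generate_sample(p, i))
  manifest <- list(params = unclass(p), n = as.integer(n),
                   generator = "praseg synthetic lesion generator")
  list(samples = samples, manifest = manifest)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest the manifest of [generate_dataset()] (or a path to its
#'   JSON serialization).
#' @return the regenerated dataset, bit-identical to the original.
#' @export
regenerate_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  pp <- manifest$params
  p <- lesion_params(canvas = as.integer(unlist(pp$canvas)),
                     lesion_area_fraction = as.numeric(unlist(pp$lesion_area_fraction)),
                     boundary_irregularity = pp$boundary_irregularity,
                     contrast = pp$contrast, hair_count = pp$hair_count,
                     noise_sd = pp$noise_sd, texture_sd = pp$texture_sd,
                     seed = pp$seed)
  generate_dataset(p, manifest$n)
}

#' Write a synthetic dataset to an ISIC-style directory layout
#'
#' Images go to `<dir>/images/synth_<i>.jpg`, masks to
#' `<dir>/masks/synth_<i>_segmentation.png`, and the manifest to
#' `<dir>/manifest.json`.
#'
#' @param ds output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    stem <- sprintf("synth_%04d", i - 1L)
    EBImage::writeImage(hwc_to_ebi(s$image),
                        file.path(dir, "images", paste0(stem, ".jpg")),
                        quality = 98)
    EBImage::writeImage(hwc_to_ebi(s$mask),
                        file.path(dir, "masks",
                                  paste0(stem, "_segmentation.png")))
  }
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
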