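# Seeded synthetic lesion fixtures: blob-shaped foregrounds with Fourier-
# deformed outlines on a textured background, blurred boundaries, additive
# noise and optional dark hair-like strokes (the classic dermoscopy
# distractor). Masks are the un-blurred blob supports, so the generator
# emulates ISIC/GLAS-style pairs at desk scale without any download.

#' Specification for the synthetic fixture generator
#'
#' @param n_samples number of image/mask pairs.
#' @param size square image size in pixels (divisible by 8 for the network).
#' @param n_blobs range (length-2) or single count of lesion blobs per image.
#' @param blur_sigma Gaussian boundary blur, in pixels (0 disables).
#' @param noise_sd additive Gaussian noise SD, in intensity units on [0, 1].
#' @param texture_contrast mean foreground-background intensity separation.
#' @param hair_artifacts draw dark curvilinear strokes across the image.
#' @param seed integer seed; identical specs (including seed) produce
#'   bit-identical samples. The generator drives a private RNG stream and
#'   leaves the session RNG untouched.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 8L, size = 64L, n_blobs = c(1L, 3L),
                         blur_sigma = 1, noise_sd = 0.02,
                         texture_contrast = 0.35,
                         hair_artifacts = FALSE, seed = 1L) {
  if (n_samples <= 0) stop("n_samples must be positive", call. = FALSE)
  if (length(n_blobs) == 1L) n_blobs <- rep(n_blobs, 2L)
  structure(list(n_samples = as.integer(n_samples), size = as.integer(size),
                 n_blobs = as.integer(n_blobs), blur_sigma = blur_sigma,
                 noise_sd = noise_sd, texture_contrast = texture_contrast,
                 hair_artifacts = isTRUE(hair_artifacts),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# one deformed elliptical blob support on an size x size grid
blob_mask <- function(size, cx, cy, rx, ry, rot, wobble) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # col index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  dx <- xs - cx; dy <- ys - cy
  u <- cos(rot) * dx + sin(rot) * dy
  v <- -sin(rot) * dx + cos(rot) * dy
  theta <- atan2(v / ry, u / rx)
  r <- sqrt((u / rx)^2 + (v / ry)^2)
  deform <- 1 + wobble[1] * sin(2 * theta + wobble[3]) +
    wobble[2] * sin(3 * theta + wobble[4])
  r <= deform
}

smooth_noise_field <- function(size, sigma) {
  f <- matrix(stats::rnorm(size * size), size, size)
  if (sigma > 0) f <- EBImage::imageData(EBImage::gblur(EBImage::Image(f), sigma))
  f / max(stats::sd(f), 1e-8)
}

hair_stroke <- function(canvas) {
  size <- nrow(canvas)
  # quadratic bezier across the frame
  p0 <- stats::runif(2, 1, size); p2 <- stats::runif(2, 1, size)
  p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, size / 4)
  ts <- seq(0, 1, length.out = 4L * size)
  pts <- outer((1 - ts)^2, p0) + outer(2 * ts * (1 - ts), p1) + outer(ts^2, p2)
  ij <- unique(round(pts))
  keep <- ij[, 1] >= 1 & ij[, 1] <= size & ij[, 2] >= 1 & ij[, 2] <= size
  ij <- ij[keep, , drop = FALSE]
  canvas[ij] <- TRUE
  canvas
}

generate_one_fixture <- function(spec, k) {
  size <- spec$size
  nb <- if (spec$n_blobs[1] == spec$n_blobs[2]) spec$n_blobs[1] else
    sample(spec$n_blobs[1]:spec$n_blobs[2], 1L)
  mask2d <- matrix(FALSE, size, size)
  for (b in seq_len(nb)) {
    rx <- stats::runif(1, size / 8, size / 3.2)
    ry <- stats::runif(1, size / 8, size / 3.2)
    cx <- stats::runif(1, size * 0.25, size * 0.75)
    cy <- stats::runif(1, size * 0.25, size * 0.75)
    mask2d <- mask2d | blob_mask(size, cx, cy, rx, ry,
                                 stats::runif(1, 0, pi),
                                 c(stats::runif(2, 0, 0.15), stats::runif(2, 0, 2 * pi)))
  }
  if (!any(mask2d)) {         # degenerate draw: guarantee nonempty support
    mask2d[size %/% 2, size %/% 2] <- TRUE
  }
  m <- array(0, c(1L, size, size))
  m[1, , ] <- mask2d * 1

  base_bg <- 0.30 + stats::runif(1, -0.05, 0.05)
  base_fg <- base_bg + spec$texture_contrast
  tex_bg <- smooth_noise_field(size, 2) * 0.05
  tex_fg <- smooth_noise_field(size, 1) * 0.07
  tint_bg <- stats::runif(3, -0.04, 0.04)
  tint_fg <- stats::runif(3, -0.04, 0.04)

  img <- array(0, c(3L, size, size))
  for (c in 1:3) {
    bg <- base_bg + tint_bg[c] + tex_bg
    fg <- base_fg + tint_fg[c] + tex_fg
    img[c, , ] <- bg * (1 - mask2d) + fg * mask2d
  }
  if (spec$hair_artifacts) {
    strokes <- matrix(FALSE, size, size)
    for (s in seq_len(3L)) strokes <- hair_stroke(strokes)
    for (c in 1:3) img[c, , ][strokes] <- img[c, , ][strokes] * 0.25
  }
  if (spec$blur_sigma > 0) {
    for (c in 1:3) {
      img[c, , ] <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(img[c, , ]), spec$blur_sigma))
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  new_image_sample(id = sprintf("fixture_%03d", k), image = img, mask = m,
                   source_size = c(size, size))
}

#' Generate seeded synthetic image/mask fixtures
#'
#' @param spec a [fixture_spec()].
#' @return list of `image_sample` objects; every mask has at least one
#'   foreground pixel, and identical specs yield bit-identical samples.
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_samples), function(k) generate_one_fixture(spec, k))
}

#' Write fixtures to an images/ + masks/ directory layout
#'
#' @param samples list of `image_sample` objects.
#' @param dir output directory; `images/` and `masks/` are created inside.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    EBImage::writeImage(chw_to_ebimage(s$image),
                        file.path(dir, "images", paste0(s$id, ".png")))
    write_prediction(s$mask, file.path(dir, "masks", paste0(s$id, ".png")))
  }
  invisible(dir)
}
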