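# Image/mask I/O and the foreground/background decomposition.
#
# Conventions: images are numeric arrays [3, row, col] in [0,1]; masks are
# binary arrays [1, row, col] with foreground = 1. Masks are binarized at
# 0.5 after any resize so the decomposition algebra (If = Is * Im,
# Ib = Is * (1 - Im), If + Ib = Is) holds exactly.

# EBImage stores [x (col), y (row), channel]; convert to [channel, row, col]
ebimage_to_chw <- function(img, channels = 3L) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, channels), c(dim(a), channels))
  if (dim(a)[3] > channels) a <- a[, , seq_len(channels), drop = FALSE]
  aperm(a, c(3, 2, 1))
}

chw_to_ebimage <- function(x) {
  a <- aperm(x, c(3, 2, 1))
  if (dim(a)[3] == 1L) {
    EBImage::Image(a[, , 1])
  } else {
    EBImage::Image(a, colormode = "Color")
  }
}

#' Load an image/mask pair
#'
#' Reads a PNG/JPEG image and its single-channel mask, resizes both to a
#' square working resolution (image: bilinear; mask: nearest-neighbor), and
#' binarizes the mask at 0.5. Image and mask may have different on-disk
#' sizes; each is resized independently.
#'
#' @param image_path,mask_path file paths; `mask_path` may be `NULL` for an
#'   unlabeled image (the sample then carries no mask).
#' @param working_size target square size in pixels.
#' @param id sample identifier; defaults to the image file stem.
#' @return an `image_sample`: list with `id`, `image` (`[3, S, S]` in
#'   `[0, 1]`), `mask` (`[1, S, S]` binary or `NULL`), `source_size`
#'   (height, width of the image file).
#' @export
load_sample <- function(image_path, mask_path = NULL, working_size = 256L,
                        id = NULL) {
  if (working_size <= 0) stop("working_size must be positive", call. = FALSE)
  if (!file.exists(image_path)) {
    stop("cannot read image file: ", image_path, call. = FALSE)
  }
  img <- tryCatch(EBImage::readImage(image_path),
                  error = function(e) stop("cannot decode image file: ",
                                           image_path, call. = FALSE))
  src <- dim(EBImage::imageData(img))[1:2]
  img <- EBImage::resize(img, w = working_size, h = working_size,
                         filter = "bilinear")
  image <- ebimage_to_chw(img, 3L)
  image[image < 0] <- 0; image[image > 1] <- 1
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) {
      stop("cannot read mask file: ", mask_path, call. = FALSE)
    }
    mk <- tryCatch(EBImage::readImage(mask_path),
                   error = function(e) stop("cannot decode mask file: ",
                                            mask_path, call. = FALSE))
    mk <- EBImage::resize(mk, w = working_size, h = working_size,
                          filter = "none")
    mask <- ebimage_to_chw(mk, 1L)[1, , , drop = FALSE]
    mask <- binarize_mask(mask)
    if (sum(mask) == 0) {
      warning("mask is empty after loading: ", mask_path, call. = FALSE)
    }
  }
  new_image_sample(id = if (is.null(id)) file_stem(image_path) else id,
                   image = image, mask = mask,
                   source_size = c(src[2], src[1]))
}

new_image_sample <- function(id, image, mask, source_size) {
  structure(list(id = id, image = image, mask = mask,
                 source_size = as.integer(source_size)),
            class = "image_sample")
}

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Binarize a mask at 0.5
#'
#' Idempotent on already-binary masks.
#'
#' @param mask numeric array.
#' @return array of the same shape containing only 0 and 1.
#' @export
binarize_mask <- function(mask) {
  out <- array(as.numeric(mask >= 0.5), dim(mask))
  out
}

assert_binary <- function(mask, what = "mask") {
  if (!all(mask %in% c(0, 1))) {
    stop(what, " must be binary (values in {0, 1})", call. = FALSE)
  }
  invisible(TRUE)
}

#' Foreground/background decomposition
#'
#' Splits an image by its binary mask: `foreground = image * mask`,
#' `background = image * (1 - mask)` (mask broadcast over channels), so
#' `foreground + background` reproduces the image exactly.
#'
#' @param sample an `image_sample` with a mask.
#' @return list with `foreground` and `background`, both `[3, H, W]`.
#' @export
decompose_sample <- function(sample) {
  stopifnot(inherits(sample, "image_sample"))
  if (is.null(sample$mask)) {
    stop("decompose_sample: sample has no mask", call. = FALSE)
  }
  fb_decompose(sample$image, sample$mask)
}

# array-level decomposition shared with the training path
fb_decompose <- function(image, mask) {
  assert_binary(mask)
  m <- mask[1, , ]
  d <- dim(image)
  mb <- aperm(array(rep(m, d[1]), c(d[2], d[3], d[1])), c(3, 1, 2))
  list(foreground = image * mb, background = image * (1 - mb))
}

#' Write a binary mask as a PNG prediction
#'
#' Foreground is stored as 255, background as 0; the file round-trips
#' through [load_sample()] / [EBImage::readImage].
#'
#' @param mask binary `[1, H, W]` array.
#' @param path output file path (`.png`).
#' @return the path, invisibly.
#' @export
write_prediction <- function(mask, path) {
  assert_binary(mask)
  ok <- tryCatch({
    EBImage::writeImage(chw_to_ebimage(mask), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    stop("cannot write prediction to: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a paired image/mask dataset directory
#'
#' Expects subdirectories `images/` and `masks/` with matching file stems,
#' or a CSV manifest with columns `id`, `image`, `mask` (paths relative to
#' the manifest's directory).
#'
#' @param dir dataset directory.
#' @param working_size working resolution passed to [load_sample()].
#' @param manifest optional CSV manifest path.
#' @return list of `image_sample` objects.
#' @export
read_dataset <- function(dir, working_size = 256L, manifest = NULL) {
  if (!is.null(manifest)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    base <- dirname(manifest)
    return(lapply(seq_len(nrow(tab)), function(k) {
      load_sample(file.path(base, tab$image[k]),
                  if ("mask" %in% names(tab) && nzchar(tab$mask[k])) {
                    file.path(base, tab$mask[k])
                  },
                  working_size, id = tab$id[k])
    }))
  }
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (!length(imgs)) stop("no images under ", file.path(dir, "images"), call. = FALSE)
  masks <- list.files(file.path(dir, "masks"), full.names = TRUE)
  mask_by_stem <- stats::setNames(masks, vapply(masks, file_stem, ""))
  lapply(imgs, function(p) {
    mp <- mask_by_stem[[file_stem(p)]]
    load_sample(p, mp, working_size)
  })
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<image_sample '%s'> %dx%d px, %s mask (source %dx%d)\n",
              x$id, d[2], d[3],
              if (is.null(x$mask)) "no" else
                sprintf("%d-px-foreground", sum(x$mask)),
              x$source_size[1], x$source_size[2]))
  invisible(x)
}
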