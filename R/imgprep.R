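# Image preparation: I/O, nearest-neighbour resizing, Gaussian smoothing,
# histogram equalization and paired image/mask augmentation.
#
# Images are plain numeric matrices with intensities on the canonical
# internal scale [0, 1] (8-bit files are divided by 255 on read). Masks are
# 0/1 matrices of the same shape as their paired image. Coordinates are
# 0-based (row, col) internally wherever a continuous lattice is mapped.

#' Read a grayscale image from a PNG or TIFF file
#'
#' Intensities are returned on the [0, 1] scale. Colour images are reduced
#' to a single channel by averaging the channels, which is lossless for the
#' channel-replicated grayscale files typical of B-mode ultrasound exports.
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff)
#' @return numeric matrix of intensities in [0, 1]
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    sq_stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3L, dim(arr)[3L]),
                                              drop = FALSE], c(1, 2), mean)
  clip01(arr)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img numeric matrix in [0, 1]
#' @param path output path (.png, .tif, .tiff)
#' @return invisibly, the path
#' @export
write_image <- function(img, path) {
  assert_image(img)
  ext <- tolower(tools::file_ext(path))
  # 8-bit scale with half-up rounding, then back to [0,1] for the writers
  q <- round_half_up(img * 255, 0) / 255
  switch(ext,
    png  = png::writePNG(q, path),
    tif  = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    sq_stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read a binary mask (0/255 8-bit file) as a 0/1 matrix
#' @param path file path
#' @return 0/1 numeric matrix
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  (m > 0.5) * 1
}

#' Write a 0/1 mask as a 0/255 8-bit image file
#' @param mask 0/1 matrix
#' @param path output path
#' @return invisibly, the path
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  write_image(mask, path)
}

#' Nearest-neighbour resize
#'
#' Each output pixel takes the value of the input pixel whose centre is
#' nearest to the output pixel's continuous source coordinate: with 0-based
#' indices, source index = INT((i + 0.5) * size_in / size_out), applied
#' independently to the row and column lattices. No new intensity values
#' are introduced.
#'
#' @param img numeric matrix in [0, 1]
#' @param target integer vector (rows, cols) of the output shape
#' @return resized matrix of shape \code{target}
#' @export
resize_nearest <- function(img, target) {
  assert_image(img)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    sq_stop("target must be two positive integers (rows, cols)")
  src_idx <- function(n_out, n_in) {
    i <- seq_len(n_out) - 1L
    pmin(n_in - 1L, trunc((i + 0.5) * n_in / n_out)) + 1L
  }
  img[src_idx(target[1L], nrow(img)), src_idx(target[2L], ncol(img)),
      drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  d <- seq(-r, r)
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2)) / (2 * pi * sigma^2)
  k / sum(k)   # renormalize after truncation
}

# symmetric (edge-duplicating) reflection of 0-based indices
reflect_idx <- function(i, n) {
  i <- i %% (2L * n)
  ifelse(i < 0L, -1L - i, ifelse(i >= n, 2L * n - 1L - i, i))
}

#' Gaussian smoothing
#'
#' Convolves with the isotropic kernel exp(-(i^2+j^2)/(2 sigma^2)) /
#' (2 pi sigma^2), truncated at radius ceiling(3 sigma) and renormalized to
#' sum 1. Boundaries are handled by symmetric reflection, which preserves
#' the image mean exactly. The output is clipped to [0, 1].
#'
#' @param img numeric matrix in [0, 1]
#' @param sigma kernel standard deviation in pixels, > 0
#' @return smoothed matrix
#' @export
gaussian_smooth <- function(img, sigma) {
  assert_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    sq_stop("sigma must be a single positive number")
  k <- gaussian_kernel(sigma)
  r <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- reflect_idx(seq(-r, nr - 1L + r), nr) + 1L
  ci <- reflect_idx(seq(-r, nc - 1L + r), nc) + 1L
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (di in seq_len(nrow(k))) {
    for (dj in seq_len(ncol(k))) {
      out <- out + k[di, dj] *
        pad[(di - 1L) + seq_len(nr), (dj - 1L) + seq_len(nc), drop = FALSE]
    }
  }
  clip01(out)
}

#' Histogram equalization
#'
#' Builds a monotone non-decreasing intensity map from the cumulative
#' histogram over \code{bins} equal-width bins on [0, 1] and applies it, so
#' pixel rank order is preserved. A constant image has a degenerate CDF and
#' is returned unchanged with a warning.
#'
#' @param img numeric matrix in [0, 1]
#' @param bins number of histogram bins (>= 2), default 256
#' @return equalized matrix in [0, 1]
#' @export
hist_equalize <- function(img, bins = 256L) {
  assert_image(img)
  bins <- as.integer(bins)
  if (bins < 2L) sq_stop("bins must be >= 2")
  if (diff(range(img)) == 0) {
    warning("constant image: histogram equalization is a no-op")
    return(img)
  }
  b <- pmin(bins - 1L, floor(img * bins))          # 0-based bin index
  counts <- tabulate(b + 1L, nbins = bins)
  cdf <- cumsum(counts) / length(img)
  matrix(cdf[b + 1L], nrow(img), ncol(img))
}

#' Augmentation specification
#'
#' Bundles one geometric + photometric transform. The geometric part
#' (shift, scale, rotate, horizontal flip) is applied identically to image
#' and mask; photometric operators (CLAHE, brightness, sharpen, contrast
#' stretch) touch the image only.
#'
#' @param shift translation as a fraction of image size, |shift| < 1
#'   (length 1 or 2: rows, cols)
#' @param scale multiplicative zoom factor, > 0
#' @param rotate rotation in degrees about the image centre
#' @param hflip logical, mirror columns
#' @param clahe logical, contrast-limited adaptive histogram equalization
#' @param brightness_delta additive intensity offset
#' @param sharpen logical, unsharp masking
#' @param contrast_stretch logical, percentile contrast stretch
#' @param seed integer; fully determines the transform
#' @return an object of class \code{augment_spec}
#' @export
augment_spec <- function(shift = 0, scale = 1, rotate = 0, hflip = FALSE,
                         clahe = FALSE, brightness_delta = 0,
                         sharpen = FALSE, contrast_stretch = FALSE,
                         seed = 0L) {
  if (scale <= 0) sq_stop("scale must be > 0")
  if (any(abs(shift) >= 1)) sq_stop("|shift| must be < 1")
  structure(list(shift = rep(shift, length.out = 2L), scale = scale,
                 rotate = rotate, hflip = hflip, clahe = clahe,
                 brightness_delta = brightness_delta, sharpen = sharpen,
                 contrast_stretch = contrast_stretch,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# inverse-map geometric transform, nearest-neighbour resampling; pixels
# mapped from outside the source lattice become `fill`
geom_transform <- function(img, spec, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  th <- spec$rotate * pi / 180
  gr <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  gc <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  if (spec$hflip) gc <- (nc - 1) - gc
  # undo shift, then rotation/scale about the centre
  y <- gr - spec$shift[1L] * nr - cy
  x <- gc - spec$shift[2L] * nc - cx
  sy <- ( cos(th) * y + sin(th) * x) / spec$scale + cy
  sx <- (-sin(th) * y + cos(th) * x) / spec$scale + cx
  si <- floor(sy + 0.5); sj <- floor(sx + 0.5)
  ok <- si >= 0 & si < nr & sj >= 0 & sj < nc
  out <- matrix(fill, nr, nc)
  out[ok] <- img[cbind(si[ok] + 1L, sj[ok] + 1L)]
  out
}

unsharp <- function(img, amount = 1, sigma = 1) {
  clip01(img + amount * (img - gaussian_smooth(img, sigma)))
}

stretch_contrast <- function(img, lo = 0.01, hi = 0.99) {
  q <- stats::quantile(img, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(img)
  clip01((img - q[1]) / (q[2] - q[1]))
}

apply_clahe <- function(img) {
  nx <- max(2L, min(8L, ncol(img) %/% 16L))
  ny <- max(2L, min(8L, nrow(img) %/% 16L))
  out <- EBImage::clahe(EBImage::Image(t(img)), nx = nx, ny = ny)
  clip01(t(EBImage::imageData(out)))
}

#' Paired image/mask augmentation
#'
#' Applies the same geometric transform to image and mask (both resampled
#' with nearest neighbour, so the mask stays binary), then the photometric
#' operators to the image only. Fully deterministic given the spec.
#'
#' @param img numeric matrix in [0, 1]
#' @param mask paired 0/1 matrix of the same shape
#' @param spec an \code{\link{augment_spec}}
#' @return list with elements \code{img} and \code{mask}
#' @export
augment_pair <- function(img, mask, spec) {
  assert_image(img)
  assert_mask(mask, img)
  if (!inherits(spec, "augment_spec")) sq_stop("spec must be an augment_spec")
  geom_needed <- spec$hflip || any(spec$shift != 0) || spec$scale != 1 ||
    spec$rotate != 0
  if (geom_needed) {
    img <- geom_transform(img, spec)
    mask <- geom_transform(mask, spec)
  }
  if (spec$clahe) img <- apply_clahe(img)
  if (spec$brightness_delta != 0) img <- clip01(img + spec$brightness_delta)
  if (spec$sharpen) img <- unsharp(img)
  if (spec$contrast_stretch) img <- stretch_contrast(img)
  list(img = img, mask = mask)
}
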