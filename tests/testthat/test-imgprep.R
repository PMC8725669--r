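test_that("nearest-neighbour resize is exact on identity and block upscaling", {
  set.seed(11)
  img <- matrix(runif(15 * 13), 15, 13)
  expect_identical(resize_nearest(img, dim(img)), img)

  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- resize_nearest(cb, c(4L, 4L))
  # brute-force oracle: nearest source pixel centre per output pixel
  oracle <- matrix(0, 4, 4)
  for (i in 0:3) for (j in 0:3) {
    sy <- (i + 0.5) * 2 / 4 - 0.5
    sx <- (j + 0.5) * 2 / 4 - 0.5
    d <- outer((0:1 - sy)^2, (0:1 - sx)^2, "+")
    w <- which(d == min(d), arr.ind = TRUE)[1, ]
    oracle[i + 1, j + 1] <- cb[w[1], w[2]]
  }
  expect_identical(up, oracle)
  expect_identical(up, matrix(c(0, 0, 1, 1, 0, 0, 1, 1,
                                1, 1, 0, 0, 1, 1, 0, 0), 4, 4))
})

test_that("resize introduces no new intensity values and rejects bad targets", {
  set.seed(3)
  for (i in 1:5) {
    img <- matrix(sample(c(0.1, 0.4, 0.9), 60, replace = TRUE), 10, 6)
    out <- resize_nearest(img, c(sample(1:20, 1), sample(1:20, 1)))
    expect_true(all(out %in% img))
  }
  # canonical working size round-trip stays within the input value set
  big <- resize_nearest(matrix(runif(16), 4, 4), c(512L, 512L))
  expect_identical(dim(big), c(512L, 512L))
  expect_error(resize_nearest(matrix(0.5, 2, 2), c(0L, 4L)), "positive")
})

test_that("gaussian smoothing matches the normalized truncated kernel", {
  # impulse response equals direct evaluation of the kernel
  for (sigma in c(0.5, 1.3)) {
    n <- 2L * ceiling(3 * sigma) + 7L
    img <- matrix(0, n, n)
    cen <- (n + 1L) %/% 2L
    img[cen, cen] <- 1
    out <- gaussian_smooth(img, sigma)
    r <- ceiling(3 * sigma)
    d <- seq(-r, r)
    k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2)) / (2 * pi * sigma^2)
    k <- k / sum(k)
    expect_equal(out[cen + d, cen + d], k, tolerance = 1e-12)
  }
})

test_that("smoothing preserves constants, the mean, and the intensity range", {
  expect_equal(gaussian_smooth(matrix(0.42, 9, 7), 0.5),
               matrix(0.42, 9, 7), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    img <- matrix(runif(19 * 23), 19, 23)
    out <- gaussian_smooth(img, runif(1, 0.4, 2.5))
    expect_lt(abs(mean(out) - mean(img)), 1e-9)
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
  }
  expect_error(gaussian_smooth(matrix(0.5, 3, 3), 0), "positive")
})

test_that("histogram equalization maps two-valued images to their CDF levels", {
  img <- matrix(c(rep(0.2, 30), rep(0.7, 70)), 10, 10)
  out <- hist_equalize(img)
  expect_equal(sort(unique(as.vector(out))), c(0.3, 1.0))
  expect_true(all(out[img == 0.2] == 0.3))
  expect_true(all(out[img == 0.7] == 1.0))
})

test_that("equalization preserves rank order and is near-identity on uniform data", {
  set.seed(9)
  img <- matrix(runif(40 * 40), 40, 40)
  out <- hist_equalize(img)
  o <- order(img)
  expect_true(all(diff(out[o]) >= 0))
  # a uniform histogram is (within one bin) a fixed point of the CDF map
  expect_lt(max(abs(out - img)), 2 / 256 + 3 / sqrt(length(img)))
  expect_warning(hist_equalize(matrix(0.5, 4, 4)), "constant")
})

test_that("augmentation applies identical geometry to image and mask", {
  set.seed(21)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(0, 32, 32); mask[10:16, 5:12] <- 1

  idn <- augment_pair(img, mask, augment_spec())
  expect_identical(idn$img, img)
  expect_identical(idn$mask, mask)

  fl <- augment_pair(img, mask, augment_spec(hflip = TRUE))
  cen0 <- mean(which(mask > 0, arr.ind = TRUE)[, 2]) - 1   # 0-based
  cen1 <- mean(which(fl$mask > 0, arr.ind = TRUE)[, 2]) - 1
  expect_equal(cen1, (32 - 1) - cen0, tolerance = 1e-12)
  expect_true(all(fl$mask %in% c(0, 1)))

  # full operator list composes and keeps the mask binary
  full <- augment_pair(img, mask, augment_spec(
    shift = 0.05, scale = 1.08, rotate = 12, hflip = TRUE, clahe = TRUE,
    brightness_delta = 0.05, sharpen = TRUE, contrast_stretch = TRUE))
  expect_true(all(full$mask %in% c(0, 1)))
  expect_true(all(full$img >= 0 & full$img <= 1))
  # determinism
  again <- augment_pair(img, mask, augment_spec(
    shift = 0.05, scale = 1.08, rotate = 12, hflip = TRUE, clahe = TRUE,
    brightness_delta = 0.05, sharpen = TRUE, contrast_stretch = TRUE))
  expect_identical(full, again)
  expect_error(augment_pair(img, mask[1:10, ], augment_spec()), "shape")
})

test_that("geometric transform commutes with mask binarization", {
  set.seed(33)
  soft <- matrix(runif(24 * 24), 24, 24)
  spec <- augment_spec(shift = 0.1, scale = 0.9, rotate = 20, hflip = TRUE)
  tr_then_bin <- (sonoquant:::geom_transform(soft, spec) > 0.5) * 1
  bin_then_tr <- sonoquant:::geom_transform((soft > 0.5) * 1, spec)
  expect_identical(tr_then_bin, bin_then_tr)
})

test_that("image and mask files round-trip through PNG at 8-bit precision", {
  tmp <- withr::local_tempdir()
  set.seed(2)
  img <- matrix(runif(20 * 18), 20, 18)
  f <- file.path(tmp, "img.png")
  write_image(img, f)
  expect_lt(max(abs(read_image(f) - img)), 1 / 255)
  mask <- matrix(rbinom(20 * 18, 1, 0.4), 20, 18)
  fm <- file.path(tmp, "mask.png")
  write_mask(mask, fm)
  expect_identical(read_mask(fm), mask * 1)
})
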