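test_that("single Otsu threshold separates a bimodal image", {
  img <- matrix(c(rep(0.2, 40), rep(0.8, 24)), 8, 8)
  t <- otsu_thresholds(img, 1L)
  expect_length(t, 1L)
  expect_gt(t, 0.2)
  expect_lte(t, 0.8)
})

test_that("multilevel thresholds equal exhaustive brute-force search", {
  set.seed(17)
  # unequal three-plateau image
  img <- matrix(sample(c(0.1, 0.5, 0.9), 64, replace = TRUE,
                       prob = c(0.5, 0.2, 0.3)), 8, 8)
  expect_equal(otsu_thresholds(img, 2L), brute_otsu(img, 2L))
  for (s in 1:6) {
    set.seed(s)
    img <- matrix(runif(24 * 24)^1.5, 24, 24)
    expect_equal(otsu_thresholds(img, 1L), brute_otsu(img, 1L))
    expect_equal(otsu_thresholds(img, 2L), brute_otsu(img, 2L))
  }
})

test_that("thresholding rejects images with too few distinct values", {
  img <- matrix(c(rep(0.3, 30), rep(0.6, 34)), 8, 8)
  expect_error(otsu_thresholds(img, 2L), "2 distinct")
})

test_that("quantization implements the half-open threshold binning", {
  img <- matrix(c(0.1, 0.49, 0.5, 0.51, 0.9, 1.0), 2, 3)
  lev <- quantize(img, 0.5)
  expect_identical(as.vector(lev), c(0L, 0L, 1L, 1L, 1L, 1L))
  # a 1 x n threshold vector yields n+1 levels on a piecewise image
  img3 <- matrix(sample(c(0.1, 0.5, 0.9), 100, replace = TRUE,
                        prob = c(0.3, 0.3, 0.4)), 10, 10)
  t <- otsu_thresholds(img3, 2L)
  lev3 <- quantize(img3, t)
  expect_identical(sort(unique(as.vector(lev3))), 0:2)
  # idempotence: labels reproduce the generating partition
  expect_identical(lev3 == 0L, img3 == 0.1)
  expect_identical(lev3 == 2L, img3 == 0.9)
})

test_that("class-mean remapping of quantized labels is squared-error optimal", {
  set.seed(8)
  img <- matrix(runif(30 * 30), 30, 30)
  t <- otsu_thresholds(img, 3L)
  lev <- quantize(img, t)
  v <- as.vector(img); l <- as.character(as.vector(lev))
  means <- tapply(v, l, mean)
  sse_mean <- sum((v - means[l])^2)
  for (i in 1:10) {
    other <- means + rnorm(length(means), sd = 0.05)
    expect_gte(sum((v - other[l])^2), sse_mean)
  }
})

test_that("lesion selection recovers a dark disk without a coarse mask", {
  nr <- 64
  gr <- matrix(rep(1:nr, nr), nr, nr); gc <- t(gr)
  disk <- ((gr - 32)^2 + (gc - 40)^2 <= 12^2) * 1
  img <- matrix(0.9, nr, nr); img[disk > 0] <- 0.1
  lev <- quantize(img, otsu_thresholds(img, 1L))
  out <- select_lesion(lev, img)
  expect_identical(out, disk)
})

test_that("coarse-guided selection keeps the overlapping dark component only", {
  nr <- 64
  gr <- matrix(rep(1:nr, nr), nr, nr); gc <- t(gr)
  ell <- (((gr - 30) / 14)^2 + ((gc - 26) / 9)^2 <= 1) * 1
  spur <- ((gr - 54)^2 + (gc - 54)^2 <= 5^2) * 1
  img <- matrix(0.85, nr, nr)
  img[ell > 0] <- 0.15
  img[spur > 0] <- 0.2            # second dark component, away from coarse
  coarse <- (((gr - 30) / 16)^2 + ((gc - 26) / 11)^2 <= 1) * 1
  lev <- quantize(img, otsu_thresholds(img, 1L))
  out <- select_lesion(lev, img, coarse = coarse)
  expect_identical(out, ell)
})

test_that("selected lesions are a single filled 8-connected component", {
  set.seed(4)
  for (s in 1:5) {
    p <- simple_phantom(s, label = "M")
    work <- gaussian_smooth(p$image, 1.5)
    lev <- quantize(work, otsu_thresholds(work, 3L))
    out <- select_lesion(lev, work)
    if (sum(out) == 0) next
    lab <- sonoquant:::label_components_8(out)
    expect_identical(max(lab), 1L)
    expect_identical(sonoquant:::fill_holes(out), out)
  }
})

test_that("refinement passes trustworthy coarse masks through unchanged", {
  p <- simple_phantom(42)
  out <- refine_segmentation(p$image, p$mask)
  expect_false(attr(out, "refined"))
  expect_equal(unclass(out)[, ], p$mask, ignore_attr = TRUE)
  # pass-through never degrades IoU (identity)
  expect_equal(mean_iou(list((out > 0) * 1), list(p$mask)), 1)
})

test_that("the quantization path recovers lesions from an empty coarse mask", {
  ious <- vapply(1:8, function(s) {
    p <- simple_phantom(s)
    out <- refine_segmentation(p$image, matrix(0, 128, 128))
    expect_true(attr(out, "refined"))
    sum(out > 0 & p$mask > 0) / sum(out > 0 | p$mask > 0)
  }, 0)
  expect_gte(mean(ious), 0.7)
})

test_that("refinement falls back to the coarse mask on degenerate images", {
  img <- matrix(c(rep(0.3, 60), rep(0.7, 68)), 8, 16)  # two distinct values
  coarse <- matrix(0, 8, 16)
  out <- refine_segmentation(img, coarse, n = 3L, smooth_sigma = 0)
  expect_false(attr(out, "refined"))
  expect_equal(unclass(out)[, ], coarse, ignore_attr = TRUE)
})
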