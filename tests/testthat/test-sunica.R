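test_that("patch extraction subtracts per-patch means exactly", {
  cfg <- patch_config(patch_size = 11L, stride = 3L)
  # constant image: all-zero patches
  P <- extract_patches(matrix(0.6, 30, 30), cfg)
  expect_true(all(P == 0))
  # ramp image: patch means are exactly zero after subtraction
  ramp <- matrix(rep(seq(0, 1, length.out = 40), 40), 40, 40)
  P <- extract_patches(ramp, cfg)
  expect_lt(max(abs(rowMeans(P))), 1e-14)
  expect_identical(ncol(P), 121L)
  expect_error(extract_patches(matrix(0.5, 8, 8), cfg), "patch_size")
  # seeded subsampling is deterministic
  set.seed(99)
  img <- matrix(runif(50 * 50), 50, 50)
  small <- patch_config(patch_size = 5L, stride = 1L, max_patches = 200L,
                        seed = 7L)
  expect_identical(extract_patches(img, small), extract_patches(img, small))
})

test_that("fixed-point ICA recovers orthogonally mixed Laplacian sources", {
  set.seed(7)
  d <- 8L; n <- 20000L
  S <- matrix(rexp(d * n) * sample(c(-1, 1), d * n, replace = TRUE), d, n)
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  X <- t(Q %*% S)                                 # n x d "patches"
  model <- fit_ica_model(X, k = d, drop_top = 0L, seed = 1L)
  # the response projection applied to the mixing must be a signed
  # permutation (up to scale): each source loads one filter only
  R <- model$proj %*% Q
  cors <- apply(abs(R), 2, max) / sqrt(colSums(R^2))
  expect_gte(min(cors), 0.95)
})

test_that("generalized Gaussian moment fit recovers shape and scale", {
  for (beta in c(1, 2)) {
    for (s in 1:3) {
      set.seed(s)
      x <- rggd(10000L, beta, s = 1.3)
      fit <- sonoquant:::fit_ggd(x)
      expect_lt(abs(fit$beta - beta) / beta, 0.1)
      expect_lt(abs(fit$scale - 1.3) / 1.3, 0.15)
    }
  }
})

local_model <- function() {
  set.seed(12)
  imgs <- lapply(1:4, function(i) matrix(runif(48 * 48), 48, 48))
  patches <- extract_patches(imgs, patch_config(patch_size = 7L, stride = 1L,
                                                max_patches = 8000L, seed = 2L))
  fit_ica_model(patches, k = 8L, drop_top = 1L, seed = 3L)
}

test_that("log-saliency equals the sum of per-filter -log P(f_i)", {
  model <- local_model()
  set.seed(5)
  img <- matrix(runif(20 * 20), 20, 20)
  g <- expand.grid(r = 4:17, c = 4:17)
  resp <- sonoquant:::model_responses(img, model, g$r, g$c)
  joint <- sonoquant:::neglog_pf(resp, model)
  manual <- rep(0, ncol(resp))
  for (i in seq_len(model$k)) {
    b <- model$ggd_shape[i]; s <- model$ggd_scale[i]
    logpdf <- log(b / (2 * s)) - lgamma(1 / b) - abs(resp[i, ] / s)^b
    manual <- manual - logpdf
  }
  expect_lt(max(abs(joint - manual)), 1e-9)
})

test_that("saliency is flat on constant images and shift-invariant", {
  model <- local_model()
  smap <- saliency_map(matrix(0.37, 25, 25), model)
  expect_true(all(smap == 0))
  set.seed(6)
  img <- sonoquant:::clip01(matrix(runif(25 * 25, 0.2, 0.6), 25, 25))
  expect_equal(saliency_map(img, model),
               saliency_map(sonoquant:::clip01(img + 0.2), model), tolerance = 1e-9)
})

test_that("an oddball patch attracts the saliency maximum", {
  model <- local_model()
  set.seed(31)
  # low-contrast homogeneous texture with one high-contrast oddball patch
  # (per-patch mean subtraction makes saliency a contrast rarity, so the
  # oddball must differ in local structure, not in mean level)
  img <- matrix(0.5 + 0.08 * sin(outer(1:40, 1:40, "+")), 40, 40)
  img <- sonoquant:::clip01(img + matrix(rnorm(1600, sd = 0.01), 40, 40))
  odd <- img
  odd[18:24, 18:24] <- (outer(18:24, 18:24, "+") %% 2)   # checkerboard
  smap <- saliency_map(odd, model)
  peak <- which(smap == max(smap), arr.ind = TRUE)[1, ]
  expect_true(peak[1] >= 15 && peak[1] <= 27)
  expect_true(peak[2] >= 15 && peak[2] <= 27)
})

test_that("lesion feature vectors are unit-norm and local to the mask", {
  model <- local_model()
  set.seed(44)
  base <- matrix(runif(40 * 40), 40, 40)
  mask <- matrix(0, 40, 40); mask[15:25, 15:25] <- 1
  f <- ica_feature_vector(base, mask, model)
  expect_length(f, model$k + 1L)
  expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-12)
  # altering the image outside the patch-dilated mask leaves f1 unchanged
  other <- base
  other[1:8, ] <- runif(8 * 40)
  other[, 33:40] <- runif(40 * 8)
  expect_equal(ica_feature_vector(other, mask, model), f, tolerance = 1e-12)
  expect_error(ica_feature_vector(base, matrix(0, 40, 40), model), "mask")
})

test_that("degenerate constant regions yield the guarded zero vector", {
  model <- local_model()
  img <- matrix(0.5, 30, 30)
  mask <- matrix(1, 30, 30)
  expect_warning(f <- ica_feature_vector(img, mask, model), "degenerate")
  expect_true(all(f == 0))
})
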