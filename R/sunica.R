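# Sparse-filter saliency features. Small patches are sampled from images,
# reduced by PCA (excluding the top, DC/luminance-dominated components),
# unmixed into statistically independent sparse filters by fixed-point ICA,
# and each filter's response distribution is modelled by a zero-mean
# generalized Gaussian P(f_i) ~ exp(-|f_i/s_i|^beta_i). Bottom-up saliency
# of a pixel is the rarity of its joint response, P(F)^-1 with
# P(F) = prod_i P(f_i); it is computed and pooled in the log domain since
# P(F)^-1 overflows for rare patches.

#' Patch sampling configuration
#'
#' @param patch_size odd patch side length in pixels (>= 3)
#' @param stride sampling stride in pixels (>= 1)
#' @param max_patches cap on the number of sampled patches
#' @param seed integer seed controlling patch subsampling
#' @return an object of class \code{patch_config}
#' @export
patch_config <- function(patch_size = 11L, stride = 4L,
                         max_patches = 50000L, seed = 0L) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L)
    sq_stop("patch_size must be odd and >= 3")
  if (stride < 1L) sq_stop("stride must be >= 1")
  structure(list(patch_size = patch_size, stride = as.integer(stride),
                 max_patches = as.integer(max_patches),
                 seed = as.integer(seed)),
            class = "patch_config")
}

# linear indices of one patch, row-major vectorization (row varies last)
patch_offsets <- function(patch_size, nr) {
  r <- seq_len(patch_size) - 1L
  as.vector(t(outer(r, r * nr, "+")))   # row-major: row index fastest outer dim
}

# patch matrix for given top-left corners (vectors r0, c0; 1-based)
patches_at <- function(img, r0, c0, patch_size) {
  nr <- nrow(img)
  base <- (c0 - 1L) * nr + r0
  off <- patch_offsets(patch_size, nr)
  m <- matrix(img[outer(base, off, "+")], nrow = length(base))
  m
}

#' Extract mean-subtracted patches from images
#'
#' Patches are vectorized row-major and each patch's own mean is subtracted
#' (the single-channel analogue of colour-channel mean subtraction; B-mode
#' ultrasound has luminance only). At most \code{cfg$max_patches} patches
#' are kept, subsampled deterministically with \code{cfg$seed}.
#'
#' @param imgs a single image matrix or a list of image matrices
#' @param cfg a \code{\link{patch_config}}
#' @return numeric matrix, one patch per row
#' @export
extract_patches <- function(imgs, cfg = patch_config()) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  ps <- cfg$patch_size
  mats <- lapply(imgs, function(img) {
    assert_image(img)
    if (nrow(img) < ps || ncol(img) < ps)
      sq_stop("image (", nrow(img), "x", ncol(img),
              ") is smaller than patch_size ", ps)
    r0 <- seq(1L, nrow(img) - ps + 1L, by = cfg$stride)
    c0 <- seq(1L, ncol(img) - ps + 1L, by = cfg$stride)
    g <- expand.grid(r0 = r0, c0 = c0)
    patches_at(img, g$r0, g$c0, ps)
  })
  X <- do.call(rbind, mats)
  if (nrow(X) > cfg$max_patches) {
    keep <- with_seed(cfg$seed, sample.int(nrow(X), cfg$max_patches))
    X <- X[sort(keep), , drop = FALSE]
  }
  X - rowMeans(X)
}

# moment-matched zero-mean generalized Gaussian fit: kurtosis -> shape beta,
# variance -> scale s. beta clamped to [0.3, 4].
ggd_kurtosis <- function(beta) {
  exp(lgamma(5 / beta) + lgamma(1 / beta) - 2 * lgamma(3 / beta))
}

fit_ggd <- function(x, beta_range = c(0.3, 4)) {
  v <- mean(x^2)
  if (v <= 0) return(list(beta = 2, scale = 1e-12))
  kur <- mean(x^4) / v^2
  lo <- beta_range[1]; hi <- beta_range[2]
  beta <- if (kur >= ggd_kurtosis(lo)) lo
          else if (kur <= ggd_kurtosis(hi)) hi
          else stats::uniroot(function(b) ggd_kurtosis(b) - kur,
                              lower = lo, upper = hi, tol = 1e-9)$root
  s <- sqrt(v * exp(lgamma(1 / beta) - lgamma(3 / beta)))
  list(beta = beta, scale = s)
}

# -log P(x) under the GGD, including the normalizing constant
ggd_neglogpdf <- function(x, beta, s) {
  abs(x / s)^beta - (log(beta) - log(2 * s) - lgamma(1 / beta))
}

# symmetric fixed-point ICA (tanh contrast) on whitened data Z (d x N)
fastica_symm <- function(Z, k, seed, max_iter = 1000L, tol = 1e-5) {
  d <- nrow(Z); N <- ncol(Z)
  W <- with_seed(seed, matrix(stats::rnorm(k * d), k, d))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                       length(e$values)) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(U)
    W1 <- (G %*% t(Z)) / N - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) return(list(W = W, iter = it))
  }
  sq_stop("ICA did not converge within ", max_iter, " iterations")
}

#' Fit the sparse-filter saliency model
#'
#' PCA is run on the (grand-mean-centred) patch matrix; the
#' \code{drop_top} highest-eigenvalue components (dominated by luminance /
#' low-frequency structure) are excluded, then components are retained
#' until 95% of the remaining variance is reached, capped at \code{k}.
#' Fixed-point ICA in the whitened reduced space yields unit-norm sparse
#' filters, and each filter's training responses are fit by a zero-mean
#' generalized Gaussian via moment matching (kurtosis gives the shape,
#' variance the scale).
#'
#' @param patches patch matrix from \code{\link{extract_patches}}
#' @param k number of ICA filters requested (the fitted count may be lower
#'   if fewer components carry variance)
#' @param drop_top number of leading principal components to exclude
#' @param seed integer seed for the ICA initialization
#' @return an object of class \code{ica_model} with fields
#'   \code{mean_patch}, \code{proj} (k x patch_dim response projection),
#'   \code{ica_filters}, \code{pca_basis}, \code{kept_indices},
#'   \code{ggd_shape}, \code{ggd_scale}, \code{patch_size}
#' @export
fit_ica_model <- function(patches, k = 32L, drop_top = 1L, seed = 0L) {
  if (!is.matrix(patches)) sq_stop("patches must be a matrix")
  k <- as.integer(k)
  if (nrow(patches) < 10L * k)
    sq_stop("need at least 10*k patches (", 10L * k, "), got ", nrow(patches))
  pd <- ncol(patches)
  mu <- colMeans(patches)
  Xc <- sweep(patches, 2L, mu)
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-10)
  # per-patch mean subtraction removes exactly one dimension by design;
  # only warn for deficiency beyond that
  if (length(pos) < pd - 1L)
    warning("rank-deficient patch matrix: keeping ", length(pos),
            " of ", pd, " dimensions")
  avail <- setdiff(pos, seq_len(drop_top))
  if (length(avail) < 1L) sq_stop("no components left after drop_top")
  ev <- e$values[avail]
  frac <- cumsum(ev) / sum(ev)
  d95 <- which(frac >= 0.95)[1L]
  d_kept <- min(max(d95, 1L), k, length(avail))
  kept <- avail[seq_len(d_kept)]
  basis <- t(e$vectors[, kept, drop = FALSE])          # d_kept x patch_dim
  white <- basis / sqrt(e$values[kept])                # whitening rows
  k_eff <- min(k, d_kept)
  Z <- white %*% t(Xc)                                 # d_kept x N
  ica <- fastica_symm(Z, k_eff, seed)
  W <- ica$W                                           # k_eff x d_kept, rows unit
  proj <- W %*% white                                  # k_eff x patch_dim
  resp <- W %*% Z                                      # training responses
  fits <- apply(resp, 1L, fit_ggd)
  structure(list(
    mean_patch = mu,
    pca_basis = basis,
    kept_indices = kept,
    ica_filters = W,
    proj = proj,
    ggd_shape = vapply(fits, `[[`, 0, "beta"),
    ggd_scale = vapply(fits, `[[`, 0, "scale"),
    k = k_eff,
    patch_size = as.integer(round(sqrt(pd))),
    ica_iterations = ica$iter
  ), class = "ica_model")
}

# responses (k x n_centres) of the model's filters at given patch centres
model_responses <- function(img, model, centers_r, centers_c) {
  ps <- model$patch_size
  h <- (ps - 1L) %/% 2L
  X <- patches_at(img, centers_r - h, centers_c - h, ps)
  X <- X - rowMeans(X)
  X <- sweep(X, 2L, model$mean_patch)
  model$proj %*% t(X)
}

# raw (unshifted) log-saliency -sum_i log P(f_i) per centre
neglog_pf <- function(resp, model) {
  out <- 0
  for (i in seq_len(model$k))
    out <- out + ggd_neglogpdf(resp[i, ], model$ggd_shape[i],
                               model$ggd_scale[i])
  out
}

# log-saliency above its theoretical minimum (attained at zero response,
# the GGD mode): sum_i |f_i/s_i|^beta_i. Local to the responses, zero for
# a degenerate region.
excess_logsal <- function(resp, model) {
  out <- 0
  for (i in seq_len(model$k))
    out <- out + abs(resp[i, ] / model$ggd_scale[i])^model$ggd_shape[i]
  out
}

#' Bottom-up saliency map
#'
#' Saliency of a pixel is the inverse probability of its local filter
#' responses, reported in the log domain: -log P(F) =
#' -sum_i log P(f_i). Border pixels without a full patch take the nearest
#' valid value, and the map is shifted so its minimum is 0.
#'
#' @param img numeric matrix in [0, 1], at least patch_size in both
#'   dimensions
#' @param model an \code{\link{fit_ica_model}} result
#' @return non-negative numeric matrix of the same shape as \code{img}
#' @export
saliency_map <- function(img, model) {
  assert_image(img)
  ps <- model$patch_size
  if (nrow(img) < ps || ncol(img) < ps)
    sq_stop("image is smaller than the model patch size ", ps)
  h <- (ps - 1L) %/% 2L
  rr <- (h + 1L):(nrow(img) - h)
  cc <- (h + 1L):(ncol(img) - h)
  g <- expand.grid(r = rr, c = cc)
  resp <- model_responses(img, model, g$r, g$c)
  val <- matrix(neglog_pf(resp, model), length(rr), length(cc))
  full <- matrix(0, nrow(img), ncol(img))
  ri <- pmin(pmax(seq_len(nrow(img)), h + 1L), nrow(img) - h) - h
  ci <- pmin(pmax(seq_len(ncol(img)), h + 1L), ncol(img) - h) - h
  full[] <- val[ri, ci]
  full - min(full)
}

#' Lesion-region saliency feature vector
#'
#' Builds f1: the mean absolute response of each filter over patch centres
#' inside the mask, plus the mean log-saliency (measured above its
#' theoretical minimum at zero response, so the entry depends only on the
#' masked region) over those centres, then L2-normalizes. Deterministic given (img, mask, model). For a degenerate
#' (constant) region all responses vanish and the zero vector is returned
#' with a warning.
#'
#' @param img numeric matrix in [0, 1]
#' @param mask 0/1 lesion mask, non-empty
#' @param model an \code{\link{fit_ica_model}} result
#' @return numeric vector of length \code{model$k + 1}, unit L2 norm (or
#'   all zeros for a degenerate region)
#' @export
ica_feature_vector <- function(img, mask, model) {
  assert_image(img)
  assert_mask(mask, img)
  if (sum(mask) == 0)
    sq_stop("empty mask: pool over the whole image instead ",
            "(pass mask = matrix(1, nrow(img), ncol(img)))")
  ps <- model$patch_size
  h <- (ps - 1L) %/% 2L
  idx <- which(mask > 0, arr.ind = TRUE)
  # clamp centres so the patch fits; keeps lesions near the border usable
  r <- pmin(pmax(idx[, 1], h + 1L), nrow(img) - h)
  c <- pmin(pmax(idx[, 2], h + 1L), ncol(img) - h)
  keep <- !duplicated(cbind(r, c))
  X <- patches_at(img, r[keep] - h, c[keep] - h, ps)
  Xz <- X - rowMeans(X)
  if (max(abs(Xz)) == 0) {
    # constant region: after per-patch mean subtraction every patch is
    # zero, so the responses carry no region information
    warning("degenerate region: zero responses, returning the zero vector")
    return(rep(0, model$k + 1L))
  }
  resp <- model$proj %*% t(sweep(Xz, 2L, model$mean_patch))
  f1 <- c(rowMeans(abs(resp)), mean(excess_logsal(resp, model)))
  nrm <- sqrt(sum(f1^2))
  if (nrm == 0) {
    warning("degenerate region: zero responses, returning the zero vector")
    return(f1)
  }
  f1 / nrm
}
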