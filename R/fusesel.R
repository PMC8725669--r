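# Serial feature fusion, the pluggable deep-feature backend contract with
# a deterministic stub, and lasso-regularized binomial feature
# selection/classification.

#' Fit min-max scaling parameters for serial fusion
#'
#' Computes per-column min/max of the two feature blocks on the training
#' split; the parameters are stored and reused at test time so both blocks
#' land on a comparable [0, 1] scale before concatenation.
#'
#' @param f1 matrix (samples x n) of the first feature block
#' @param f2 matrix (samples x m) of the second block (may have 0 columns)
#' @return an object of class \code{fuse_scaler}
#' @export
fuse_scaler <- function(f1, f2) {
  f1 <- as_feature_matrix(f1); f2 <- as_feature_matrix(f2)
  structure(list(min1 = apply2_min(f1), max1 = apply2_max(f1),
                 min2 = apply2_min(f2), max2 = apply2_max(f2),
                 n = ncol(f1), m = ncol(f2)),
            class = "fuse_scaler")
}

as_feature_matrix <- function(x) {
  if (is.null(x)) return(matrix(0, 1, 0))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (any(!is.finite(x))) sq_stop("feature values must be finite")
  x
}

apply2_min <- function(x) if (ncol(x)) apply(x, 2L, min) else numeric(0)
apply2_max <- function(x) if (ncol(x)) apply(x, 2L, max) else numeric(0)

scale_block <- function(x, lo, hi) {
  if (!ncol(x)) return(x)
  rng <- hi - lo
  rng[rng == 0] <- 1                      # constant column maps to 0
  sweep(sweep(x, 2L, lo), 2L, rng, "/")
}

#' Serial feature fusion
#'
#' Concatenates the two blocks, alpha = (f1 || f2), of dimension n + m,
#' after min-max scaling each block with training-split statistics. With
#' \code{scaler = NULL} the inputs themselves are treated as the training
#' split and the fitted scaler is attached to the result.
#'
#' @param f1 vector or matrix (samples x n); may be empty on one side only
#' @param f2 vector or matrix (samples x m)
#' @param scaler a \code{\link{fuse_scaler}}, or NULL to fit from the inputs
#' @return fused matrix (samples x (n+m)) with attributes \code{n},
#'   \code{m} and \code{scaler}
#' @export
serial_fuse <- function(f1, f2, scaler = NULL) {
  single <- is.vector(f1) || is.vector(f2)
  f1 <- as_feature_matrix(f1); f2 <- as_feature_matrix(f2)
  if (ncol(f1) == 0L && ncol(f2) == 0L)
    sq_stop("both feature blocks are empty")
  if (ncol(f1) == 0L) f1 <- matrix(0, nrow(f2), 0L)
  if (ncol(f2) == 0L) f2 <- matrix(0, nrow(f1), 0L)
  if (nrow(f1) > 1L || nrow(f2) > 1L) {
    if (ncol(f1) && ncol(f2) && nrow(f1) != nrow(f2))
      sq_stop("f1 and f2 must have the same number of samples")
  }
  if (is.null(scaler)) scaler <- fuse_scaler(f1, f2)
  if (ncol(f1) != scaler$n || ncol(f2) != scaler$m)
    sq_stop("block dimensions do not match the scaler (n=", scaler$n,
            ", m=", scaler$m, ")")
  a <- cbind(scale_block(f1, scaler$min1, scaler$max1),
             scale_block(f2, scaler$min2, scaler$max2))
  structure(a, n = scaler$n, m = scaler$m, scaler = scaler,
            class = c("fused_features", class(a)))
}

#' Recover the unscaled feature blocks from a fused matrix
#'
#' Inverts \code{\link{serial_fuse}} exactly using the stored scaling
#' parameters.
#'
#' @param alpha a \code{serial_fuse} result
#' @return list with matrices \code{f1} and \code{f2} in original units
#' @export
unfuse <- function(alpha) {
  sc <- attr(alpha, "scaler")
  if (is.null(sc)) sq_stop("alpha carries no fuse_scaler")
  n <- sc$n; m <- sc$m
  a <- unclass(alpha)
  unscale <- function(x, lo, hi) {
    if (!ncol(x)) return(x)
    rng <- hi - lo; rng[rng == 0] <- 1
    sweep(sweep(x, 2L, rng, "*"), 2L, lo, "+")
  }
  list(f1 = unscale(a[, seq_len(n), drop = FALSE], sc$min1, sc$max1),
       f2 = unscale(a[, n + seq_len(m), drop = FALSE], sc$min2, sc$max2))
}

# ---- deterministic deep-feature stub ------------------------------------

# Hu invariant-moment magnitudes of a masked intensity image
hu_moments <- function(img, mask) {
  w <- img * mask
  s <- sum(w)
  if (s == 0) return(rep(0, 7))
  nr <- nrow(img); nc <- ncol(img)
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), nc), nr, nc)
  xb <- sum(w * x) / s; yb <- sum(w * y) / s
  mu <- function(p, q) sum(w * (x - xb)^p * (y - yb)^q)
  eta <- function(p, q) mu(p, q) / s^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
  log1p(abs(h) * 1e6)      # magnitudes on a tame scale
}

#' Deterministic deep-feature backend stub
#'
#' Stands in for a learned feature extractor while exercising the same
#' contract any real backend must satisfy: (image, mask) -> fixed-length
#' numeric vector, identical output for identical inputs. The features are
#' a 16-bin masked-region intensity histogram, seven invariant-moment
#' magnitudes, and a seeded random projection of those 23 values padded or
#' truncated to \code{dim}.
#'
#' @param img numeric matrix in [0, 1]
#' @param mask 0/1 mask; an empty mask falls back to whole-image pooling
#'   with a warning
#' @param dim output dimension (>= 1)
#' @param seed integer seed of the padding projection
#' @return numeric vector of length \code{dim}
#' @export
deep_feature_stub <- function(img, mask, dim = 32L, seed = 0L) {
  assert_image(img)
  assert_mask(mask, img)
  dim <- as.integer(dim)
  if (dim < 1L) sq_stop("dim must be >= 1")
  if (sum(mask) == 0) {
    warning("empty mask: pooling over the whole image")
    mask <- matrix(1, nrow(img), ncol(img))
  }
  v <- img[mask > 0]
  hist16 <- tabulate(pmin(16L, floor(v * 16) + 1L), nbins = 16L) / length(v)
  base <- c(hist16, hu_moments(img, mask))
  if (dim <= length(base)) return(base[seq_len(dim)])
  P <- with_seed(seed,
    matrix(stats::rnorm((dim - length(base)) * length(base)),
           dim - length(base), length(base)))
  c(base, as.vector(P %*% base) / sqrt(length(base)))
}

# ---- lasso-regularized binomial classification --------------------------

#' L1-penalized logistic regression with internal lambda selection
#'
#' Fits the coordinate-descent lasso path for a binomial model over
#' \code{lambda_grid} (by default 50 log-spaced values spanning four
#' decades below the smallest all-zero lambda), selects lambda by seeded
#' k-fold cross-validated deviance, and reports the selected (non-zero)
#' features. Used both for feature selection and as a classifier.
#'
#' @param features numeric matrix (samples x features)
#' @param labels two-class factor or vector; the second sorted level is
#'   modelled as the "success" class
#' @param lambda_grid optional decreasing lambda sequence
#' @param folds internal CV fold count (default 5)
#' @param seed integer seed for the internal fold assignment
#' @return an object of class \code{lasso_model} with \code{coefficients},
#'   \code{intercept}, \code{lambda}, \code{selected}, \code{levels}
#' @export
lasso_fit <- function(features, labels, lambda_grid = NULL, folds = 5L,
                      seed = 0L) {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L)
    sq_stop("labels must contain exactly two classes, got ", nlevels(y))
  if (min(table(y)) < 2L) sq_stop("need at least 2 samples per class")
  foldid <- with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      f[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(features, y, family = "binomial",
                          lambda = lambda_grid, nlambda = 50L,
                          lambda.min.ratio = 1e-4, foldid = foldid)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  beta <- co[-1L, 1L]
  sel <- which(beta != 0)
  if (length(sel) == 0L)
    warning("all coefficients zero at the selected lambda; intercept-only model")
  structure(list(coefficients = beta, intercept = co[1L, 1L],
                 lambda = cv$lambda.min, selected = sel,
                 levels = levels(y), glmnet_cv = cv),
            class = "lasso_model")
}

#' Predict from a lasso model
#'
#' @param object a \code{\link{lasso_fit}} result
#' @param newx feature matrix
#' @param type "class" (default; probability thresholded at 0.5) or "prob"
#' @param ... unused
#' @return factor of predicted classes, or numeric success probabilities
#' @export
predict.lasso_model <- function(object, newx, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  eta <- drop(newx %*% object$coefficients) + object$intercept
  p <- 1 / (1 + exp(-eta))
  if (type == "prob") return(p)
  factor(object$levels[(p >= 0.5) + 1L], levels = object$levels)
}
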