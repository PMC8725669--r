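# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive between-class-variance maximization over all threshold
# placements on the 256-bin histogram (n = 1 or 2).
brute_otsu <- function(img, n) {
  L <- 256L
  b <- pmin(L - 1L, floor(as.vector(img) * L))
  cnt <- tabulate(b + 1L, nbins = L)
  N <- length(b)
  cen <- (seq_len(L) - 0.5) / L
  cw <- cumsum(cnt) / N
  cm <- cumsum(cnt * cen) / N
  segf <- function(i, j) {
    W <- cw[j] - if (i > 1L) cw[i - 1L] else 0
    M <- cm[j] - if (i > 1L) cm[i - 1L] else 0
    if (W > 0) M^2 / W else 0
  }
  best <- -Inf; bt <- NULL
  if (n == 1L) {
    for (t1 in 1:(L - 1L)) {
      v <- segf(1L, t1) + segf(t1 + 1L, L)
      if (v > best) { best <- v; bt <- t1 / L }
    }
  } else {
    for (t1 in 1:(L - 2L)) {
      s1 <- segf(1L, t1)
      for (t2 in (t1 + 1L):(L - 1L)) {
        v <- s1 + segf(t1 + 1L, t2) + segf(t2 + 1L, L)
        if (v > best) { best <- v; bt <- c(t1, t2) / L }
      }
    }
  }
  bt
}

# Zero-mean generalized Gaussian sampler: |X|^beta ~ Gamma(1/beta) * s^beta
rggd <- function(n, beta, s = 1) {
  g <- stats::rgamma(n, shape = 1 / beta)
  s * g^(1 / beta) * sample(c(-1, 1), n, replace = TRUE)
}

# Direct two-rater kappa from label vectors (not from a 2x2 matrix)
kappa_from_labels <- function(actual, pred) {
  lv <- union(unique(actual), unique(pred))
  po <- mean(actual == pred)
  pe <- sum(vapply(lv, function(l) mean(actual == l) * mean(pred == l), 0))
  (po - pe) / (1 - pe)
}

# label vectors realizing a 2x2 confusion matrix (rows actual B,M)
labels_from_cm <- function(bb, bm, mb, mm) {
  list(actual = c(rep("B", bb + bm), rep("M", mb + mm)),
       pred = c(rep("B", bb), rep("M", bm), rep("B", mb), rep("M", mm)))
}

# speckle phantom helper with few knobs for the segmentation tests
simple_phantom <- function(seed, label = "B", ...) {
  make_phantom(phantom_spec(class_label = label, seed = seed, ...))
}
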