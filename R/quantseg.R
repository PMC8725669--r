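# Multilevel Otsu thresholding, quantization to n+1 discrete levels, and
# tumour-level lesion selection. The quantization path refines a coarse
# segmentation when it looks untrustworthy, or acts as a standalone
# baseline segmenter for hypoechoic (darker-than-background) lesions.

OTSU_BINS <- 256L

#' Region selection criteria
#'
#' @param min_area minimum component area in pixels (>= 1)
#' @param circularity_range admissible [low, high] circularity, 4*pi*A/P^2
#' @param roundness_range admissible [low, high] roundness,
#'   4*A/(pi*major_axis^2)
#' @param overlap_weight weight of coarse-mask overlap in component scoring
#' @return an object of class \code{region_criteria}
#' @export
region_criteria <- function(min_area = 25L,
                            circularity_range = c(0, 1),
                            roundness_range = c(0, 1),
                            overlap_weight = 0.5) {
  if (min_area < 1) sq_stop("min_area must be >= 1")
  if (overlap_weight < 0) sq_stop("overlap_weight must be >= 0")
  structure(list(min_area = as.integer(min_area),
                 circularity_range = circularity_range,
                 roundness_range = roundness_range,
                 overlap_weight = overlap_weight),
            class = "region_criteria")
}

#' Multilevel Otsu thresholds
#'
#' Returns the n thresholds that maximize the between-class intensity
#' variance of the image histogram (256 bins on [0, 1]), i.e. the weighted
#' sum of squared class means. The optimum is found exactly by dynamic
#' programming over occupied histogram bins, which is equivalent to
#' exhaustive search over all threshold placements. Ties are broken toward
#' the lexicographically smallest threshold set. Thresholds are bin
#' boundaries, strictly ascending, in (0, 1).
#'
#' @param img numeric matrix in [0, 1]
#' @param n number of thresholds (>= 1); the quantized image has n+1 levels
#' @return numeric vector of n ascending thresholds
#' @export
otsu_thresholds <- function(img, n = 3L) {
  assert_image(img)
  n <- as.integer(n)
  if (n < 1L) sq_stop("n must be >= 1")
  nd <- length(unique(as.vector(img)))
  if (nd < n + 1L)
    sq_stop("degenerate input: image has only ", nd,
            " distinct intensity values, need at least ", n + 1L)
  L <- OTSU_BINS
  b <- pmin(L - 1L, floor(as.vector(img) * L))        # 0-based bin
  counts <- tabulate(b + 1L, nbins = L)
  occ <- which(counts > 0L)                            # 1-based occupied bins
  m <- length(occ)
  if (m < n + 1L)
    sq_stop("degenerate input: image occupies only ", m,
            " histogram bins, need at least ", n + 1L)
  w <- counts[occ] / length(b)
  cen <- (occ - 0.5) / L                               # bin centres
  cw <- c(0, cumsum(w)); cm <- c(0, cumsum(w * cen))
  # seg(i, j): weight * mean^2 of occupied bins i..j
  seg <- function(i, j) {
    W <- cw[j + 1L] - cw[i]
    M <- cm[j + 1L] - cm[i]
    ifelse(W > 0, M^2 / W, 0)
  }
  k <- n + 1L
  # f[c, j]: best objective for occupied bins 1..j split into c classes
  f <- matrix(-Inf, k, m)
  cut <- matrix(NA_integer_, k, m)  # last class starts at occ index cut+1
  f[1L, ] <- seg(1L, seq_len(m))
  if (k > 1L) {
    for (cc in 2L:k) {
      for (j in cc:m) {
        i <- (cc - 1L):(j - 1L)                        # last split position
        v <- f[cc - 1L, i] + seg(i + 1L, j)
        best <- which.max(v)                           # first max: smallest i
        f[cc, j] <- v[best]
        cut[cc, j] <- i[best]
      }
    }
  }
  splits <- integer(n)                                 # occ indices ending a class
  j <- m
  for (cc in k:2L) {
    splits[cc - 1L] <- cut[cc, j]
    j <- cut[cc, j]
  }
  occ[splits] / L                                      # upper bin edges
}

#' Quantize an image with a threshold vector
#'
#' Labels each pixel by the half-open binning [0, t1), [t1, t2), ...,
#' [tn, 1]: label(p) = number of thresholds <= img(p), an integer in 0..n.
#'
#' @param img numeric matrix in [0, 1]
#' @param t ascending threshold vector
#' @return integer matrix of labels in 0..length(t)
#' @export
quantize <- function(img, t) {
  assert_image(img)
  if (is.unsorted(t, strictly = TRUE)) sq_stop("thresholds must be strictly ascending")
  matrix(findInterval(as.vector(img), t), nrow(img), ncol(img))
}

# 8-connected component labelling by iterated minimum-label propagation
# (vectorized over the whole lattice; converges in O(component diameter)
# sweeps, which is small for compact lesions).
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- mask > 0
  lab[fg] <- seq_len(sum(fg))
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    out[r1, c1] <- m[r1 - dr, c1 - dc, drop = FALSE]
    out
  }
  labf <- lab; labf[!fg] <- Inf
  repeat {
    nb <- labf
    for (d in list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1),
                   c(0,1), c(1,-1), c(1,0), c(1,1)))
      nb <- pmin(nb, shift(labf, d[1], d[2]))
    nb[!fg] <- Inf
    if (all(nb[fg] == labf[fg])) break
    labf <- nb
  }
  lab[fg] <- match(labf[fg], sort(unique(labf[fg])))
  lab
}

# fill holes: background 4-connected to the border stays background,
# enclosed background becomes foreground
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- mask == 0
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- bg[1, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, nc] <- reach[, nc] | bg[, nc]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  out <- mask
  out[bg & !reach] <- 1
  out
}

# Perimeter of a single 8-connected region by Moore boundary tracing.
# Chain steps are weighted 0.980 (isothetic) / 1.406 (diagonal), the
# Vossepoel-Smeulders correction that removes most of the staircase bias
# of raw chain length on digital curves.
region_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0)
  if (length(fg) == 0L) return(0)
  if (length(fg) == 1L) return(4 * 0.980)
  start_c <- (fg[1L] - 1L) %/% nr + 1L
  start_r <- (fg[1L] - 1L) %% nr + 1L
  # Moore neighbourhood in clockwise order starting from west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    mask[r, c] > 0
  per <- 0
  cr <- start_r; cc <- start_c
  backtrack <- 1L                        # came from the west
  first_step <- TRUE
  repeat {
    found <- FALSE
    d <- backtrack
    for (s in seq_len(8L)) {
      d <- d %% 8L + 1L
      rr <- cr + dr[d]; ccn <- cc + dc[d]
      if (inside(rr, ccn)) {
        per <- per + if (dr[d] != 0L && dc[d] != 0L) 1.406 else 0.980
        # new backtrack: direction pointing back toward the previous pixel,
        # advanced so the scan resumes just after it
        backtrack <- (d + 3L) %% 8L + 1L
        cr <- rr; cc <- ccn
        found <- TRUE
        break
      }
    }
    if (!found) return(4 * 0.980)        # isolated pixel
    if (!first_step && cr == start_r && cc == start_c) break
    first_step <- FALSE
    if (per > 16 * (nr + nc)) break      # safety against pathological loops
  }
  per
}

# shape descriptors of a single-region 0/1 mask
region_shape <- function(mask) {
  A <- sum(mask)
  if (A == 0) return(list(area = 0, circularity = 0, roundness = 0,
                          solidity = 0))
  P <- region_perimeter(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  mu <- colMeans(idx)
  if (A > 2) {
    S <- stats::cov(idx) * (A - 1) / A          # population second moments
    # rasterization floor: a 1-pixel-wide region still has unit extent
    lam <- max(eigen(S + diag(1 / 12, 2), symmetric = TRUE,
                     only.values = TRUE)$values)
  } else lam <- 1 / 12
  major <- 4 * sqrt(lam)
  circ <- if (P > 0) 4 * pi * A / P^2 else 0
  rnd <- 4 * A / (pi * major^2)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  sol <- if (hull_area > 0) min(1, A / hull_area) else 1
  list(area = A, circularity = min(circ, 1), roundness = min(rnd, 1),
       solidity = sol)
}

#' Select the lesion region from a quantized level map
#'
#' Picks the tumour level (by default the level with the lowest mean
#' intensity, matching the hypoechoic appearance of breast lesions; with a
#' coarse mask, the level overlapping it most), extracts its 8-connected
#' components, scores them by area, circularity, roundness and (when a
#' coarse mask is supplied) overlap, and returns the best component with
#' holes filled. Returns an all-zero mask if no component reaches
#' \code{crit$min_area}.
#'
#' @param levels integer label matrix from \code{\link{quantize}}
#' @param img the source image (for level mean intensities)
#' @param coarse optional coarse 0/1 mask steering level choice and scoring
#' @param crit a \code{\link{region_criteria}}
#' @param tumor_side "dark" (hypoechoic, default) or "bright"
#' @return 0/1 mask of the selected lesion
#' @export
select_lesion <- function(levels, img, coarse = NULL,
                          crit = region_criteria(),
                          tumor_side = c("dark", "bright")) {
  assert_image(img)
  assert_same_shape(levels, img, "levels and img")
  tumor_side <- match.arg(tumor_side)
  empty <- matrix(0, nrow(img), ncol(img))
  lv <- sort(unique(as.vector(levels)))
  if (length(lv) == 0L) { warning("empty level map"); return(empty) }
  if (!is.null(coarse)) {
    assert_mask(coarse, img, "coarse")
    if (sum(coarse) == 0) coarse <- NULL
  }
  if (is.null(coarse)) {
    mean_int <- vapply(lv, function(l) mean(img[levels == l]), 0)
    tumor <- lv[if (tumor_side == "dark") which.min(mean_int)
                else which.max(mean_int)]
  } else {
    ov <- vapply(lv, function(l) {
      inlev <- levels == l
      sum(inlev & coarse > 0) / sum(inlev)
    }, 0)
    tumor <- lv[which.max(ov)]
  }
  lab <- label_components_8((levels == tumor) * 1)
  ncomp <- max(lab)
  if (ncomp == 0L) { warning("tumor level has no pixels"); return(empty) }
  stats_list <- lapply(seq_len(ncomp), function(i) region_shape((lab == i) * 1))
  areas <- vapply(stats_list, `[[`, 0, "area")
  keep <- which(
    areas >= crit$min_area &
    vapply(stats_list, `[[`, 0, "circularity") >= crit$circularity_range[1] &
    vapply(stats_list, `[[`, 0, "circularity") <= crit$circularity_range[2] &
    vapply(stats_list, `[[`, 0, "roundness") >= crit$roundness_range[1] &
    vapply(stats_list, `[[`, 0, "roundness") <= crit$roundness_range[2])
  if (length(keep) == 0L) {
    warning("no component passes the region criteria")
    return(empty)
  }
  amax <- max(areas[keep])
  score <- vapply(keep, function(i) {
    s <- stats_list[[i]]
    comp <- lab == i
    if (!is.null(coarse)) {
      jac <- sum(comp & coarse > 0) / sum(comp | coarse > 0)
      crit$overlap_weight * jac + 0.25 * s$circularity + 0.25 * s$area / amax
    } else {
      dark <- mean(img[comp])
      if (tumor_side == "bright") dark <- 1 - dark
      0.5 * s$area / amax + 0.25 * s$circularity + 0.25 * (1 - dark)
    }
  }, 0)
  best <- keep[which.max(score)]
  fill_holes((lab == best) * 1)
}

#' Trigger rule for segmentation refinement
#'
#' A coarse mask "needs reconsideration" when it is empty, smaller than
#' \code{min_area_frac} of the image, or has solidity below
#' \code{solidity_floor}.
#'
#' @param min_area_frac minimum credible mask area as a fraction of image area
#' @param solidity_floor minimum credible solidity (area / convex hull area)
#' @return an object of class \code{trigger_rule}
#' @export
trigger_rule <- function(min_area_frac = 0.001, solidity_floor = 0.5) {
  structure(list(min_area_frac = min_area_frac,
                 solidity_floor = solidity_floor), class = "trigger_rule")
}

#' Refine a coarse segmentation via quantization
#'
#' If the trigger fires, the quantization path (mild Gaussian smoothing to
#' suppress speckle, then \code{otsu_thresholds} -> \code{quantize} ->
#' \code{select_lesion}) replaces the coarse mask; otherwise the coarse
#' mask passes through unchanged. The decision is recorded in the
#' \code{"refined"} and \code{"reason"} attributes of the returned mask.
#' A degenerate-input failure of Otsu thresholding falls back to the
#' unchanged coarse mask.
#'
#' @param img numeric matrix in [0, 1]
#' @param coarse coarse 0/1 mask from any segmentation backend
#' @param n number of Otsu thresholds (n+1 quantization levels), default 3
#' @param crit a \code{\link{region_criteria}}
#' @param trigger a \code{\link{trigger_rule}}
#' @param smooth_sigma pre-quantization smoothing sigma in pixels
#'   (0 disables)
#' @param tumor_side passed to \code{\link{select_lesion}}
#' @return 0/1 mask with attributes \code{refined} (logical) and
#'   \code{reason} (character)
#' @export
refine_segmentation <- function(img, coarse, n = 3L,
                                crit = region_criteria(),
                                trigger = trigger_rule(),
                                smooth_sigma = 1.5,
                                tumor_side = "dark") {
  assert_image(img)
  assert_mask(coarse, img, "coarse")
  area <- sum(coarse)
  reason <- NULL
  if (area == 0) reason <- "empty coarse mask"
  else if (area < trigger$min_area_frac * length(img))
    reason <- "coarse area below trigger threshold"
  else if (region_shape(coarse)$solidity < trigger$solidity_floor)
    reason <- "coarse solidity below trigger floor"
  if (is.null(reason)) {
    out <- coarse
    attr(out, "refined") <- FALSE
    attr(out, "reason") <- "pass-through"
    return(out)
  }
  work <- if (smooth_sigma > 0) gaussian_smooth(img, smooth_sigma) else img
  t <- tryCatch(otsu_thresholds(work, n), error = function(e) NULL)
  if (is.null(t)) {
    out <- coarse
    attr(out, "refined") <- FALSE
    attr(out, "reason") <- paste0(reason, "; quantization degenerate, kept coarse")
    return(out)
  }
  lev <- quantize(work, t)
  out <- select_lesion(lev, work, coarse = if (area > 0) coarse else NULL,
                       crit = crit, tumor_side = tumor_side)
  attr(out, "refined") <- TRUE
  attr(out, "reason") <- reason
  out
}
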