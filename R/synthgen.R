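# Seeded generator of ultrasound-like speckle phantoms: one hypoechoic
# lesion per image on a brighter background, multiplied by gamma-distributed
# speckle (the fully developed speckle approximation for B-mode images).
# Benign lesions are smooth ovals; malignant lesions are irregular,
# spiculated and more strongly hypoechoic ("denser").

#' Phantom specification
#'
#' @param shape image shape (rows, cols)
#' @param class_label "B" (benign) or "M" (malignant)
#' @param lesion_center fractional (row, col) centre coordinates
#' @param lesion_radius lesion semi-major axis as a fraction of the
#'   smaller image dimension, in (0, 0.5)
#' @param irregularity boundary perturbation amplitude in [0, 1]; low for
#'   benign, high for malignant
#' @param lesion_intensity_offset additive lesion intensity (negative:
#'   hypoechoic)
#' @param speckle_looks gamma-speckle shape parameter (>= 1); noise
#'   variance shrinks as looks grow
#' @param background_level background intensity in [0, 1]
#' @param axis_ratio minor/major axis ratio of the base ellipse
#' @param seed integer; fully determines the sample
#' @return an object of class \code{phantom_spec}
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         class_label = c("B", "M"),
                         lesion_center = c(0.5, 0.5),
                         lesion_radius = 0.18,
                         irregularity = NULL,
                         lesion_intensity_offset = NULL,
                         speckle_looks = 16L,
                         background_level = 0.55,
                         axis_ratio = 0.85,
                         seed = 0L) {
  class_label <- match.arg(class_label)
  if (is.null(irregularity))
    irregularity <- if (class_label == "B") 0.08 else 0.45
  if (is.null(lesion_intensity_offset))
    lesion_intensity_offset <- if (class_label == "B") -0.22 else -0.38
  if (lesion_radius <= 0 || lesion_radius >= 0.5)
    sq_stop("lesion_radius must be in (0, 0.5)")
  if (speckle_looks < 1) sq_stop("speckle_looks must be >= 1")
  structure(list(shape = as.integer(shape), class_label = class_label,
                 lesion_center = lesion_center,
                 lesion_radius = lesion_radius,
                 irregularity = irregularity,
                 lesion_intensity_offset = lesion_intensity_offset,
                 speckle_looks = as.integer(speckle_looks),
                 background_level = background_level,
                 axis_ratio = axis_ratio,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one speckle phantom
#'
#' The lesion boundary is a star-convex curve: an ellipse whose radius is
#' modulated by a seeded band-limited perturbation scaled by
#' \code{irregularity}. The mask is the exact rasterization of that curve
#' (pixel centre inside the boundary); the image is the piecewise-constant
#' phantom multiplied by gamma speckle with shape \code{speckle_looks} and
#' unit mean, clipped to [0, 1]. A lesion that would extend outside the
#' image is re-centred with a warning. The same seed gives a bit-identical
#' sample.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @return list with \code{image}, \code{mask}, \code{label}, \code{spec}
#' @export
make_phantom <- function(spec) {
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  a <- spec$lesion_radius * min(nr, nc)          # semi-major axis, pixels
  b <- a * spec$axis_ratio
  rmax <- a * (1 + spec$irregularity)
  ctr <- spec$lesion_center * c(nr - 1L, nc - 1L)
  lo <- rmax + 1; hi_r <- nr - 2 - rmax; hi_c <- nc - 2 - rmax
  if (ctr[1L] < lo || ctr[1L] > hi_r || ctr[2L] < lo || ctr[2L] > hi_c) {
    ctr <- c(min(max(ctr[1L], lo), hi_r), min(max(ctr[2L], lo), hi_c))
    warning("lesion would extend outside the image: re-centred")
  }
  with_seed(spec$seed, {
    orient <- stats::runif(1, 0, pi)
    gr <- matrix(rep(seq_len(nr) - 1, nc), nr, nc) - ctr[1L]
    gc <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - ctr[2L]
    theta <- atan2(gr, gc)
    u <- theta - orient
    r_ell <- a * b / sqrt((b * cos(u))^2 + (a * sin(u))^2)
    pert <- if (spec$irregularity > 0) {
      n_harm <- 7L
      amp <- stats::rnorm(n_harm) / (2:(n_harm + 1L))
      phase <- stats::runif(n_harm, 0, 2 * pi)
      p <- 0
      for (h in seq_len(n_harm))
        p <- p + amp[h] * cos((h + 1L) * theta + phase[h])
      mx <- max(abs(p)); if (mx > 0) p / mx else p
    } else 0
    rho <- r_ell * (1 + spec$irregularity * pert)
    mask <- (sqrt(gr^2 + gc^2) <= rho) * 1
    clean <- matrix(spec$background_level, nr, nc)
    clean[mask > 0] <- clean[mask > 0] + spec$lesion_intensity_offset
    clean <- clip01(clean)
    speckle <- matrix(stats::rgamma(nr * nc, shape = spec$speckle_looks,
                                    rate = spec$speckle_looks), nr, nc)
    list(image = clip01(clean * speckle), mask = mask,
         label = spec$class_label, spec = spec)
  })
}

#' Generate a labelled phantom dataset
#'
#' Per-sample specifications are drawn from class-conditional
#' distributions whose separation (hypoechogenicity gap and boundary
#' irregularity gap between benign and malignant) scales with
#' 1 - difficulty. Default class counts emulate a benign-heavy clinical
#' case mix (437 benign / 210 malignant). Deterministic per seed.
#'
#' @param n_benign number of benign samples
#' @param n_malignant number of malignant samples
#' @param seed integer master seed
#' @param difficulty class-separation control in [0, 1]; 0 = trivially
#'   separable
#' @param shape image shape for all samples
#' @return list of samples as returned by \code{\link{make_phantom}}
#' @export
make_dataset <- function(n_benign = 437L, n_malignant = 210L, seed = 0L,
                         difficulty = 0.5, shape = c(128L, 128L)) {
  n <- n_benign + n_malignant
  if (n == 0L) return(list())
  sep <- 1 - difficulty
  labels <- c(rep("B", n_benign), rep("M", n_malignant))
  specs <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      benign <- labels[i] == "B"
      irr <- if (benign)
        stats::runif(1, 0.02, 0.08 + 0.20 * difficulty)
      else
        stats::runif(1, 0.10 + 0.35 * sep, 0.25 + 0.45 * sep)
      off <- -(0.16 + 0.10 * stats::runif(1)) -
        (if (benign) 0 else 0.20 * sep + 0.04 * stats::runif(1))
      phantom_spec(
        shape = shape, class_label = labels[i],
        lesion_center = stats::runif(2, 0.40, 0.60),
        lesion_radius = stats::runif(1, 0.13, 0.21),
        irregularity = irr,
        lesion_intensity_offset = off,
        speckle_looks = 16L,
        background_level = stats::runif(1, 0.52, 0.62),
        axis_ratio = stats::runif(1, 0.70, 0.95),
        seed = sub_seeds[i])
    })
  })
  lapply(specs, make_phantom)
}

#' Write a phantom dataset to disk
#'
#' Writes images/*.png, masks/*.png (0/255) and labels.csv with columns
#' id, label, seed.
#'
#' @param samples list from \code{\link{make_dataset}}
#' @param dir output directory (created if needed)
#' @return invisibly, the labels data frame
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("sample_%04d", seq_along(samples))
  for (i in seq_along(samples)) {
    write_image(samples[[i]]$image,
                file.path(dir, "images", paste0(ids[i], ".png")))
    write_mask(samples[[i]]$mask,
               file.path(dir, "masks", paste0(ids[i], ".png")))
  }
  lab <- data.frame(id = ids,
                    label = vapply(samples, `[[`, "", "label"),
                    seed = vapply(samples,
                                  function(s) s$spec$seed, 0L))
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(lab)
}
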