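#' @keywords internal
"_PACKAGE"

# Shared validators and small numeric helpers.

sq_stop <- function(...) stop(..., call. = FALSE)

#' Round half-up to a number of decimal places
#'
#' Base \code{round()} rounds half to even; printed clinical tables round
#' half away from zero, so metric reporting uses this variant.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    sq_stop(arg, " must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L)
    sq_stop(arg, " must have at least one row and one column")
  if (any(!is.finite(img)))
    sq_stop(arg, " contains non-finite intensities")
  if (min(img) < 0 || max(img) > 1)
    sq_stop(arg, " intensities must lie in [0, 1]")
  invisible(img)
}

assert_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    sq_stop(arg, " must be a numeric matrix")
  if (!all(mask %in% c(0, 1)))
    sq_stop(arg, " must be binary (values 0/1)")
  if (!is.null(img) && !identical(dim(mask), dim(img)))
    sq_stop(arg, " shape must match its paired image")
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    sq_stop(what, " must have identical shapes (",
            paste(dim(a), collapse = "x"), " vs ",
            paste(dim(b), collapse = "x"), ")")
  invisible(NULL)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Local RNG scope: run expr under a given seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
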