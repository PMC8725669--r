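# Segmentation losses (soft dice, cross-entropy, focal, total) and
# evaluation metrics (mean IoU, mean F-score). Predictions are soft
# foreground-probability maps in [0, 1]; truths are 0/1 masks. Losses are
# reported as means/ratios over pixels so they are image-size invariant.

#' Loss parameters
#'
#' @param eps smoothing constant added to dice numerators/denominators
#' @param gamma focal modulation exponent (0 reduces focal loss to
#'   cross-entropy)
#' @param w_t weight of the focal term in the total loss, and the beta^2
#'   weight of the mean F-score
#' @param mode "standard" two-class soft dice, or "paper_literal" for the
#'   printed variant without the factor 2 and with the anomalous
#'   background denominator (kept for comparison; it does not reach 0 at
#'   perfect overlap)
#' @return an object of class \code{loss_params}
#' @export
loss_params <- function(eps = 1e-6, gamma = 2, w_t = 1,
                        mode = c("standard", "paper_literal")) {
  if (eps <= 0) sq_stop("eps must be > 0")
  if (gamma < 0) sq_stop("gamma must be >= 0")
  if (w_t < 0) sq_stop("w_t must be >= 0")
  structure(list(eps = eps, gamma = gamma, w_t = w_t,
                 mode = match.arg(mode)), class = "loss_params")
}

assert_prob_mask <- function(pred) {
  if (!is.matrix(pred) || !is.numeric(pred) || any(!is.finite(pred)) ||
      min(pred) < 0 || max(pred) > 1)
    sq_stop("pred must be a numeric matrix of probabilities in [0, 1]")
  invisible(pred)
}

#' Two-class soft dice loss
#'
#' Standard mode: 1 - (dice_fg + dice_bg) / 2 with the epsilon-smoothed
#' soft dice coefficient of each class; in [0, 1] and 0 at perfect
#' overlap (up to eps). The "paper_literal" mode evaluates the printed
#' fractions without the factor 2.
#'
#' @param pred probability matrix in [0, 1]
#' @param truth 0/1 matrix of the same shape
#' @param p a \code{\link{loss_params}}
#' @return scalar loss
#' @export
dice_loss <- function(pred, truth, p = loss_params()) {
  assert_prob_mask(pred); assert_mask(truth)
  assert_same_shape(pred, truth, "pred and truth")
  eps <- p$eps
  s_fp <- sum(pred); s_fr <- sum(truth); s_ff <- sum(pred * truth)
  s_bp <- sum(1 - pred); s_br <- sum(1 - truth)
  s_bb <- sum((1 - pred) * (1 - truth))
  if (p$mode == "standard") {
    f1 <- (2 * s_ff + eps) / (s_fp + s_fr + eps)
    f2 <- (2 * s_bb + eps) / (s_bp + s_br + eps)
    1 - (f1 + f2) / 2
  } else {
    n <- length(pred)
    f1 <- (s_ff + eps) / (s_fp + s_fr + eps)
    f2 <- (s_bb + eps) / (2 * n - s_fp + s_fr + eps)
    1 - f1 - f2
  }
}

#' Focal loss
#'
#' Mean over pixels of -(1 - p_t)^gamma log p_t, where p_t is the
#' predicted probability of the true class (the foreground probability on
#' foreground pixels, its complement on background). gamma = 0 reduces
#' exactly to binary cross-entropy.
#'
#' @inheritParams dice_loss
#' @return scalar loss
#' @export
focal_loss <- function(pred, truth, p = loss_params()) {
  assert_prob_mask(pred); assert_mask(truth)
  assert_same_shape(pred, truth, "pred and truth")
  pc <- pmin(1 - 1e-7, pmax(1e-7, pred))
  pt <- ifelse(truth > 0, pc, 1 - pc)
  mean(-(1 - pt)^p$gamma * log(pt))
}

#' Total loss: dice + w_t * focal
#'
#' @inheritParams dice_loss
#' @return scalar loss
#' @export
total_loss <- function(pred, truth, p = loss_params()) {
  dice_loss(pred, truth, p) + p$w_t * focal_loss(pred, truth, p)
}

as_mask_list <- function(x, arg) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L)
    sq_stop(arg, " must be a non-empty list of masks")
  x
}

iou_single <- function(pred, truth) {
  u <- sum(pred > 0 | truth > 0)
  if (u == 0) return(1)                 # empty vs empty
  sum(pred > 0 & truth > 0) / u
}

#' Mean intersection over union
#'
#' Per-image foreground IoU averaged over the list; an image where both
#' masks are empty scores 1.
#'
#' @param preds list of predicted 0/1 masks (or a single matrix)
#' @param truths list of ground-truth 0/1 masks
#' @return scalar mean IoU
#' @export
mean_iou <- function(preds, truths) {
  preds <- as_mask_list(preds, "preds"); truths <- as_mask_list(truths, "truths")
  if (length(preds) != length(truths))
    sq_stop("preds and truths must have equal length")
  mean(mapply(iou_single, preds, truths))
}

fscore_single <- function(pred, truth, beta2) {
  tp <- sum(pred > 0 & truth > 0)
  np <- sum(pred > 0); nt <- sum(truth > 0)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  prec <- tp / np; rec <- tp / nt
  if (prec + rec == 0) return(0)
  (1 + beta2) * prec * rec / (beta2 * prec + rec)
}

#' Mean F-score
#'
#' Per-image F_beta with beta^2 = w_t, averaged over the list; w_t = 1
#' gives the mean F1 (dice) score, which relates to IoU per image by
#' F1 = 2 IoU / (1 + IoU).
#'
#' @inheritParams mean_iou
#' @param w_t the beta^2 weight (default 1)
#' @return scalar mean F-score
#' @export
mean_fscore <- function(preds, truths, w_t = 1) {
  preds <- as_mask_list(preds, "preds"); truths <- as_mask_list(truths, "truths")
  if (length(preds) != length(truths))
    sq_stop("preds and truths must have equal length")
  mean(mapply(fscore_single, preds, truths, MoreArgs = list(beta2 = w_t)))
}

#' Full segmentation evaluation report
#'
#' @param preds list of probability or 0/1 prediction matrices
#' @param truths list of 0/1 truth masks
#' @param p a \code{\link{loss_params}}
#' @return list with dice_loss, focal_loss, total_loss, mean_iou, mean_f1
#'   and a per_image data frame
#' @export
seg_eval <- function(preds, truths, p = loss_params()) {
  preds <- as_mask_list(preds, "preds"); truths <- as_mask_list(truths, "truths")
  hard <- lapply(preds, function(m) (m >= 0.5) * 1)
  per <- data.frame(
    dice_loss = mapply(function(a, b) dice_loss(a, b, p), preds, truths),
    focal_loss = mapply(function(a, b) focal_loss(a, b, p), preds, truths),
    iou = mapply(iou_single, hard, truths),
    f1 = mapply(fscore_single, hard, truths, MoreArgs = list(beta2 = p$w_t)))
  per$total_loss <- per$dice_loss + p$w_t * per$focal_loss
  list(dice_loss = mean(per$dice_loss), focal_loss = mean(per$focal_loss),
       total_loss = mean(per$total_loss), mean_iou = mean(per$iou),
       mean_f1 = mean(per$f1), per_image = per)
}
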