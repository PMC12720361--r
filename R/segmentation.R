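# Pluggable segmentation support: the two segmentation stages of the
# framework (background removal, head-region labelling) are represented by
# a callable contract -- any function mapping an RGB image array to a
# label_mask with the declared class table. A reference segmenter that
# inverts the synthetic scene color table stands in for trained networks
# so the full pipeline runs end to end.

#' Focal loss
#'
#' `FL(pt) = -alpha * (1 - pt)^gamma * log(pt)` (natural log), averaged
#' over pixels, where `pt` is the predicted probability of the true class
#' at each pixel. With `gamma = 0`, `alpha = 1` this is exactly the
#' cross-entropy. Probabilities are clamped below at `1e-7` before the
#' log.
#'
#' @param pt Numeric vector/matrix of true-class probabilities in
#'   `[0, 1]`.
#' @param alpha Class-balance factor in (0, 1].
#' @param gamma Focusing exponent (>= 0); larger values down-weight
#'   well-classified (easy) pixels.
#' @return Mean focal loss (dimensionless scalar).
#' @examples
#' focal_loss(0.5, alpha = 1, gamma = 2)  # 0.25 * log(2)
#' @export
focal_loss <- function(pt, alpha = 0.25, gamma = 2) {
  pt <- as.numeric(pt)
  if (any(!is.finite(pt)) || any(pt < 0) || any(pt > 1))
    stop("focal_loss: pt must be probabilities in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("focal_loss: alpha must lie in (0, 1]", call. = FALSE)
  if (gamma < 0)
    stop("focal_loss: gamma must be >= 0", call. = FALSE)
  pt <- pmax(pt, 1e-7)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Dice loss
#'
#' `1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)`
#' with the conventional smoothing `eps = 1`. Zero (up to the eps
#' rounding) at a perfect prediction; approaches 1 for large disjoint
#' masks.
#'
#' @param pred Soft prediction mask in `[0, 1]`.
#' @param truth Binary truth mask (same dimensions).
#' @param eps Smoothing constant.
#' @return Loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("dice_loss: dimension mismatch", call. = FALSE)
  tr <- as.numeric(truth)
  pr <- as.numeric(pred)
  1 - (2 * sum(pr * tr) + eps) / (sum(pr) + sum(tr) + eps)
}

#' Binary cross-entropy loss
#'
#' Mean `-(t * log(p) + (1 - t) * log(1 - p))` with probabilities clamped
#' to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred Soft prediction mask in `[0, 1]`.
#' @param truth Binary truth mask (same dimensions).
#' @return Mean BCE loss.
#' @export
bce_loss <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("bce_loss: dimension mismatch", call. = FALSE)
  p <- pmin(pmax(as.numeric(pred), 1e-7), 1 - 1e-7)
  t_ <- as.numeric(truth)
  mean(-(t_ * log(p) + (1 - t_) * log(1 - p)))
}

#' Combined mask loss (focal + dice)
#'
#' The mask-loss combination used for small-region segmentation: a focal
#' term on the per-pixel true-class probability plus a dice term on the
#' soft mask, with configurable weights (1:1 by default). Non-negative,
#' and zero only at a perfect prediction (up to the dice eps).
#'
#' @param pred Soft prediction mask in `[0, 1]`.
#' @param truth Binary truth mask.
#' @param alpha,gamma Focal-loss parameters.
#' @param focal_weight,dice_weight Combination weights.
#' @return Scalar loss.
#' @export
mask_loss <- function(pred, truth, alpha = 0.25, gamma = 2,
                      focal_weight = 1, dice_weight = 1) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  pt <- ifelse(truth > 0.5, pred, 1 - pred)   # probability of the true class
  focal_weight * focal_loss(pt, alpha = alpha, gamma = gamma) +
    dice_weight * dice_loss(pred, truth)
}

#' Reference segmenter for synthetic scenes
#'
#' Inverts the fixed color table of [region_labels()]: each pixel of a
#' color-coded synthetic scene image is assigned the region whose render
#' color it carries. In strict mode any color absent from the table is an
#' error (listing the offending values); with `strict = FALSE` pixels are
#' assigned by nearest color (Euclidean distance in RGB), which tolerates
#' additive image noise. Stands in for a trained segmentation network so
#' the pipeline runs end to end on synthetic scenes; any external model
#' honouring the same contract (image in, [label_mask()] out, declared
#' class table) can be substituted.
#'
#' @param img An `h x w x 3` numeric array, values in 0-255 (or 0-1,
#'   detected and rescaled).
#' @param strict Error on unmapped colors instead of nearest-color
#'   assignment.
#' @return A [label_mask()] in the `"rgb"` frame.
#' @export
reference_segmenter <- function(img, strict = TRUE) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("reference_segmenter: img must be an h x w x 3 array", call. = FALSE)
  if (max(img) <= 1) img <- img * 255
  tab <- region_labels()
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- h * w
  rgbm <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
                as.numeric(img[, , 3]))
  d2 <- sapply(seq_len(nrow(tab)), function(i)
    (rgbm[, 1] - tab$r[i])^2 + (rgbm[, 2] - tab$g[i])^2 +
      (rgbm[, 3] - tab$b[i])^2)
  best <- max.col(-d2, ties.method = "first")
  if (strict) {
    miss <- d2[cbind(seq_len(n), best)] > 1e-6
    if (any(miss)) {
      bad <- unique(rgbm[miss, , drop = FALSE])
      bad <- utils::head(bad, 5)
      stop("reference_segmenter: unmapped colors: ",
           paste(apply(round(bad, 1), 1, paste, collapse = ","),
                 collapse = "; "), call. = FALSE)
    }
  }
  label_mask(matrix(tab$code[best], h, w), frame = "rgb")
}
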