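#' Confusion matrix from a truth/prediction mask pair
#'
#' Pools per-pixel counts: `counts[i, j]` is the number of pixels whose
#' true class is `i` and predicted class is `j` (classes 0-based in the
#' masks, rows/columns 1-based in the matrix).
#'
#' @param truth,pred [label_mask()] objects (or bare integer matrices) of
#'   identical dimensions with codes in `0:(k-1)`.
#' @param k Number of classes (default 5: background + four head regions).
#' @param class_names Optional class names (defaults to
#'   [region_labels()] names when `k == 5`).
#' @return An object of class `"confusion_matrix"`: a k x k integer
#'   matrix with a `class_names` attribute.
#' @export
confusion_from_masks <- function(truth, pred, k = 5L, class_names = NULL) {
  g <- function(m) if (inherits(m, "label_mask")) m$grid else {
    m <- as.matrix(m); storage.mode(m) <- "integer"; m
  }
  t_ <- g(truth); p_ <- g(pred)
  if (!identical(dim(t_), dim(p_)))
    stop(sprintf("confusion_from_masks: dimension mismatch (%s vs %s)",
                 paste(dim(t_), collapse = "x"), paste(dim(p_), collapse = "x")),
         call. = FALSE)
  if (any(t_ < 0L | t_ >= k) || any(p_ < 0L | p_ >= k))
    stop(sprintf("confusion_from_masks: label code outside 0..%d", k - 1L),
         call. = FALSE)
  counts <- matrix(tabulate(as.vector(t_) * k + as.vector(p_) + 1L,
                            nbins = k * k),
                   k, k, byrow = TRUE)
  if (is.null(class_names))
    class_names <- if (k == 5L) region_labels()$name else
      paste0("class", 0:(k - 1L))
  dimnames(counts) <- list(truth = class_names, pred = class_names)
  structure(counts, class = c("confusion_matrix", "matrix"),
            class_names = class_names)
}

#' Segmentation metrics from a confusion matrix
#'
#' Per-class IoU, mean IoU (MIoU) and mean pixel accuracy (MPA):
#' `IoU_i = p_ii / (sum_j p_ij + sum_j p_ji - p_ii)` and
#' `PA_i = p_ii / sum_j p_ij` (per-class recall), averaged over classes
#' present in truth or prediction. Classes absent from both are excluded
#' from the means (0/0 is undefined) and listed in `excluded_classes`.
#'
#' @param cm A `"confusion_matrix"` (or bare k x k count matrix).
#' @param restrict_to Optional character vector of class names to restrict
#'   the means to (e.g. the four head regions, excluding background).
#' @return A list of class `"metric_report"`: `iou` (named per-class),
#'   `pixel_accuracy` (named per-class), `miou`, `mpa`,
#'   `excluded_classes`.
#' @export
metric_report <- function(cm, restrict_to = NULL) {
  counts <- unclass(as.matrix(cm))
  nm <- attr(cm, "class_names")
  if (is.null(nm)) nm <- rownames(counts)
  if (is.null(nm)) nm <- paste0("class", seq_len(nrow(counts)) - 1L)
  if (sum(counts) == 0)
    stop("metric_report: empty evaluation (all-zero confusion matrix)",
         call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  dg <- diag(counts)
  present <- rs > 0 | cs > 0
  iou <- ifelse(present, dg / pmax(rs + cs - dg, 1), NA_real_)
  pa <- ifelse(present, ifelse(rs > 0, dg / rs, 0), NA_real_)
  names(iou) <- names(pa) <- nm
  use <- present
  if (!is.null(restrict_to)) use <- use & nm %in% restrict_to
  if (!any(use))
    stop("metric_report: no classes to average over", call. = FALSE)
  structure(list(iou = iou, pixel_accuracy = pa,
                 miou = mean(iou[use]), mpa = mean(pa[use]),
                 excluded_classes = nm[!present]),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics\n")
  for (n in names(x$iou))
    cat(sprintf("  %-11s IoU %s  PA %s\n", n,
                formatC(x$iou[[n]], format = "f", digits = 4),
                formatC(x$pixel_accuracy[[n]], format = "f", digits = 4)))
  cat(sprintf("  MIoU %.4f  MPA %.4f\n", x$miou, x$mpa))
  if (length(x$excluded_classes))
    cat("  excluded (absent):", paste(x$excluded_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return `sum(a & b) / sum(a | b)`; `NaN` when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask_iou: dimension mismatch", call. = FALSE)
  sum(a & b) / sum(a | b)
}

#' Centroid offset between two binary masks
#'
#' Euclidean distance, in pixels, between the unweighted pixel-center
#' centroids of two non-empty binary masks.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return Distance in pixels.
#' @export
centroid_offset <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("centroid_offset: dimension mismatch", call. = FALSE)
  cent <- function(m) {
    ij <- which(m, arr.ind = TRUE)
    if (nrow(ij) == 0L)
      stop("centroid_offset: empty mask", call. = FALSE)
    c(u = mean(ij[, 2]) - 1, v = mean(ij[, 1]) - 1)
  }
  ca <- cent(a); cb <- cent(b)
  sqrt(sum((ca - cb)^2))
}
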