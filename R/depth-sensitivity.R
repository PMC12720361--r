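#' Depth-sweep configuration
#'
#' The depth-error experiment traverses a depth interval around a baseline
#' working depth and compares each depth's mapped masks against the
#' baseline-depth masks. Defaults follow the protocol of sweeping
#' `[580, 620]` mm in 1 mm increments around a 600 mm baseline.
#'
#' @param baseline Baseline depth in mm.
#' @param d_min,d_max Sweep bounds in mm (inclusive).
#' @param step Increment in mm.
#' @return An object of class `"depth_sweep_config"`.
#' @export
depth_sweep_config <- function(baseline = 600, d_min = 580, d_max = 620,
                               step = 1) {
  if (step <= 0) stop("depth_sweep_config: step must be positive", call. = FALSE)
  if (d_min > baseline || baseline > d_max)
    stop("depth_sweep_config: need d_min <= baseline <= d_max", call. = FALSE)
  n <- (d_max - d_min) / step
  if (abs(n - round(n)) > 1e-9)
    stop("depth_sweep_config: (d_max - d_min) must be an integer multiple of step",
         call. = FALSE)
  structure(list(baseline = baseline, d_min = d_min, d_max = d_max,
                 step = step,
                 depths = seq(d_min, d_max, by = step)),
            class = "depth_sweep_config")
}

#' Sweep mapping depth and compare against the baseline-depth masks
#'
#' For every depth on the grid and every input frame, runs
#' [map_label_mask()] and compares each head region's mask against the
#' same frame's baseline-depth mask: per-region IoU and centroid offset,
#' averaged over frames. Comparison is against baseline-depth *mapped*
#' masks, not ground truth. Regions empty in a frame at the baseline
#' depth are skipped for that frame (IoU is undefined there) and tallied.
#'
#' @param masks A list of [label_mask()] objects (RGB frame), one per
#'   frame.
#' @param rig A [camera_rig()].
#' @param cfg A [depth_sweep_config()].
#' @param min_area Passed to [map_label_mask()].
#' @return An object of class `"depth_sweep"`: a list with `table` (long
#'   data.frame: `depth_mm`, `region`, `mean_iou`, `mean_offset_px`,
#'   `n_frames`, `n_skipped`), `config`, and `n_input_frames`.
#' @export
sweep_depths <- function(masks, rig, cfg = depth_sweep_config(),
                         min_area = 5L) {
  if (inherits(masks, "label_mask")) masks <- list(masks)
  if (length(masks) == 0L)
    stop("sweep_depths: need at least one input mask", call. = FALSE)
  regions <- head_regions()
  fcs <- lapply(masks, .frame_contours, min_area = min_area)
  base <- lapply(fcs, .map_frame_contours, rig = rig, depth = cfg$baseline)
  rows <- list()
  for (d in cfg$depths) {
    cur <- if (d == cfg$baseline) base else
      lapply(fcs, .map_frame_contours, rig = rig, depth = d)
    for (r in regions) {
      ious <- c(); offs <- c(); skipped <- 0L
      for (f in seq_along(masks)) {
        bm <- base[[f]]$masks[[r]]
        if (!any(bm)) { skipped <- skipped + 1L; next }
        cm <- cur[[f]]$masks[[r]]
        ious <- c(ious, if (any(cm | bm)) sum(cm & bm) / sum(cm | bm) else NA)
        offs <- c(offs, if (any(cm)) centroid_offset(cm, bm) else NA)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        depth_mm = d, region = r,
        mean_iou = if (length(ious)) mean(ious, na.rm = TRUE) else NA_real_,
        mean_offset_px = if (length(offs)) mean(offs, na.rm = TRUE) else NA_real_,
        n_frames = length(ious), n_skipped = skipped,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), config = cfg,
                 n_input_frames = length(masks)),
            class = "depth_sweep")
}

#' Summarize a depth sweep
#'
#' Long-format per-region records plus a pooled (region-averaged) table
#' and monotone-trend diagnostics: moving away from the baseline on
#' either side, mean IoU should not increase and mean offset should not
#' decrease (up to a small rasterization tolerance).
#'
#' @param sweep A `"depth_sweep"` from [sweep_depths()].
#' @param tol_iou,tol_offset Tolerances for the monotonicity diagnostics
#'   (mask rasterization quantizes both quantities).
#' @return A list of class `"depth_sweep_summary"`: `table` (per region),
#'   `pooled` (averaged over regions per depth), `diagnostics` with the
#'   largest IoU increase / offset decrease away from baseline and
#'   logical `monotone_iou` / `monotone_offset` flags.
#' @export
summarize_sweep <- function(sweep, tol_iou = 1e-3, tol_offset = 0.01) {
  tab <- sweep$table
  base <- sweep$config$baseline
  pooled <- aggregate(tab[, c("mean_iou", "mean_offset_px")],
                      by = list(depth_mm = tab$depth_mm), FUN = mean)
  worst_iou <- -Inf; worst_off <- Inf
  for (r in unique(tab$region)) {
    tr <- tab[tab$region == r & is.finite(tab$mean_iou), ]
    tr <- tr[order(tr$depth_mm), ]
    for (side in c(-1, 1)) {
      s <- tr[sign(tr$depth_mm - base) %in% c(0, side), ]
      if (nrow(s) < 2L) next
      if (side < 0) s <- s[rev(seq_len(nrow(s))), ]  # away from baseline
      worst_iou <- max(worst_iou, max(diff(s$mean_iou)))
      worst_off <- min(worst_off, min(diff(s$mean_offset_px)))
    }
  }
  structure(list(
    table = tab, pooled = pooled,
    diagnostics = list(
      max_iou_increase = worst_iou,
      max_offset_decrease = worst_off,
      monotone_iou = worst_iou <= tol_iou,
      monotone_offset = worst_off >= -tol_offset)),
    class = "depth_sweep_summary")
}

#' @export
print.depth_sweep_summary <- function(x, ...) {
  cat("Depth sweep summary\n")
  print(utils::head(x$pooled, 5))
  cat("  ...\n")
  d <- x$diagnostics
  cat(sprintf("  max IoU increase away from baseline: %.3g (monotone: %s)\n",
              d$max_iou_increase, d$monotone_iou))
  cat(sprintf("  max offset decrease away from baseline: %.3g (monotone: %s)\n",
              d$max_offset_decrease, d$monotone_offset))
  invisible(x)
}

#' Plot a depth sweep
#'
#' Two base-graphics panels: mean IoU vs depth and mean centroid offset
#' vs depth, one line per head region.
#'
#' @param x A `"depth_sweep"` object.
#' @param ... Unused.
#' @export
plot.depth_sweep <- function(x, ...) {
  tab <- x$table
  regions <- unique(tab$region)
  cols <- grDevices::hcl.colors(max(4L, length(regions)), "Dark 2")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (what in c("mean_iou", "mean_offset_px")) {
    ylab <- if (what == "mean_iou") "mean IoU vs baseline" else
      "mean centroid offset (px)"
    plot(NA, xlim = range(tab$depth_mm), ylim = range(tab[[what]], na.rm = TRUE),
         xlab = "depth (mm)", ylab = ylab)
    for (i in seq_along(regions)) {
      tr <- tab[tab$region == regions[i], ]
      graphics::lines(tr$depth_mm, tr[[what]], col = cols[i], lwd = 2)
    }
    graphics::abline(v = x$config$baseline, lty = 3)
    graphics::legend("bottomright", legend = regions, col = cols, lwd = 2,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Write / read a depth-sweep summary table as CSV
#'
#' Columns `depth_mm`, `region`, `mean_iou`, `mean_offset_px`,
#' `n_frames`, `n_skipped`. The round trip is lossless at full double
#' precision.
#'
#' @param sweep A `"depth_sweep"` or its `table`.
#' @param path CSV path.
#' @return `read_sweep_csv()` returns the table as a data.frame.
#' @export
write_sweep_csv <- function(sweep, path) {
  tab <- if (inherits(sweep, "depth_sweep")) sweep$table else sweep
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
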