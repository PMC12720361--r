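#' Region label code table
#'
#' The fixed integer coding of the semantic classes used throughout the
#' package: background = 0, comb = 1, eye = 2, beak = 3, wattle = 4.
#'
#' @return A data.frame with columns `code`, `name`, and the RGB render
#'   color (`r`, `g`, `b`, 0-255) used by the synthetic scene generator
#'   and inverted by [reference_segmenter()].
#' @export
region_labels <- function() {
  data.frame(
    code = 0:4,
    name = c("background", "comb", "eye", "beak", "wattle"),
    r = c(0, 220, 40, 230, 200),
    g = c(0, 40, 40, 200, 60),
    b = c(0, 40, 220, 40, 180),
    stringsAsFactors = FALSE)
}

#' Names of the four head regions
#'
#' Convenience accessor for the non-background classes, in code order.
#' @return Character vector `c("comb", "eye", "beak", "wattle")`.
#' @export
head_regions <- function() c("comb", "eye", "beak", "wattle")

# Resolve a region given as name or code to list(code, name).
resolve_region <- function(region) {
  tab <- region_labels()
  if (is.character(region)) {
    i <- match(region, tab$name)
  } else {
    i <- match(as.integer(region), tab$code)
  }
  if (is.na(i))
    stop(sprintf("unknown region label: %s", as.character(region)), call. = FALSE)
  list(code = tab$code[i], name = tab$name[i])
}

#' Integer-coded per-pixel label mask
#'
#' A height x width integer matrix of [region_labels()] codes, tagged with
#' the channel frame whose pixel grid it lives in (`"rgb"` or `"ir"`).
#'
#' @param grid Integer matrix of label codes (rows = image rows).
#' @param frame `"rgb"` or `"ir"`.
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(grid, frame = c("rgb", "ir")) {
  frame <- match.arg(frame)
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  codes <- region_labels()$code
  bad <- setdiff(unique(as.vector(grid)), codes)
  if (length(bad))
    stop("label_mask: invalid label codes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(grid = grid, frame = frame), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x$grid), levels = region_labels()$code,
                      labels = region_labels()$name))
  cat(sprintf("label_mask [%s frame] %d x %d px\n",
              x$frame, nrow(x$grid), ncol(x$grid)))
  print(tab)
  invisible(x)
}

#' Read / write a label mask as 8-bit grayscale PNG
#'
#' Label codes are stored directly as 8-bit gray levels (0-4), the plain
#' integer-coded convention of segmentation datasets.
#'
#' @param path PNG file path.
#' @param frame Frame tag to attach on read.
#' @param mask A [label_mask()] to write.
#' @return `read_label_mask()` returns a [label_mask()];
#'   `write_label_mask()` returns `path` invisibly.
#' @export
read_label_mask <- function(path, frame = c("rgb", "ir")) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  label_mask(round(img * 255), frame = match.arg(frame))
}

#' @rdname read_label_mask
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(mask$grid / 255, path)
  invisible(path)
}

#' Per-region binary masks in the IR pixel grid
#'
#' The output of the mask-level cross-modal mapping: one logical mask per
#' head region (all at the IR resolution), the depth the mapping used, and
#' per-region bookkeeping of the fraction of mapped contour vertices that
#' fell outside the IR image bounds.
#'
#' @param masks Named list of logical matrices (names from
#'   [head_regions()]); all must share dimensions.
#' @param depth_used Depth in mm used for the mapping.
#' @param out_of_bounds_fraction Named numeric in `[0, 1]` per region.
#' @return An object of class `"roi_set"`.
#' @export
roi_set <- function(masks, depth_used,
                    out_of_bounds_fraction = setNames(rep(0, length(masks)),
                                                      names(masks))) {
  regions <- head_regions()
  if (!all(names(masks) %in% regions))
    stop("roi_set: mask names must be head regions", call. = FALSE)
  dims <- unique(lapply(masks, dim))
  if (length(dims) > 1L)
    stop("roi_set: all region masks must share dimensions", call. = FALSE)
  masks <- lapply(masks, function(m) { storage.mode(m) <- "logical"; m })
  if (any(out_of_bounds_fraction < 0 | out_of_bounds_fraction > 1, na.rm = TRUE))
    stop("roi_set: out_of_bounds_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(masks = masks, depth_used = depth_used,
                 out_of_bounds_fraction = out_of_bounds_fraction),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("roi_set (%d x %d px, depth %.1f mm)\n", d[1], d[2], x$depth_used))
  for (r in names(x$masks))
    cat(sprintf("  %-7s %6d px  (out-of-bounds fraction %.3f)\n",
                r, sum(x$masks[[r]]), x$out_of_bounds_fraction[[r]]))
  invisible(x)
}

#' Write / read an ROI set as per-region PNGs plus a JSON sidecar
#'
#' Each region mask is written as `roi_<region>.png` (binary 8-bit), with
#' `roi.json` holding `depth_used` and the out-of-bounds fractions.
#'
#' @param roi A [roi_set()].
#' @param dir Output directory (created if missing).
#' @return `write_roi_set()` returns `dir` invisibly; `read_roi_set()`
#'   returns a [roi_set()].
#' @export
write_roi_set <- function(roi, dir) {
  stopifnot(inherits(roi, "roi_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in names(roi$masks))
    png::writePNG(roi$masks[[r]] * 1, file.path(dir, paste0("roi_", r, ".png")))
  meta <- list(depth_used_mm = roi$depth_used,
               out_of_bounds_fraction = as.list(roi$out_of_bounds_fraction))
  jsonlite::write_json(meta, file.path(dir, "roi.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "roi.json"), simplifyVector = TRUE)
  files <- list.files(dir, pattern = "^roi_.*\\.png$", full.names = TRUE)
  masks <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img > 0.5
  })
  names(masks) <- sub("^roi_(.*)\\.png$", "\\1", basename(files))
  masks <- masks[intersect(head_regions(), names(masks))]
  oob <- unlist(meta$out_of_bounds_fraction)[names(masks)]
  roi_set(masks, depth_used = meta$depth_used_mm,
          out_of_bounds_fraction = oob)
}

#' Flatten an ROI set into a single IR-frame label mask
#'
#' Regions are written in the order comb, wattle, beak, eye so that the
#' smallest structures win where mapped regions overlap after projection.
#'
#' @param roi A [roi_set()].
#' @return A [label_mask()] in the `"ir"` frame.
#' @export
flatten_roi_set <- function(roi) {
  stopifnot(inherits(roi, "roi_set"))
  d <- dim(roi$masks[[1]])
  grid <- matrix(0L, d[1], d[2])
  tab <- region_labels()
  for (r in c("comb", "wattle", "beak", "eye"))
    if (!is.null(roi$masks[[r]]))
      grid[roi$masks[[r]]] <- tab$code[tab$name == r]
  label_mask(grid, frame = "ir")
}
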