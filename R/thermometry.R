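#' Per-pixel IR temperature matrix
#'
#' A height x width matrix of temperatures in degrees C aligned 1:1 with
#' the IR pixel grid, with capture metadata. Values outside a plausible
#' surface-temperature range trigger a warning (not an error).
#'
#' @param grid Numeric matrix of temperatures (degrees C).
#' @param frame_id Optional frame identifier.
#' @param timestamp Optional capture time label (e.g. `"16:30"`).
#' @param plausible_range Warn if any value falls outside this range.
#' @return An object of class `"temperature_matrix"`.
#' @export
temperature_matrix <- function(grid, frame_id = NA_character_,
                               timestamp = NA_character_,
                               plausible_range = c(-20, 80)) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (!all(is.finite(grid)))
    stop("temperature_matrix: all temperatures must be finite", call. = FALSE)
  if (any(grid < plausible_range[1] | grid > plausible_range[2]))
    warning(sprintf(
      "temperature_matrix: values outside the plausible range [%g, %g] C",
      plausible_range[1], plausible_range[2]), call. = FALSE)
  structure(list(grid = grid, frame_id = frame_id, timestamp = timestamp),
            class = "temperature_matrix")
}

#' Read / write a temperature matrix as headerless CSV
#'
#' Row-major plain CSV of degrees-C floats, one CSV row per IR image row
#' (the export format of thermal-camera vendor tools).
#'
#' @param path CSV path.
#' @param t A [temperature_matrix()] to write.
#' @param ... Passed to [temperature_matrix()] on read.
#' @return `read_temperature_matrix()` returns a
#'   [temperature_matrix()].
#' @export
read_temperature_matrix <- function(path, ...) {
  g <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(g) <- NULL
  temperature_matrix(g, ...)
}

#' @rdname read_temperature_matrix
#' @export
write_temperature_matrix <- function(t, path) {
  stopifnot(inherits(t, "temperature_matrix"))
  utils::write.table(format(t$grid, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Per-region temperature statistics
#'
#' For every non-empty region mask of an ROI set, computes the mean, min
#' and max temperature (degrees C) and the pixel count over the mask.
#' The mean is the quantity reported downstream; min/max are carried as
#' diagnostics. Empty regions are omitted with a warning and recorded in
#' the `"empty_regions"` attribute.
#'
#' @param t A [temperature_matrix()] (IR grid).
#' @param roi A [roi_set()] with masks of the same dimensions.
#' @return A data.frame with columns `region`, `mean_c`, `min_c`,
#'   `max_c`, `pixel_count`.
#' @export
region_stats <- function(t, roi) {
  stopifnot(inherits(t, "temperature_matrix"), inherits(roi, "roi_set"))
  if (!identical(dim(t$grid), dim(roi$masks[[1]])))
    stop(sprintf("region_stats: dimension mismatch (%s vs %s)",
                 paste(dim(t$grid), collapse = "x"),
                 paste(dim(roi$masks[[1]]), collapse = "x")), call. = FALSE)
  rows <- list(); empty <- character(0)
  for (r in names(roi$masks)) {
    m <- roi$masks[[r]]
    if (!any(m)) { empty <- c(empty, r); next }
    v <- t$grid[m]
    rows[[r]] <- data.frame(region = r, mean_c = mean(v), min_c = min(v),
                            max_c = max(v), pixel_count = length(v),
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("region_stats: all region masks are empty", call. = FALSE)
  if (length(empty))
    warning("region_stats: empty regions omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "empty_regions") <- empty
  out
}

#' Group report of mean head-region temperatures
#'
#' Aggregates per-bird region temperatures into group means for each
#' (density, age, condition, region) cell, i.e. the mean of per-bird
#' mean temperatures with the number of birds per cell. When a bird
#' contributes several frames, frames are averaged within the bird first
#' (`per_bird = TRUE`, the default) so each bird counts once; with
#' `per_bird = FALSE` all records are pooled directly.
#'
#' @param records A data.frame with columns `density` (birds/m2), `age_weeks`,
#'   `condition` (`"experimental"` or `"control"`), `bird_id`, `region`,
#'   `mean_c`.
#' @param per_bird Average frames within bird before averaging over birds.
#' @return A data.frame (`density`, `age_weeks`, `condition`, `region`,
#'   `mean_c`, `n`) ordered by density, age, condition, region; cells
#'   with no records are absent (no imputation).
#' @export
group_report <- function(records, per_bird = TRUE) {
  need <- c("density", "age_weeks", "condition", "bird_id", "region", "mean_c")
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("group_report: need at least one record", call. = FALSE)
  if (!all(need %in% names(records)))
    stop("group_report: records must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (per_bird) {
    records <- aggregate(
      mean_c ~ density + age_weeks + condition + bird_id + region,
      data = records, FUN = mean)
  }
  n_fun <- function(v) c(mean_c = mean(v), n = length(v))
  agg <- aggregate(mean_c ~ density + age_weeks + condition + region,
                   data = records, FUN = mean)
  cnt <- aggregate(mean_c ~ density + age_weeks + condition + region,
                   data = records, FUN = length)
  agg$n <- cnt$mean_c
  ord <- order(agg$density, agg$age_weeks, agg$condition,
               match(agg$region, region_labels()$name))
  agg <- agg[ord, c("density", "age_weeks", "condition", "region",
                    "mean_c", "n")]
  rownames(agg) <- NULL
  agg
}
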