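#' Write / read a camera rig as JSON
#'
#' Schema: top-level keys `rgb` and `ir`, each with `fx`, `fy`, `cx`,
#' `cy`, `width`, `height` and `dist` = `[k1, k2, p1, p2, k3]`;
#' `extrinsics` with `rotation` (9 row-major floats) and
#' `translation_mm` (3 floats); optional `metadata` (`emissivity`,
#' `temperature_accuracy_c`, `rms_reprojection_error_px`). Numbers are
#' written at full precision so a read -> write -> read round trip is
#' bit-exact.
#'
#' @param rig A [camera_rig()].
#' @param path JSON file path.
#' @return `read_camera_rig()` returns a [camera_rig()];
#'   `write_camera_rig()` returns `path` invisibly.
#' @export
write_camera_rig <- function(rig, path) {
  stopifnot(inherits(rig, "camera_rig"))
  ch <- function(x) list(
    fx = x$intrinsics$fx, fy = x$intrinsics$fy,
    cx = x$intrinsics$cx, cy = x$intrinsics$cy,
    width = x$intrinsics$width, height = x$intrinsics$height,
    dist = unname(unlist(x$distortion)))
  obj <- list(
    rgb = ch(rig$rgb), ir = ch(rig$ir),
    extrinsics = list(
      rotation = as.numeric(t(rig$extrinsics$rotation)),
      translation_mm = rig$extrinsics$translation),
    metadata = list(
      emissivity = rig$emissivity,
      temperature_accuracy_c = rig$temperature_accuracy,
      rms_reprojection_error_px = rig$rms_reprojection_error))
  # digits = I(17): shortest-exact is not guaranteed by NA; 17 significant
  # digits round-trip IEEE doubles bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_camera_rig
#' @export
read_camera_rig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- function(x) list(
    intrinsics = intrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height),
    distortion = distortion_coeffs(k1 = x$dist[1], k2 = x$dist[2],
                                   p1 = x$dist[3], p2 = x$dist[4],
                                   k3 = x$dist[5]))
  ext <- obj$extrinsics
  R <- if (!is.null(dim(ext$rotation))) ext$rotation else
    matrix(ext$rotation, 3, 3, byrow = TRUE)
  md <- obj$metadata
  rms <- md$rms_reprojection_error_px
  camera_rig(
    rgb = ch(obj$rgb), ir = ch(obj$ir),
    extrinsics = rig_extrinsics(R, ext$translation_mm),
    rms_reprojection_error = if (is.null(rms)) NA_real_ else rms,
    emissivity = if (is.null(md$emissivity)) 0.96 else md$emissivity,
    temperature_accuracy = if (is.null(md$temperature_accuracy_c)) 0.5 else
      md$temperature_accuracy_c)
}

#' Write / read corner observations as CSV
#'
#' Columns `pose_id`, `channel`, `board_i`, `board_j`, `u`, `v`.
#'
#' @param obs A [corner_observations()].
#' @param path CSV path.
#' @param board The [checkerboard_spec()] the corners belong to
#'   (the CSV carries pixel coordinates only).
#' @return `read_corner_observations()` returns a
#'   [corner_observations()].
#' @export
write_corner_observations <- function(obs, path) {
  stopifnot(inherits(obs, "corner_observations"))
  df <- obs$corners
  df$u <- format(df$u, digits = 17, trim = TRUE, scientific = FALSE)
  df$v <- format(df$v, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corner_observations
#' @export
read_corner_observations <- function(path, board) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  corner_observations(df, board)
}
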