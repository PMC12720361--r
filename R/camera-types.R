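#' Camera intrinsics
#'
#' Focal lengths and principal point relating normalized camera coordinates
#' to pixel coordinates, plus the sensor resolution. Pixel coordinates are
#' 0-based, `(u, v) = (column, row)`, with integer coordinates at pixel
#' centers.
#'
#' @param fx,fy Focal lengths in pixels (must be positive).
#' @param cx,cy Principal point (column, row) in pixels.
#' @param width,height Image size in pixels.
#' @return An object of class `"intrinsics"`.
#' @examples
#' intrinsics(fx = 2400, fy = 2400, cx = 1344, cy = 760,
#'            width = 2688, height = 1520)
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height) {
  vals <- c(fx = fx, fy = fy, cx = cx, cy = cy,
            width = width, height = height)
  if (!all(is.finite(vals)))
    stop("intrinsics: all fields must be finite numbers", call. = FALSE)
  if (fx <= 0 || fy <= 0)
    stop("intrinsics: focal lengths must be positive", call. = FALSE)
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0L || height <= 0L)
    stop("intrinsics: width and height must be positive integers", call. = FALSE)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    warning("intrinsics: principal point lies outside the image", call. = FALSE)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height),
            class = "intrinsics")
}

#' Lens distortion coefficients
#'
#' Brown-Conrady radial (`k1`, `k2`, `k3`) and tangential (`p1`, `p2`)
#' coefficients acting on normalized (dimensionless) camera coordinates.
#' All-zero coefficients encode a distortion-free channel.
#'
#' @param k1,k2,k3 Radial coefficients.
#' @param p1,p2 Tangential coefficients.
#' @return An object of class `"distortion_coeffs"`.
#' @export
distortion_coeffs <- function(k1 = 0, k2 = 0, p1 = 0, p2 = 0, k3 = 0) {
  vals <- c(k1 = k1, k2 = k2, p1 = p1, p2 = p2, k3 = k3)
  if (!all(is.finite(vals)))
    stop("distortion_coeffs: all coefficients must be finite", call. = FALSE)
  structure(as.list(vals), class = "distortion_coeffs")
}

#' Rigid transform between the RGB and IR camera frames
#'
#' Stored in the RGB-frame -> IR-frame direction: a point `P` in RGB camera
#' coordinates maps to `rotation %*% P + translation` in IR camera
#' coordinates. Lengths are in mm.
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1).
#' @param translation Length-3 translation vector in mm.
#' @return An object of class `"rig_extrinsics"`.
#' @export
rig_extrinsics <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("rig_extrinsics: translation must be a finite 3-vector", call. = FALSE)
  if (!all(is.finite(rotation)))
    stop("rig_extrinsics: rotation must be finite", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rig_extrinsics: rotation is not orthonormal (tol 1e-9)", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rig_extrinsics: rotation must have determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rig_extrinsics")
}

#' Dual-channel camera rig
#'
#' Full geometric description of an RGB + infrared rig: intrinsics and
#' distortion for both channels and the RGB->IR extrinsic transform.
#' `emissivity` and `temperature_accuracy` are thermal-camera metadata only
#' (the camera applies emissivity internally; no radiometric correction is
#' performed by this package).
#'
#' @param rgb,ir Lists with elements `intrinsics` and `distortion`.
#' @param extrinsics A [rig_extrinsics()] (RGB frame -> IR frame).
#' @param rms_reprojection_error Optional RMS reprojection error in pixels,
#'   set by [calibrate_rig()].
#' @param emissivity Surface emissivity assumed by the thermal channel,
#'   in (0, 1].
#' @param temperature_accuracy Stated absolute temperature accuracy in
#'   degrees C.
#' @return An object of class `"camera_rig"`.
#' @export
camera_rig <- function(rgb, ir, extrinsics = rig_extrinsics(),
                       rms_reprojection_error = NA_real_,
                       emissivity = 0.96, temperature_accuracy = 0.5) {
  chk_channel <- function(ch, name) {
    if (!inherits(ch$intrinsics, "intrinsics"))
      stop(sprintf("camera_rig: %s$intrinsics must be an intrinsics object", name),
           call. = FALSE)
    if (is.null(ch$distortion)) ch$distortion <- distortion_coeffs()
    if (!inherits(ch$distortion, "distortion_coeffs"))
      stop(sprintf("camera_rig: %s$distortion must be distortion_coeffs", name),
           call. = FALSE)
    ch[c("intrinsics", "distortion")]
  }
  rgb <- chk_channel(rgb, "rgb")
  ir <- chk_channel(ir, "ir")
  if (!inherits(extrinsics, "rig_extrinsics"))
    stop("camera_rig: extrinsics must be a rig_extrinsics object", call. = FALSE)
  if (!is.na(emissivity) && (emissivity <= 0 || emissivity > 1))
    stop("camera_rig: emissivity must lie in (0, 1]", call. = FALSE)
  structure(list(rgb = rgb, ir = ir, extrinsics = extrinsics,
                 rms_reprojection_error = rms_reprojection_error,
                 emissivity = emissivity,
                 temperature_accuracy = temperature_accuracy),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  fmt_ch <- function(ch, name) {
    i <- ch$intrinsics
    d <- unlist(ch$distortion)
    cat(sprintf("  %-3s %dx%d  fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
                name, i$width, i$height, i$fx, i$fy, i$cx, i$cy))
    cat(sprintf("      dist [k1 k2 p1 p2 k3] = %s\n",
                paste(formatC(d, format = "g", digits = 4), collapse = " ")))
  }
  cat("Dual-channel camera rig\n")
  fmt_ch(x$rgb, "rgb")
  fmt_ch(x$ir, "ir")
  cat(sprintf("  baseline (RGB->IR translation, mm): %s\n",
              paste(formatC(x$extrinsics$translation, format = "f", digits = 3),
                    collapse = " ")))
  ang <- tryCatch(rotation_to_rodrigues(x$extrinsics$rotation),
                  error = function(e) rep(NA_real_, 3))
  cat(sprintf("  rotation angle: %.4f deg\n", sqrt(sum(ang^2)) * 180 / pi))
  if (!is.na(x$rms_reprojection_error))
    cat(sprintf("  RMS reprojection error: %.4f px\n", x$rms_reprojection_error))
  cat(sprintf("  emissivity %.2f, temperature accuracy +/- %.1f C\n",
              x$emissivity, x$temperature_accuracy))
  invisible(x)
}

# Coerce point input to an n x 2 (or n x 3) numeric matrix.
# Accepts a numeric vector of length `ncol` (a single point) or a matrix.
as_points <- function(p, ncol = 2L, what = "point") {
  if (is.null(dim(p))) {
    if (length(p) != ncol)
      stop(sprintf("expected a length-%d %s or an n x %d matrix", ncol, what, ncol),
           call. = FALSE)
    p <- matrix(as.numeric(p), 1L, ncol)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != ncol)
      stop(sprintf("expected an n x %d matrix of %ss", ncol, what), call. = FALSE)
    storage.mode(p) <- "double"
  }
  if (!all(is.finite(p)))
    stop(sprintf("non-finite %s coordinates", what), call. = FALSE)
  p
}
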