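#' Normalize pixel coordinates
#'
#' Converts pixel coordinates to normalized (dimensionless) camera
#' coordinates using the channel intrinsics:
#' `x = (u - cx) / fx`, `y = (v - cy) / fy`.
#'
#' @param p A pixel point `(u, v)` or an n x 2 matrix of points.
#' @param intr An [intrinsics()] object.
#' @return An n x 2 matrix of normalized coordinates (single points are
#'   returned as a 1 x 2 matrix).
#' @export
normalize_pixel <- function(p, intr) {
  p <- as_points(p, 2L, "pixel point")
  cbind(x = (p[, 1] - intr$cx) / intr$fx,
        y = (p[, 2] - intr$cy) / intr$fy)
}

#' Apply lens distortion to normalized coordinates
#'
#' Brown-Conrady forward model. With `r2 = x^2 + y^2`:
#' `x_d = x (1 + k1 r2 + k2 r2^2 + k3 r2^3) + 2 p1 x y + p2 (r2 + 2 x^2)`
#' and the symmetric expression for `y_d`.
#'
#' @param n Normalized point(s): length-2 vector or n x 2 matrix.
#' @param d A [distortion_coeffs()] object.
#' @return An n x 2 matrix of distorted normalized coordinates.
#' @export
distort_normalized <- function(n, d) {
  n <- as_points(n, 2L, "normalized point")
  x <- n[, 1]; y <- n[, 2]
  r2 <- x * x + y * y
  radial <- 1 + r2 * (d$k1 + r2 * (d$k2 + r2 * d$k3))
  cbind(x = x * radial + 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x * x),
        y = y * radial + d$p1 * (r2 + 2 * y * y) + 2 * d$p2 * x * y)
}

#' Invert lens distortion on normalized coordinates
#'
#' Solves `distort_normalized(n_hat, d) = n` for `n_hat` by the standard
#' fixed-point iteration `x <- (x_obs - tangential(x)) / radial(x)`,
#' to a residual tolerance of 1e-10 on normalized coordinates
#' (at most `max_iter` iterations). Non-convergence is an error, not a
#' silent pass-through.
#'
#' @param n Observed (distorted) normalized point(s).
#' @param d A [distortion_coeffs()] object.
#' @param tol Convergence tolerance on the forward residual.
#' @param max_iter Maximum number of fixed-point iterations.
#' @return An n x 2 matrix of undistorted normalized coordinates.
#' @export
undistort_normalized <- function(n, d, tol = 1e-10, max_iter = 50L) {
  n <- as_points(n, 2L, "normalized point")
  colnames(n) <- c("x", "y")
  if (all(unlist(d) == 0)) return(n)
  x <- n[, 1]; y <- n[, 2]
  x0 <- x; y0 <- y
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    r2 <- x * x + y * y
    radial <- 1 + r2 * (d$k1 + r2 * (d$k2 + r2 * d$k3))
    tx <- 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x * x)
    ty <- d$p1 * (r2 + 2 * y * y) + 2 * d$p2 * x * y
    x <- (x0 - tx) / radial
    y <- (y0 - ty) / radial
    fwd <- distort_normalized(cbind(x, y), d)
    err <- pmax(abs(fwd[, 1] - x0), abs(fwd[, 2] - y0))
    if (all(is.finite(err)) && max(err) < tol) { ok <- TRUE; break }
  }
  if (!ok) {
    bad <- if (all(is.finite(err))) which.max(err) else which(!is.finite(err))[1]
    stop(sprintf(
      "undistort_normalized: no convergence after %d iterations at point (%.6g, %.6g)",
      max_iter, n[bad, 1], n[bad, 2]), call. = FALSE)
  }
  cbind(x = x, y = y)
}

#' Back-project normalized coordinates onto a fronto-parallel plane
#'
#' Lifts normalized coordinates to 3D camera-frame points on the plane
#' `Z = depth`: `(x * depth, y * depth, depth)`. `depth` is the distance
#' from the camera to the target plane along the optical axis, in mm.
#'
#' @param n Normalized point(s).
#' @param depth Working depth in mm (must be > 0).
#' @return An n x 3 matrix of camera-frame points (mm).
#' @export
backproject_at_depth <- function(n, depth) {
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) || depth <= 0)
    stop("backproject_at_depth: depth must be a single positive number (mm)",
         call. = FALSE)
  n <- as_points(n, 2L, "normalized point")
  cbind(X = n[, 1] * depth, Y = n[, 2] * depth, Z = rep(depth, nrow(n)))
}

#' Transform camera-frame points from the RGB to the IR frame
#'
#' Applies the rigid extrinsic transform: `rotation %*% P + translation`.
#'
#' @param p Camera-frame point(s): length-3 vector or n x 3 matrix (mm).
#' @param ext A [rig_extrinsics()] object.
#' @return An n x 3 matrix of IR-frame points (mm).
#' @export
transform_rgb_to_ir <- function(p, ext) {
  p <- as_points(p, 3L, "3D point")
  out <- p %*% t(ext$rotation)
  out <- sweep(out, 2L, ext$translation, "+")
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Project camera-frame points to pixel coordinates
#'
#' Perspective division `(x, y) = (X/Z, Y/Z)`, forward distortion, then
#' `u = fx * x_d + cx`, `v = fy * y_d + cy`. Points with `Z <= 0` lie
#' behind the camera and raise an error.
#'
#' @param p Camera-frame point(s) (mm); `Z` must be positive.
#' @param intr Channel [intrinsics()].
#' @param d Channel [distortion_coeffs()] (defaults to none).
#' @return An n x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_to_ir <- function(p, intr, d = distortion_coeffs()) {
  p <- as_points(p, 3L, "3D point")
  bad <- which(p[, 3] <= 0)
  if (length(bad))
    stop(sprintf(
      "project_to_ir: point behind camera (Z <= 0) at row %d: (%.6g, %.6g, %.6g)",
      bad[1], p[bad[1], 1], p[bad[1], 2], p[bad[1], 3]), call. = FALSE)
  n <- cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
  nd <- distort_normalized(n, d)
  cbind(u = intr$fx * nd[, 1] + intr$cx,
        v = intr$fy * nd[, 2] + intr$cy)
}

#' Map RGB pixel coordinates into the IR image
#'
#' The per-point cross-modal mapping chain: RGB pixels are normalized and
#' undistorted, back-projected onto the working-depth plane, rigidly
#' transformed into the IR camera frame, and re-projected through the IR
#' intrinsics and distortion. Mapped points falling outside the IR image
#' bounds are returned (not an error) and flagged in the
#' `"out_of_bounds"` attribute.
#'
#' @param p RGB pixel point(s): length-2 vector or n x 2 matrix.
#' @param rig A [camera_rig()].
#' @param depth Working depth in mm (distance from the RGB channel to the
#'   target plane; must be > 0).
#' @return An n x 2 matrix of continuous IR pixel coordinates with a
#'   logical `"out_of_bounds"` attribute (one flag per point).
#' @examples
#' rig <- make_rig(scene_spec("parallax", seed = 1))
#' map_pixel_rgb_to_ir(c(1344, 760), rig, depth = 600)
#' @export
map_pixel_rgb_to_ir <- function(p, rig, depth) {
  n <- normalize_pixel(p, rig$rgb$intrinsics)
  n <- undistort_normalized(n, rig$rgb$distortion)
  P <- backproject_at_depth(n, depth)
  P <- transform_rgb_to_ir(P, rig$extrinsics)
  q <- project_to_ir(P, rig$ir$intrinsics, rig$ir$distortion)
  w <- rig$ir$intrinsics$width; h <- rig$ir$intrinsics$height
  oob <- q[, 1] < 0 | q[, 1] > (w - 1) | q[, 2] < 0 | q[, 2] > (h - 1)
  attr(q, "out_of_bounds") <- unname(oob)
  q
}
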