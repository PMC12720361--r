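# Synthetic dual-channel scenes: seeded rigs, checkerboard corner
# observations, parametric head-region masks, ground-truth IR masks by
# direct projection of the generating geometry, and region-dependent
# temperature fields. This module is the test bed for every other module:
# ground-truth IR masks are computed from the generating polygons only
# (never via the contour-mapping path), so agreement between the two
# routes is a test result, not an input.

# Evaluate expr with a temporary RNG state seeded from `seed`.
.with_seed <- function(seed, expr) {
  if (is.null(seed))
    stop("a seed is required for randomized synthetic output", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic scene specification
#'
#' Parameters of a synthetic dual-channel scene. Presets:
#' \describe{
#'   \item{`"paper-like"`}{RGB 2688 x 1520 (f ~ 2400 px), IR 384 x 288
#'     (f ~ 588 px, the optics of a 17 um-pitch thermal core with a 10 mm
#'     lens), ~47 mm X-dominant baseline, mild Brown-Conrady distortion,
#'     600 mm working depth. Per-seed jitter on intrinsics, baseline and
#'     head placement.}
#'   \item{`"reduced"`}{Quarter-resolution version (672 x 380 / 96 x 72)
#'     preserving the angular geometry (focal lengths scaled by 1/4) for
#'     fast sweeps.}
#'   \item{`"parallax"`}{Zero distortion in both channels, identity
#'     rotation and a pure X baseline: the configuration in which depth
#'     mis-specification produces the closed-form parallax offset
#'     `f_x_ir * b * |1/d - 1/d'|`.}
#'   \item{`"zero-baseline"`}{Identity extrinsics and zero distortion:
#'     mapping is depth-independent.}
#' }
#'
#' @param preset One of `"paper-like"`, `"reduced"`, `"parallax"`,
#'   `"zero-baseline"`.
#' @param seed Integer seed (mandatory; every randomized output is a pure
#'   function of the spec and this seed).
#' @param depth Working depth in mm (default 600).
#' @param region_temp_c Named per-region mean temperatures (degrees C).
#'   Defaults place comb/wattle warm and the keratinized beak cool.
#' @param bg_temp_range_c Background field range (low-order 2-D
#'   polynomial).
#' @param noise_sd_c Per-pixel temperature noise sd (degrees C).
#' @param head_scale Global scale factor for the head-region templates.
#' @param jitter Logical: apply per-seed jitter to rig and head placement.
#' @param render_color Render the color-coded RGB image (needed by
#'   [reference_segmenter()]).
#' @param ... Field overrides (matched by name against the spec list).
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(preset = c("paper-like", "reduced", "parallax",
                                  "zero-baseline"),
                       seed = NULL, depth = 600,
                       region_temp_c = c(comb = 39.5, eye = 40.5,
                                         beak = 33.0, wattle = 39.0),
                       bg_temp_range_c = c(26, 30),
                       noise_sd_c = 0.3,
                       head_scale = 1,
                       jitter = TRUE,
                       render_color = TRUE, ...) {
  preset <- match.arg(preset)
  sc <- if (preset == "reduced") 0.25 else 1
  spec <- list(
    preset = preset, seed = seed, depth = depth,
    rgb_size = c(2688, 1520) * sc,
    ir_size = c(384, 288) * sc,
    f_rgb = 2400 * sc, f_ir = 588 * sc,
    baseline_mm = c(47, 1.5, -2.5),
    rot_deg = c(0.15, -0.45, 0.1),
    dist_rgb = c(k1 = -0.09, k2 = 0.035, p1 = 3e-4, p2 = -2e-4, k3 = 0),
    dist_ir = c(k1 = -0.18, k2 = 0.05, p1 = -4e-4, p2 = 2e-4, k3 = 0),
    region_temp_c = region_temp_c,
    bg_temp_range_c = bg_temp_range_c,
    noise_sd_c = noise_sd_c,
    head_scale = head_scale,
    head_jitter_mm = 15, head_rot_jitter_deg = 10,
    head_scale_jitter = 0.1,
    template_style = "head",
    max_region_overlap = 0.05,
    jitter = jitter,
    render_color = render_color)
  if (preset %in% c("parallax", "zero-baseline")) {
    spec$dist_rgb[] <- 0
    spec$dist_ir[] <- 0
    spec$rot_deg <- c(0, 0, 0)
    spec$baseline_mm <- if (preset == "parallax") c(47, 0, 0) else c(0, 0, 0)
    spec$jitter <- FALSE
    # oracle geometry, not biology: smooth enlarged region blobs keep IR
    # mask-centroid quantization well below the closed-form signal
    spec$template_style <- "blob"
    spec$head_scale <- 2 * spec$head_scale
    spec$head_rot_jitter_deg <- 45
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(spec))
      stop("scene_spec: unknown field: ", nm, call. = FALSE)
    spec[[nm]] <- dots[[nm]]
  }
  if (any(spec$ir_size <= 0) || any(spec$rgb_size <= 0))
    stop("scene_spec: resolutions must be positive", call. = FALSE)
  if (spec$noise_sd_c < 0)
    stop("scene_spec: noise sd must be >= 0", call. = FALSE)
  structure(spec, class = "scene_spec")
}

#' Generate a synthetic dual-channel rig
#'
#' Deterministic for a given spec and seed. The `"paper-like"` preset
#' uses the printed channel resolutions (RGB 2688 x 1520, IR 384 x 288)
#' and a nonzero X-dominant baseline; per-seed jitter perturbs focal
#' lengths, principal points, baseline and distortion by small realistic
#' amounts unless `spec$jitter` is `FALSE`.
#'
#' @param spec A [scene_spec()].
#' @return A [camera_rig()].
#' @export
make_rig <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, {
    jf <- function(x, rel) if (spec$jitter) x * (1 + stats::rnorm(length(x), 0, rel)) else x
    ja <- function(x, abs_) if (spec$jitter) x + stats::rnorm(length(x), 0, abs_) else x
    f_rgb <- jf(spec$f_rgb, 0.003)
    f_ir <- jf(spec$f_ir, 0.003)
    c_rgb <- ja((spec$rgb_size - 1) / 2, 0.002 * spec$rgb_size[1])
    c_ir <- ja((spec$ir_size - 1) / 2, 0.002 * spec$ir_size[1])
    dr <- ja(spec$dist_rgb, c(0.005, 0.002, 5e-5, 5e-5, 0))
    di <- ja(spec$dist_ir, c(0.008, 0.003, 5e-5, 5e-5, 0))
    tvec <- ja(spec$baseline_mm, c(0.5, 0.3, 0.5))
    rdeg <- ja(spec$rot_deg, 0.05)
    R <- rodrigues_to_rotation(rdeg * pi / 180)
    camera_rig(
      rgb = list(intrinsics = intrinsics(f_rgb, f_rgb * (1 + if (spec$jitter) stats::rnorm(1, 0, 1e-3) else 0),
                                         c_rgb[1], c_rgb[2],
                                         spec$rgb_size[1], spec$rgb_size[2]),
                 distortion = do.call(distortion_coeffs, as.list(dr))),
      ir = list(intrinsics = intrinsics(f_ir, f_ir * (1 + if (spec$jitter) stats::rnorm(1, 0, 1e-3) else 0),
                                        c_ir[1], c_ir[2],
                                        spec$ir_size[1], spec$ir_size[2]),
                distortion = do.call(distortion_coeffs, as.list(di))),
      extrinsics = rig_extrinsics(R, tvec))
  })
}

# Head-region polygon templates in head-local plane coordinates (mm,
# x right, y down), disjoint by construction. Style "head": serrated comb
# crown above, large eye, beak wedge to the right, wattle lobe below.
# Style "blob": smooth ellipses of the same layout -- used by the
# closed-form oracle presets, where straight axis-aligned boundary runs
# would quantize mask centroids coherently across rows.
.head_templates <- function(style = c("head", "blob")) {
  style <- match.arg(style)
  circle <- function(cx, cy, rx, ry, n = 24) {
    a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(cx + rx * cos(a), cy + ry * sin(a))
  }
  if (style == "blob")
    return(list(
      comb = circle(-2, -36, 26, 13, n = 32),
      eye = circle(0, -6, 9, 9),
      beak = circle(29, 0, 15, 8, n = 24),
      wattle = circle(0, 24, 11, 16, n = 24)))
  list(
    comb = cbind(
      c(-30, -31, -25, -18, -11, -3, 5, 13, 20, 26, 28),
      c(-22, -32, -44, -32, -48, -33, -49, -32, -44, -30, -22)),
    eye = circle(0, -6, 9, 9),
    beak = cbind(c(12, 34, 47, 44, 28, 12), c(-9, -7, -1, 5, 9, 9)),
    wattle = circle(0, 24, 11, 16, n = 20))
}

#' Generate synthetic checkerboard corner observations
#'
#' Randomly poses a planar board in front of the rig (varied tilts and
#' distances), projects the inner corners through both channels
#' (including distortion), and keeps only poses whose full corner grid is
#' visible in both frames (rejected poses are resampled; failure to place
#' a visible pose in 1000 attempts is an error). Optional i.i.d. Gaussian
#' pixel noise is added after the visibility test.
#'
#' @param rig A [camera_rig()].
#' @param board A [checkerboard_spec()] (default: 15 x 16 squares of
#'   25 mm).
#' @param n_poses Number of poses (>= 1).
#' @param noise_sd_px Corner noise sd in pixels.
#' @param seed Integer seed.
#' @return A [corner_observations()].
#' @export
make_checkerboard_observations <- function(rig,
                                           board = checkerboard_spec(15, 16, 25),
                                           n_poses = 10, noise_sd_px = 0,
                                           seed = NULL) {
  stopifnot(n_poses >= 1)
  bc <- board_corners(board)
  XY <- cbind(bc$X, bc$Y)
  XY <- sweep(XY, 2, colMeans(XY))          # pose about the board center
  margin <- 5
  w_rgb <- rig$rgb$intrinsics$width; h_rgb <- rig$rgb$intrinsics$height
  w_ir <- rig$ir$intrinsics$width; h_ir <- rig$ir$intrinsics$height
  # distance range scaled so the board can fit the narrower (IR) frame
  # board distances chosen so the full grid can fit the narrower (IR)
  # frame; tilts are bounded away from frontal (near-frontal poses carry
  # little information about principal points and distortion)
  span <- max(board$squares_cols, board$squares_rows) * board$square_size
  z_lo <- 1.15 * span * rig$ir$intrinsics$fy / h_ir
  z_hi <- 1.7 * z_lo
  .with_seed(seed, {
    out <- vector("list", n_poses)
    for (i in seq_len(n_poses)) {
      placed <- FALSE
      for (attempt in 1:1000) {
        tilt <- stats::runif(2, 12, 35) * sample(c(-1, 1), 2, TRUE) * pi / 180
        roll <- stats::runif(1, -pi, pi)
        R <- rodrigues_to_rotation(c(tilt[1], 0, 0)) %*%
          rodrigues_to_rotation(c(0, tilt[2], 0)) %*%
          rodrigues_to_rotation(c(0, 0, roll))
        z <- stats::runif(1, z_lo, z_hi)
        t <- c(stats::runif(2, -0.1, 0.1) * z, z)
        P <- cbind(XY, 0) %*% t(R)
        P <- sweep(P, 2, t, "+")
        uv_rgb <- tryCatch(
          project_to_ir(P, rig$rgb$intrinsics, rig$rgb$distortion),
          error = function(e) NULL)
        P_ir <- transform_rgb_to_ir(P, rig$extrinsics)
        uv_ir <- tryCatch(
          project_to_ir(P_ir, rig$ir$intrinsics, rig$ir$distortion),
          error = function(e) NULL)
        ok <- !is.null(uv_rgb) && !is.null(uv_ir) &&
          all(uv_rgb[, 1] >= margin & uv_rgb[, 1] <= w_rgb - 1 - margin &
                uv_rgb[, 2] >= margin & uv_rgb[, 2] <= h_rgb - 1 - margin) &&
          all(uv_ir[, 1] >= margin & uv_ir[, 1] <= w_ir - 1 - margin &
                uv_ir[, 2] >= margin & uv_ir[, 2] <= h_ir - 1 - margin)
        if (ok) {
          if (noise_sd_px > 0) {
            uv_rgb <- uv_rgb + stats::rnorm(length(uv_rgb), 0, noise_sd_px)
            uv_ir <- uv_ir + stats::rnorm(length(uv_ir), 0, noise_sd_px)
          }
          out[[i]] <- rbind(
            data.frame(pose_id = i, channel = "rgb",
                       board_i = bc$board_i, board_j = bc$board_j,
                       u = uv_rgb[, 1], v = uv_rgb[, 2]),
            data.frame(pose_id = i, channel = "ir",
                       board_i = bc$board_i, board_j = bc$board_j,
                       u = uv_ir[, 1], v = uv_ir[, 2]))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("make_checkerboard_observations: could not place a fully visible pose in 1000 attempts",
             call. = FALSE)
    }
    corner_observations(do.call(rbind, out), board)
  })
}

#' Generate a synthetic scene
#'
#' Places the four head-region polygon templates on the working-depth
#' plane (with per-seed placement jitter), renders the RGB label mask and
#' color-coded image by projecting the generating polygons through the
#' RGB channel, builds ground-truth IR region masks by projecting the
#' same polygons directly through the extrinsics and IR channel (never
#' via the contour-mapping path), and synthesizes the IR temperature
#' matrix (smooth polynomial background outside regions; each region at
#' its generating mean temperature; i.i.d. Gaussian pixel noise).
#'
#' @param spec A [scene_spec()] (seed mandatory).
#' @param rig Optional pre-built [camera_rig()]; defaults to
#'   `make_rig(spec)`.
#' @return An object of class `"synthetic_scene"`: `rgb_mask`
#'   ([label_mask()]), `rgb_color` (h x w x 3 array or `NULL`),
#'   `ir_gt` ([roi_set()]), `temps` ([temperature_matrix()]), `rig`,
#'   `plane_polygons_mm` (generating polygons, RGB-camera plane
#'   coordinates), `spec`, `seed`.
#' @export
make_scene <- function(spec, rig = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(rig)) rig <- make_rig(spec)
  .with_seed(spec$seed + 1000003L, {
    w_rgb <- rig$rgb$intrinsics$width; h_rgb <- rig$rgb$intrinsics$height
    w_ir <- rig$ir$intrinsics$width; h_ir <- rig$ir$intrinsics$height
    depth <- spec$depth
    # head placement on the depth plane, in RGB camera-frame mm
    # head placement jitter is per-seed regardless of rig jitter (exact
    # rigs still see varied scenes); set the jitter fields to 0 to pin it
    s <- spec$head_scale *
      (1 + stats::runif(1, -1, 1) * spec$head_scale_jitter)
    th <- stats::runif(1, -1, 1) * spec$head_rot_jitter_deg * pi / 180
    ctr <- stats::runif(2, -1, 1) * spec$head_jitter_mm
    rot2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    polys <- lapply(.head_templates(spec$template_style), function(p)
      sweep(s * (p %*% t(rot2)), 2, ctr, "+"))

    project_poly <- function(p, channel) {
      P <- cbind(p, depth)
      if (channel == "ir") P <- transform_rgb_to_ir(P, rig$extrinsics)
      ch <- rig[[channel]]
      project_to_ir(P, ch$intrinsics, ch$distortion)
    }

    # RGB label mask: smallest structures written last win ties
    tab <- region_labels()
    grid <- matrix(0L, h_rgb, w_rgb)
    masks_rgb <- list()
    for (r in c("comb", "wattle", "beak", "eye")) {
      m <- rasterize_contour(project_poly(polys[[r]], "rgb"), h_rgb, w_rgb)
      masks_rgb[[r]] <- m
      grid[m] <- tab$code[tab$name == r]
    }
    ov <- 0
    for (a in head_regions()) for (b in head_regions())
      if (a < b && any(masks_rgb[[a]] & masks_rgb[[b]]))
        ov <- max(ov, sum(masks_rgb[[a]] & masks_rgb[[b]]) /
                    min(sum(masks_rgb[[a]]), sum(masks_rgb[[b]])))
    if (ov > spec$max_region_overlap)
      warning(sprintf(
        "make_scene: region templates overlap by fraction %.3f (> %.3f)",
        ov, spec$max_region_overlap), call. = FALSE)
    rgb_mask <- label_mask(grid, frame = "rgb")

    # ground-truth IR masks by direct projection of the generating polygons
    gt_masks <- lapply(head_regions(), function(r)
      rasterize_contour(project_poly(polys[[r]], "ir"), h_ir, w_ir))
    names(gt_masks) <- head_regions()
    ir_gt <- roi_set(gt_masks, depth_used = depth)

    # temperature field
    uu <- matrix(rep(0:(w_ir - 1), each = h_ir), h_ir, w_ir) / max(w_ir - 1, 1)
    vv <- matrix(rep(0:(h_ir - 1), times = w_ir), h_ir, w_ir) / max(h_ir - 1, 1)
    lo <- spec$bg_temp_range_c[1]; hi <- spec$bg_temp_range_c[2]
    cf <- stats::runif(3)
    bg_raw <- cf[1] * uu + cf[2] * vv + cf[3] * uu * vv
    rng <- range(bg_raw)
    temps <- lo + (bg_raw - rng[1]) / max(rng[2] - rng[1], 1e-12) * (hi - lo)
    for (r in head_regions())
      temps[gt_masks[[r]]] <- spec$region_temp_c[[r]]
    if (spec$noise_sd_c > 0)
      temps <- temps + stats::rnorm(length(temps), 0, spec$noise_sd_c)
    tm <- temperature_matrix(temps, frame_id = sprintf("scene-%d", spec$seed),
                             timestamp = "16:30")

    rgb_color <- NULL
    if (spec$render_color) {
      idx <- match(as.vector(rgb_mask$grid), tab$code)
      rgb_color <- array(0, dim = c(h_rgb, w_rgb, 3))
      rgb_color[, , 1] <- tab$r[idx]
      rgb_color[, , 2] <- tab$g[idx]
      rgb_color[, , 3] <- tab$b[idx]
    }

    structure(list(rgb_mask = rgb_mask, rgb_color = rgb_color,
                   ir_gt = ir_gt, temps = tm, rig = rig,
                   plane_polygons_mm = polys, spec = spec,
                   seed = spec$seed),
              class = "synthetic_scene")
  })
}

#' Write a synthetic scene to a directory
#'
#' Writes `rig.json`, `rgb_mask.png`, `rgb_color.png` (if rendered),
#' `ir_gt_<region>.png`, `temps.csv` and a `scene.json` metadata sidecar
#' (preset, seed, depth, generating temperatures).
#'
#' @param scene A `"synthetic_scene"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_camera_rig(scene$rig, file.path(dir, "rig.json"))
  write_label_mask(scene$rgb_mask, file.path(dir, "rgb_mask.png"))
  if (!is.null(scene$rgb_color))
    png::writePNG(scene$rgb_color / 255, file.path(dir, "rgb_color.png"))
  for (r in names(scene$ir_gt$masks))
    png::writePNG(scene$ir_gt$masks[[r]] * 1,
                  file.path(dir, paste0("ir_gt_", r, ".png")))
  write_temperature_matrix(scene$temps, file.path(dir, "temps.csv"))
  meta <- list(preset = scene$spec$preset, seed = scene$seed,
               depth_mm = scene$spec$depth,
               region_temp_c = as.list(scene$spec$region_temp_c),
               noise_sd_c = scene$spec$noise_sd_c)
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
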