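# Mask-level cross-modal mapping: contours are extracted from the RGB label
# mask, every contour vertex is pushed through the per-point mapping chain,
# and the mapped contours are closed and filled on the IR pixel grid.

# 8-connected component labelling restricted to TRUE pixels of `bin`.
# Returns an integer matrix (0 = background, 1..n = component id).
.connected_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  remaining <- which(bin)
  cur <- 0L
  while (length(remaining)) {
    seed <- remaining[1]
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L
      c <- (frontier - 1L) %/% H + 1L
      nxt <- integer(0)
      for (dc in -1:1) for (dr in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- c + dc
        keep <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
        if (!any(keep)) next
        idx <- (c2[keep] - 1L) * H + r2[keep]
        idx <- idx[bin[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

# Moore-neighbor boundary tracing of one connected component (TRUE pixels of
# `bin`), started at its topmost-leftmost pixel. Returns the ordered outer
# boundary as an n x 2 matrix of 0-based (u, v) pixel centers, oriented so
# the shoelace signed area in the (u, v) plane is positive
# ("counter-clockwise" with respect to the u/v axes).
.trace_boundary <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  idx <- which(bin)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  o <- order(r, c)
  sr <- r[o[1]]; sc <- c[o[1]]
  inreg <- function(rr, cc)
    rr >= 1L && rr <= H && cc >= 1L && cc <= W && bin[rr, cc]
  # Moore neighborhood, clockwise starting at W: (dc, dr)
  du <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dv <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dir_index <- function(dc, dr) which(du == dc & dv == dr)
  p <- c(sr, sc)
  b0 <- c(sr, sc - 1L)            # west of start; outside by scan order
  b <- b0
  pts <- matrix(c(sc - 1L, sr - 1L), 1L, 2L)
  max_steps <- 8L * length(idx) + 8L
  for (step in seq_len(max_steps)) {
    start <- dir_index(b[2] - p[2], b[1] - p[1])
    prev <- b
    found <- FALSE
    for (k in 1:8) {
      di <- ((start - 1L + k) %% 8L) + 1L
      q <- c(p[1] + dv[di], p[2] + du[di])
      if (inreg(q[1], q[2])) {
        b <- prev
        p <- q
        found <- TRUE
        break
      }
      prev <- q
    }
    if (!found) break                       # isolated pixel
    if (p[1] == sr && p[2] == sc && b[1] == b0[1] && b[2] == b0[2]) break
    pts <- rbind(pts, c(p[2] - 1L, p[1] - 1L))
  }
  # orient counter-clockwise (positive shoelace area in the (u, v) plane)
  if (nrow(pts) >= 3L) {
    u <- pts[, 1]; v <- pts[, 2]
    a2 <- sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v)
    if (a2 < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  }
  colnames(pts) <- c("u", "v")
  pts
}

#' Extract region contours from a label mask
#'
#' Finds the 8-connected components of one region's pixels and traces the
#' outer boundary of each component whose area is at least `min_area`
#' pixels (small components are treated as segmentation specks and
#' dropped). Contour points are 0-based pixel centers ordered
#' counter-clockwise (positive shoelace area in the `(u, v)` plane);
#' interior holes are not traced.
#'
#' @param mask A [label_mask()].
#' @param region Region name or code (see [region_labels()]).
#' @param min_area Minimum component pixel area (default 5).
#' @return A list of contours, each a list with elements `points`
#'   (n x 2 matrix of `(u, v)`) and `region` (name). Empty list if the
#'   region is absent.
#' @export
extract_contours <- function(mask, region, min_area = 5L) {
  stopifnot(inherits(mask, "label_mask"))
  reg <- resolve_region(region)
  bin <- mask$grid == reg$code
  if (!any(bin)) return(list())
  lab <- .connected_components(bin)
  ncomp <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = ncomp)
  out <- list()
  for (i in seq_len(ncomp)) {
    if (areas[i] < min_area) next
    pts <- .trace_boundary(lab == i)
    out[[length(out) + 1L]] <- structure(
      list(points = pts, region = reg$name), class = "contour")
  }
  out
}

#' Map a contour from the RGB frame into the IR frame
#'
#' Applies [map_pixel_rgb_to_ir()] to every contour vertex, preserving
#' point order. The returned contour has continuous IR pixel coordinates;
#' vertices outside the IR bounds are kept and flagged via the
#' `"out_of_bounds"` attribute on `points`.
#'
#' @param contour A contour from [extract_contours()].
#' @param rig A [camera_rig()].
#' @param depth Working depth in mm (> 0).
#' @return A contour in the IR frame.
#' @export
map_contour <- function(contour, rig, depth) {
  pts <- map_pixel_rgb_to_ir(contour$points, rig, depth)
  structure(list(points = pts, region = contour$region), class = "contour")
}

#' Rasterize a closed contour onto a pixel grid
#'
#' A pixel `(u, v)` is set iff its center lies inside the closed polygon
#' under the nonzero winding rule; centers lying exactly on a polygon edge
#' count as inside. The polygon is implicitly closed (last vertex connects
#' to the first) and clipped to the image bounds. Contours with fewer than
#' 3 points are degenerate: an empty mask is returned with a warning.
#'
#' @param contour A contour (or a bare n x 2 matrix of `(u, v)` points).
#' @param height,width Output grid size in pixels.
#' @return A `height x width` logical matrix.
#' @export
rasterize_contour <- function(contour, height, width) {
  pts <- if (inherits(contour, "contour")) contour$points else
    as_points(contour, 2L, "contour point")
  mask <- matrix(FALSE, height, width)
  if (is.null(pts) || nrow(pts) < 3L) {
    warning("rasterize_contour: degenerate contour (< 3 points); empty mask",
            call. = FALSE)
    return(mask)
  }
  u0 <- max(0L, floor(min(pts[, 1])))
  u1 <- min(width - 1L, ceiling(max(pts[, 1])))
  v0 <- max(0L, floor(min(pts[, 2])))
  v1 <- min(height - 1L, ceiling(max(pts[, 2])))
  if (u0 > u1 || v0 > v1) return(mask)

  tol <- 1e-9 * max(1, max(abs(pts)))
  n <- nrow(pts)
  ax <- pts[, 1]; ay <- pts[, 2]
  bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
  keep <- !(ax == bx & ay == by)            # drop zero-length edges
  ax <- ax[keep]; ay <- ay[keep]; bx <- bx[keep]; by <- by[keep]
  dx <- bx - ax; dy <- by - ay
  L <- sqrt(dx^2 + dy^2)
  ylo <- pmin(ay, by); yhi <- pmax(ay, by)
  xlo <- pmin(ax, bx); xhi <- pmax(ax, bx)
  us <- u0:u1
  nu <- length(us)

  # scanline nonzero-winding fill: for pixel row v, the winding number at
  # column u is (# upward edge crossings right of u) - (# downward ones),
  # with the half-open vertex rule ay <= v < by; centers within tol of an
  # edge are marked inside regardless of winding
  for (v in v0:v1) {
    act <- which(ylo - tol <= v & v <= yhi + tol)
    if (!length(act)) next
    row_in <- rep(FALSE, nu)
    cr_x <- numeric(0); cr_w <- integer(0)
    for (e in act) {
      if (ay[e] != by[e]) {
        # crossing of the horizontal line at v (for winding)
        if (ay[e] <= v && v < by[e]) {
          cr_x <- c(cr_x, ax[e] + dx[e] * (v - ay[e]) / dy[e])
          cr_w <- c(cr_w, 1L)
        } else if (by[e] <= v && v < ay[e]) {
          cr_x <- c(cr_x, ax[e] + dx[e] * (v - ay[e]) / dy[e])
          cr_w <- c(cr_w, -1L)
        }
        # on-edge band: |is_left| <= L * tol is an interval in u
        uc <- ax[e] + dx[e] * (v - ay[e]) / dy[e]
        hw <- L[e] * tol / abs(dy[e])
        lo <- max(uc - hw, xlo[e] - tol)
        hi <- min(uc + hw, xhi[e] + tol)
      } else {
        if (abs(v - ay[e]) > tol) next
        lo <- xlo[e] - tol
        hi <- xhi[e] + tol
      }
      if (lo <= hi) {
        i0 <- max(1L, as.integer(ceiling(lo - u0 + 1)))
        i1 <- min(nu, as.integer(floor(hi - u0 + 1)))
        if (i0 <= i1) row_in[i0:i1] <- TRUE
      }
    }
    if (length(cr_x)) {
      o <- order(cr_x)
      xs <- cr_x[o]
      # wn(u) = sum of weights of crossings with x > u
      tail_sum <- rev(cumsum(rev(cr_w[o])))
      k <- findInterval(us, xs)             # crossings with x <= u
      wn <- ifelse(k < length(xs), tail_sum[k + 1L], 0L)
      row_in <- row_in | (wn != 0L)
    }
    mask[v + 1L, us[row_in] + 1L] <- TRUE
  }
  mask
}

# Reference implementation of the same fill rule: per-pixel winding number
# accumulated edge-by-edge. Quadratic in (pixels x edges); retained as an
# independent oracle for the scanline path.
.rasterize_winding_matrix <- function(pts, height, width) {
  pts <- as_points(pts, 2L, "contour point")
  mask <- matrix(FALSE, height, width)
  if (nrow(pts) < 3L) return(mask)
  u0 <- max(0L, floor(min(pts[, 1])))
  u1 <- min(width - 1L, ceiling(max(pts[, 1])))
  v0 <- max(0L, floor(min(pts[, 2])))
  v1 <- min(height - 1L, ceiling(max(pts[, 2])))
  if (u0 > u1 || v0 > v1) return(mask)
  px <- rep(u0:u1, each = v1 - v0 + 1L)
  py <- rep(v0:v1, times = u1 - u0 + 1L)
  wn <- integer(length(px))
  onedge <- logical(length(px))
  tol <- 1e-9 * max(1, max(abs(pts)))
  n <- nrow(pts)
  ax <- pts[, 1]; ay <- pts[, 2]
  bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
  for (e in seq_len(n)) {
    if (ax[e] == bx[e] && ay[e] == by[e]) next
    is_left <- (bx[e] - ax[e]) * (py - ay[e]) - (px - ax[e]) * (by[e] - ay[e])
    L <- sqrt((bx[e] - ax[e])^2 + (by[e] - ay[e])^2)
    onedge <- onedge | (abs(is_left) <= L * tol &
      px >= min(ax[e], bx[e]) - tol & px <= max(ax[e], bx[e]) + tol &
      py >= min(ay[e], by[e]) - tol & py <= max(ay[e], by[e]) + tol)
    wn <- wn + as.integer(ay[e] <= py & py < by[e] & is_left > 0) -
      as.integer(by[e] <= py & py < ay[e] & is_left < 0)
  }
  inside <- wn != 0L | onedge
  mask[cbind(py + 1L, px + 1L)[inside, , drop = FALSE]] <- TRUE
  mask
}

#' Map an RGB label mask to per-region IR masks
#'
#' The mask-level cross-modal mapping: for each of the four head regions,
#' extracts the region's component contours from the RGB mask, maps every
#' contour vertex through the per-point chain at the given working depth,
#' and rasterizes the mapped contours (union over components) on the IR
#' pixel grid. Regions absent from the input yield empty masks.
#'
#' @param mask A [label_mask()] in the `"rgb"` frame.
#' @param rig A [camera_rig()].
#' @param depth Working depth in mm (> 0).
#' @param min_area Minimum RGB component area in pixels (see
#'   [extract_contours()]).
#' @return A [roi_set()] with `depth_used = depth` and per-region
#'   out-of-bounds vertex fractions.
#' @examples
#' scene <- make_scene(scene_spec("reduced", seed = 1))
#' roi <- map_label_mask(scene$rgb_mask, scene$rig, depth = 600)
#' @export
map_label_mask <- function(mask, rig, depth, min_area = 5L) {
  stopifnot(inherits(mask, "label_mask"))
  if (mask$frame != "rgb")
    stop("map_label_mask: mask must be in the 'rgb' frame", call. = FALSE)
  .map_frame_contours(.frame_contours(mask, min_area), rig, depth)
}

# Pre-extract all head-region contours of a frame once (the expensive,
# depth-independent half of map_label_mask; reused across sweep depths).
.frame_contours <- function(mask, min_area = 5L) {
  lapply(setNames(nm = head_regions()), function(r)
    extract_contours(mask, r, min_area = min_area))
}

.map_frame_contours <- function(fc, rig, depth) {
  if (depth <= 0)
    stop("map_label_mask: depth must be positive (mm)", call. = FALSE)
  h <- rig$ir$intrinsics$height
  w <- rig$ir$intrinsics$width
  masks <- list()
  oob <- c()
  for (r in head_regions()) {
    m <- matrix(FALSE, h, w)
    n_pts <- 0L; n_oob <- 0L
    for (ct in fc[[r]]) {
      mc <- map_contour(ct, rig, depth)
      fl <- attr(mc$points, "out_of_bounds")
      n_pts <- n_pts + nrow(mc$points)
      n_oob <- n_oob + sum(fl)
      m <- m | rasterize_contour(mc, h, w)
    }
    masks[[r]] <- m
    oob[r] <- if (n_pts > 0L) n_oob / n_pts else 0
  }
  roi_set(masks, depth_used = depth, out_of_bounds_fraction = oob)
}
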