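#' Checkerboard specification
#'
#' A planar calibration board described by its square counts and square
#' size. The detected features are the inner corners, a grid of
#' `(squares_cols - 1) x (squares_rows - 1)` points.
#'
#' @param squares_cols,squares_rows Number of squares along each board
#'   axis (>= 2).
#' @param square_size Square edge length in mm.
#' @return An object of class `"checkerboard_spec"`.
#' @examples
#' checkerboard_spec(15, 16, 25)  # 14 x 15 = 210 inner corners
#' @export
checkerboard_spec <- function(squares_cols, squares_rows, square_size) {
  if (squares_cols < 2 || squares_rows < 2)
    stop("checkerboard_spec: need at least 2 squares per side", call. = FALSE)
  if (square_size <= 0)
    stop("checkerboard_spec: square_size must be positive (mm)", call. = FALSE)
  structure(list(squares_cols = as.integer(squares_cols),
                 squares_rows = as.integer(squares_rows),
                 square_size = as.numeric(square_size)),
            class = "checkerboard_spec")
}

#' Inner-corner board coordinates
#'
#' Planar (Z = 0) board-frame coordinates of the inner corners, in mm,
#' together with their integer grid indices. Row-major over `board_j`
#' then `board_i`, matching the ordering used by corner observations.
#'
#' @param board A [checkerboard_spec()].
#' @return A data.frame with columns `board_i`, `board_j`, `X`, `Y`.
#' @export
board_corners <- function(board) {
  ni <- board$squares_cols - 1L
  nj <- board$squares_rows - 1L
  g <- expand.grid(board_i = seq_len(ni) - 1L, board_j = seq_len(nj) - 1L)
  g <- g[order(g$board_j, g$board_i), , drop = FALSE]
  rownames(g) <- NULL
  g$X <- g$board_i * board$square_size
  g$Y <- g$board_j * board$square_size
  g
}

#' Corner observations container
#'
#' Detected inner-corner pixel coordinates for a set of board poses seen
#' simultaneously by both channels. The same board indices must appear,
#' without duplicates, for every (pose, channel) combination.
#'
#' @param corners A data.frame with columns `pose_id`, `channel`
#'   (`"rgb"` or `"ir"`), `board_i`, `board_j`, `u`, `v`.
#' @param board The [checkerboard_spec()] the corners belong to.
#' @return An object of class `"corner_observations"`.
#' @export
corner_observations <- function(corners, board) {
  need <- c("pose_id", "channel", "board_i", "board_j", "u", "v")
  if (!all(need %in% names(corners)))
    stop("corner_observations: corners must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(corners$channel %in% c("rgb", "ir")))
    stop("corner_observations: channel must be 'rgb' or 'ir'", call. = FALSE)
  key <- interaction(corners$pose_id, corners$channel, drop = TRUE)
  dup <- vapply(split(corners, key), function(d)
    anyDuplicated(d[, c("board_i", "board_j")]) > 0, logical(1))
  if (any(dup))
    stop("corner_observations: duplicate board indices within a pose", call. = FALSE)
  structure(list(corners = corners, board = board,
                 n_poses = length(unique(corners$pose_id))),
            class = "corner_observations")
}

# ---- rotation parameterization -------------------------------------------

#' Rodrigues rotation conversions
#'
#' `rodrigues_to_rotation()` maps an axis-angle 3-vector (angle = vector
#' norm, radians) to a 3x3 rotation matrix; `rotation_to_rodrigues()` is
#' its inverse.
#'
#' @param r Axis-angle 3-vector.
#' @param R 3x3 rotation matrix.
#' @return A rotation matrix, resp. an axis-angle vector.
#' @export
rodrigues_to_rotation <- function(r) {
  theta <- sqrt(sum(r^2))
  if (theta < 1e-12) {
    K <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
    return(diag(3) + K)
  }
  k <- r / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' @rdname rodrigues_to_rotation
#' @export
rotation_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near-pi: axis from the symmetric part
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    # fix signs using off-diagonals
    i <- which.max(k)
    if (i == 1) { k[2] <- A[1, 2] / k[1]; k[3] <- A[1, 3] / k[1] }
    if (i == 2) { k[1] <- A[1, 2] / k[2]; k[3] <- A[2, 3] / k[2] }
    if (i == 3) { k[1] <- A[1, 3] / k[3]; k[2] <- A[2, 3] / k[3] }
    return(theta * k / sqrt(sum(k^2)))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  theta * v / (2 * sin(theta))
}

# Nearest rotation matrix (Frobenius) via SVD, det +1 enforced.
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

# ---- homography + Zhang closed form --------------------------------------

# Similarity normalization for DLT conditioning.
.normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

# Plane-to-image homography by normalized DLT. src, dst: n x 2.
.homography_dlt <- function(src, dst) {
  Ts <- .normalizing_transform(src)
  Td <- .normalizing_transform(dst)
  hs <- cbind(src, 1) %*% t(Ts)
  hd <- cbind(dst, 1) %*% t(Td)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  x <- hs[, 1]; y <- hs[, 2]
  u <- hd[, 1]; v <- hd[, 2]
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  h <- svd(A, nu = 0)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Td) %*% H %*% Ts
  H / H[3, 3]
}

# Zhang closed-form intrinsics from a list of homographies.
# Returns list(K, cond) where cond is the conditioning ratio of the
# constraint matrix (used for degeneracy warnings).
.zhang_intrinsics <- function(Hs) {
  vij <- function(H, i, j)
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  sv <- svd(V, nu = 0)
  b <- sv$v[, 6]
  solve_b <- function(b) {
    B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
    den <- B11 * B22 - B12^2
    v0 <- (B12 * B13 - B11 * B23) / den
    lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
    list(B11 = B11, B12 = B12, den = den, v0 = v0, lam = lam,
         B13 = B13)
  }
  s <- solve_b(b)
  if (s$lam / s$B11 < 0) { b <- -b; s <- solve_b(b) }
  alpha <- sqrt(s$lam / s$B11)
  beta <- sqrt(s$lam * s$B11 / s$den)
  gamma <- -s$B12 * alpha^2 * beta / s$lam
  u0 <- gamma * s$v0 / beta - s$B13 * alpha^2 / s$lam
  K <- matrix(c(alpha, 0, 0, 0, beta, 0, u0, s$v0, 1), 3, 3)
  list(K = K, cond = sv$d[1] / max(sv$d[5], 1e-300))
}

# Pose (R, t) of a plane from its homography and intrinsics.
.pose_from_homography <- function(H, K) {
  A <- solve(K) %*% H
  lam <- 1 / sqrt(sum(A[, 1]^2))
  if (lam * A[3, 3] < 0) lam <- -lam   # board must be in front (t_z > 0)
  r1 <- lam * A[, 1]; r2 <- lam * A[, 2]
  R <- nearest_rotation(cbind(r1, r2, pracma_cross(r1, r2)))
  t <- lam * A[, 3]
  list(R = R, t = t)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- reprojection machinery ----------------------------------------------

# Project board points (n x 2 planar mm) through pose (rvec, tvec) and a
# channel (intr list fx,fy,cx,cy + dist list).
.project_board <- function(XY, rvec, tvec, fx, fy, cx, cy, dist) {
  R <- rodrigues_to_rotation(rvec)
  P <- cbind(XY, 0) %*% t(R)
  P <- sweep(P, 2, tvec, "+")
  n <- cbind(P[, 1] / P[, 3], P[, 2] / P[, 3])
  nd <- distort_normalized(n, dist)
  cbind(fx * nd[, 1] + cx, fy * nd[, 2] + cy)
}

.dist_from_vec <- function(v)
  distortion_coeffs(k1 = v[1], k2 = v[2], p1 = v[3], p2 = v[4], k3 = v[5])

# Single-channel bundle refinement: intrinsics + distortion + per-pose poses.
# obs_uv: list over poses of n x 2 observed pixels; XY: board coords.
.refine_channel <- function(XY, obs_uv, K0, poses0) {
  n_pose <- length(obs_uv)
  par0 <- c(K0[1, 1], K0[2, 2], K0[1, 3], K0[2, 3], rep(0, 5),
            unlist(lapply(poses0, function(p)
              c(rotation_to_rodrigues(p$R), p$t))))
  resid <- function(par) {
    fx <- par[1]; fy <- par[2]; cx <- par[3]; cy <- par[4]
    dist <- .dist_from_vec(par[5:9])
    out <- vector("list", n_pose)
    for (i in seq_len(n_pose)) {
      pp <- par[9 + (i - 1) * 6 + (1:6)]
      prj <- .project_board(XY, pp[1:3], pp[4:6], fx, fy, cx, cy, dist)
      out[[i]] <- as.numeric(prj - obs_uv[[i]])
    }
    unlist(out)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  list(par = fit$par, resid = resid(fit$par))
}

# Joint two-channel refinement: both intrinsics/distortions, RGB poses,
# and the RGB->IR relative transform.
.refine_joint <- function(XY, obs_rgb, obs_ir, par_rgb, par_ir, rel0) {
  n_pose <- length(obs_rgb)
  par0 <- c(par_rgb[1:9], par_ir[1:9],
            rotation_to_rodrigues(rel0$R), rel0$t,
            par_rgb[-(1:9)])
  resid <- function(par) {
    ir_off <- 9
    rel_r <- par[19:21]; rel_t <- par[22:24]
    Rrel <- rodrigues_to_rotation(rel_r)
    dist_rgb <- .dist_from_vec(par[5:9])
    dist_ir <- .dist_from_vec(par[ir_off + (5:9)])
    out <- vector("list", 2L * n_pose)
    for (i in seq_len(n_pose)) {
      pp <- par[24 + (i - 1) * 6 + (1:6)]
      Rr <- rodrigues_to_rotation(pp[1:3]); tr <- pp[4:6]
      prj <- .project_board(XY, pp[1:3], pp[4:6],
                            par[1], par[2], par[3], par[4], dist_rgb)
      out[[2 * i - 1]] <- as.numeric(prj - obs_rgb[[i]])
      Ri <- Rrel %*% Rr
      ti <- as.numeric(Rrel %*% tr) + rel_t
      prj_ir <- .project_board(XY, rotation_to_rodrigues(Ri), ti,
                               par[ir_off + 1], par[ir_off + 2],
                               par[ir_off + 3], par[ir_off + 4], dist_ir)
      out[[2 * i]] <- as.numeric(prj_ir - obs_ir[[i]])
    }
    unlist(out)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  list(par = fit$par, resid = resid(fit$par))
}

#' Calibrate a dual-channel rig from checkerboard corner observations
#'
#' Zhang's planar-checkerboard method, run per channel (homography
#' estimation by normalized DLT, closed-form intrinsics, per-pose pose
#' recovery) followed by Levenberg-Marquardt bundle refinement of
#' intrinsics, Brown-Conrady distortion and poses, and a final joint
#' two-channel refinement of the RGB->IR extrinsic transform. The
#' returned rig carries the RMS reprojection error over all corners of
#' both channels.
#'
#' @param board A [checkerboard_spec()].
#' @param obs A [corner_observations()] with >= 3 poses, each with the
#'   full inner-corner grid in both channels.
#' @param image_size_rgb,image_size_ir Optional `c(width, height)` for the
#'   two channels, stored in the rig intrinsics (defaults to the corner
#'   bounding box rounded up, which is only a lower bound on the sensor).
#' @param emissivity,temperature_accuracy Metadata stored on the rig.
#' @return A [camera_rig()] with `rms_reprojection_error` populated.
#' @export
calibrate_rig <- function(board, obs,
                          image_size_rgb = NULL, image_size_ir = NULL,
                          emissivity = 0.96, temperature_accuracy = 0.5) {
  if (!inherits(obs, "corner_observations"))
    obs <- corner_observations(obs, board)
  corners <- obs$corners
  pose_ids <- sort(unique(corners$pose_id))
  if (length(pose_ids) < 3L)
    stop(sprintf(
      "calibrate_rig: insufficient data - need >= 3 poses, got %d",
      length(pose_ids)), call. = FALSE)

  bc <- board_corners(board)
  n_corners <- nrow(bc)
  key <- paste(bc$board_i, bc$board_j)
  get_uv <- function(pid, ch) {
    d <- corners[corners$pose_id == pid & corners$channel == ch, , drop = FALSE]
    if (nrow(d) != n_corners)
      stop(sprintf(
        "calibrate_rig: insufficient data - pose %s channel %s has %d of %d corners",
        pid, ch, nrow(d), n_corners), call. = FALSE)
    d <- d[match(key, paste(d$board_i, d$board_j)), , drop = FALSE]
    if (anyNA(d$u))
      stop(sprintf("calibrate_rig: pose %s channel %s is missing corners", pid, ch),
           call. = FALSE)
    cbind(d$u, d$v)
  }
  obs_rgb <- lapply(pose_ids, get_uv, ch = "rgb")
  obs_ir <- lapply(pose_ids, get_uv, ch = "ir")
  XY <- cbind(bc$X, bc$Y)

  solve_channel <- function(obs_uv, label) {
    Hs <- lapply(obs_uv, function(uv) .homography_dlt(XY, uv))
    zi <- .zhang_intrinsics(Hs)
    if (zi$cond > 1e10)
      warning(sprintf(
        "calibrate_rig: %s pose set is poorly conditioned (near-degenerate poses); best-effort result",
        label), call. = FALSE)
    poses <- lapply(Hs, .pose_from_homography, K = zi$K)
    .refine_channel(XY, obs_uv, zi$K, poses)
  }
  fit_rgb <- solve_channel(obs_rgb, "rgb")
  fit_ir <- solve_channel(obs_ir, "ir")

  n_pose <- length(pose_ids)
  get_poses <- function(par) lapply(seq_len(n_pose), function(i) {
    pp <- par[9 + (i - 1) * 6 + (1:6)]
    list(R = rodrigues_to_rotation(pp[1:3]), t = pp[4:6])
  })
  poses_rgb <- get_poses(fit_rgb$par)
  poses_ir <- get_poses(fit_ir$par)

  # per-pose relative transforms, averaged (rotation via SVD mean)
  rels <- lapply(seq_len(n_pose), function(i) {
    R <- poses_ir[[i]]$R %*% t(poses_rgb[[i]]$R)
    list(R = R, t = poses_ir[[i]]$t - as.numeric(R %*% poses_rgb[[i]]$t))
  })
  Rbar <- nearest_rotation(Reduce(`+`, lapply(rels, `[[`, "R")))
  tbar <- rowMeans(vapply(rels, `[[`, numeric(3), "t"))

  joint <- .refine_joint(XY, obs_rgb, obs_ir, fit_rgb$par, fit_ir$par,
                         list(R = Rbar, t = tbar))
  par <- joint$par
  # RMS over per-corner Euclidean errors: mean(du^2 + dv^2) equals twice the
  # mean over all residual components
  rms <- sqrt(2 * mean(joint$resid^2))

  guess_size <- function(obs_uv, given) {
    if (!is.null(given)) return(as.integer(given))
    mx <- apply(do.call(rbind, obs_uv), 2, max)
    as.integer(ceiling(mx) + 1L)
  }
  sz_rgb <- guess_size(obs_rgb, image_size_rgb)
  sz_ir <- guess_size(obs_ir, image_size_ir)

  mk_channel <- function(p, sz) list(
    intrinsics = intrinsics(fx = p[1], fy = p[2], cx = p[3], cy = p[4],
                            width = sz[1], height = sz[2]),
    distortion = .dist_from_vec(p[5:9]))

  camera_rig(
    rgb = mk_channel(par[1:9], sz_rgb),
    ir = mk_channel(par[9 + (1:9)], sz_ir),
    extrinsics = rig_extrinsics(rodrigues_to_rotation(par[19:21]), par[22:24]),
    rms_reprojection_error = rms,
    emissivity = emissivity,
    temperature_accuracy = temperature_accuracy)
}
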