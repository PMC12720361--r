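test_that("pixel normalization matches the intrinsic model", {
  ii <- intrinsics(1000, 1000, 1344, 760, 2688, 1520)
  expect_equal(unname(normalize_pixel(c(1344, 760), ii)[1, ]), c(0, 0))
  expect_equal(unname(normalize_pixel(c(2344, 760), ii)[1, ]), c(1, 0))
  expect_error(normalize_pixel(c(NA, 1), ii), "finite")
})

test_that("normalization round-trips through projection without distortion", {
  ii <- intrinsics(1532.4, 1488.1, 1340.2, 757.8, 2688, 1520)
  set.seed(101)
  p <- cbind(runif(100, 0, 2687), runif(100, 0, 1519))
  n <- normalize_pixel(p, ii)
  back <- project_to_ir(backproject_at_depth(n, 500), ii)
  expect_equal(back, p, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forward distortion follows the Brown-Conrady model", {
  expect_equal(distort_normalized(c(0.3, -0.2), distortion_coeffs()),
               cbind(x = 0.3, y = -0.2))
  d <- distortion_coeffs(k1 = 0.1)
  expect_equal(distort_normalized(c(0.1, 0), d)[1, 1], 0.1 * (1 + 0.1 * 0.01),
               ignore_attr = TRUE)
  d <- distortion_coeffs(p1 = 0.01)
  expect_equal(distort_normalized(c(0.1, 0.1), d)[1, 1],
               0.1 + 2 * 0.01 * 0.01, ignore_attr = TRUE)
})

test_that("undistortion inverts distortion over the working domain", {
  expect_equal(undistort_normalized(c(0.2, 0.1), distortion_coeffs()),
               cbind(x = 0.2, y = 0.1))
  grid <- as.matrix(expand.grid(x = seq(-0.5, 0.5, by = 0.1),
                                y = seq(-0.5, 0.5, by = 0.1)))
  for (k1 in c(-0.3, -0.1, 0.15, 0.3)) {
    d <- distortion_coeffs(k1 = k1, k2 = 0.02, p1 = 1e-3, p2 = -5e-4)
    nd <- distort_normalized(grid, d)
    expect_lt(max(abs(undistort_normalized(nd, d) - grid)), 1e-8)
  }
})

test_that("undistortion reports non-convergence on pathological coefficients", {
  d <- distortion_coeffs(k1 = -10)
  expect_error(undistort_normalized(c(0.7, 0.7), d), "convergence")
})

test_that("back-projection lifts normalized points onto the depth plane", {
  expect_equal(unname(backproject_at_depth(c(0, 0), 600)[1, ]), c(0, 0, 600))
  expect_equal(unname(backproject_at_depth(c(1, 0.5), 600)[1, ]),
               c(600, 300, 600))
  expect_error(backproject_at_depth(c(0, 0), 0), "depth")
  expect_error(backproject_at_depth(c(0, 0), -5), "depth")
})

test_that("extrinsic transform applies rotation then translation", {
  expect_equal(unname(transform_rgb_to_ir(c(1, 2, 3), rig_extrinsics())[1, ]),
               c(1, 2, 3))
  ext <- rig_extrinsics(translation = c(30, 0, 0))
  expect_equal(unname(transform_rgb_to_ir(c(0, 0, 600), ext)[1, ]),
               c(30, 0, 600))
  Rz90 <- rodrigues_to_rotation(c(0, 0, pi / 2))
  ext <- rig_extrinsics(Rz90)
  expect_equal(unname(transform_rgb_to_ir(c(1, 0, 0), ext)[1, ]), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("projection divides by depth and applies intrinsics", {
  ii <- intrinsics(500, 500, 192, 144, 384, 288)
  expect_equal(project_to_ir(c(0, 0, 600), ii)[1, 1], 192, ignore_attr = TRUE)
  expect_equal(project_to_ir(c(60, 0, 600), ii)[1, 1], 242, ignore_attr = TRUE)
  expect_error(project_to_ir(c(0, 0, -600), ii), "behind")
})

test_that("the full mapping chain is the identity on a degenerate rig", {
  rig <- identity_rig()
  set.seed(7)
  p <- cbind(runif(200, 0, 159), runif(200, 0, 119))
  for (d in c(50, 600, 5000))
    expect_equal(map_pixel_rgb_to_ir(p, rig, d), p,
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the chain agrees with direct projection of on-plane points", {
  # independent oracle: construct the 3D point from the generating plane
  # geometry and project it straight into the IR channel
  for (s in 1:5) {
    rig <- make_rig(scene_spec("paper-like", seed = s))
    set.seed(s + 500)
    P <- cbind(runif(50, -150, 150), runif(50, -90, 90), 600)
    p_rgb <- project_to_ir(P, rig$rgb$intrinsics, rig$rgb$distortion)
    q_chain <- map_pixel_rgb_to_ir(p_rgb, rig, 600)
    q_direct <- project_to_ir(transform_rgb_to_ir(P, rig$extrinsics),
                              rig$ir$intrinsics, rig$ir$distortion)
    expect_lt(max(abs(q_chain - q_direct)), 1e-6)
  }
})

test_that("depth mis-specification shifts points by the parallax closed form", {
  rig <- make_rig(scene_spec("parallax", seed = 1))
  f <- rig$ir$intrinsics$fx
  b <- rig$extrinsics$translation[1]
  set.seed(11)
  p <- cbind(runif(40, 100, 500), runif(40, 60, 300))
  d_true <- 600
  q_true <- map_pixel_rgb_to_ir(p, rig, d_true)
  for (d_wrong in c(580, 593, 611, 620)) {
    q <- map_pixel_rgb_to_ir(p, rig, d_wrong)
    expect_equal(abs(q[, 1] - q_true[, 1]),
                 rep(f * b * abs(1 / d_true - 1 / d_wrong), nrow(p)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_lt(max(abs(q[, 2] - q_true[, 2])), 1e-9)
  }
})

test_that("points mapped outside the IR frame are flagged, not dropped", {
  rig <- make_rig(scene_spec("paper-like", seed = 2))
  p <- rbind(c(1, 1), c(1344, 760))     # far corner maps outside the IR frame
  q <- map_pixel_rgb_to_ir(p, rig, 600)
  oob <- attr(q, "out_of_bounds")
  expect_length(oob, 2L)
  expect_true(oob[1])
  expect_false(oob[2])
})

test_that("domain type validation rejects malformed inputs", {
  expect_error(intrinsics(-1, 1, 0, 0, 10, 10), "positive")
  expect_warning(intrinsics(100, 100, 500, 5, 384, 288), "outside")
  expect_error(rig_extrinsics(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(rig_extrinsics(refl), "determinant")
  expect_error(distortion_coeffs(k1 = NaN), "finite")
  expect_error(camera_rig(list(intrinsics = intrinsics(1, 1, 0, 0, 2, 2)),
                          list(intrinsics = intrinsics(1, 1, 0, 0, 2, 2)),
                          emissivity = 1.5), "emissivity")
})
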