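test_that("a solid 3x3 square traces to its 8 boundary pixel centers", {
  g <- matrix(0L, 10, 12)
  g[4:6, 5:7] <- 1L                     # comb block, 0-based (u 4:6, v 3:5)
  cs <- extract_contours(label_mask(g, "rgb"), "comb")
  expect_length(cs, 1L)
  pts <- cs[[1]]$points
  expect_equal(nrow(pts), 8L)
  want <- expand.grid(u = 4:6, v = 3:5)
  want <- want[!(want$u == 5 & want$v == 4), ]   # interior pixel not traced
  expect_setequal(paste(pts[, 1], pts[, 2]), paste(want$u, want$v))
  # counter-clockwise: positive shoelace area in the (u, v) plane
  u <- pts[, 1]; v <- pts[, 2]
  expect_gt(sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v), 0)
})

test_that("contour extraction respects region absence, multiplicity and min_area", {
  g <- matrix(0L, 20, 30)
  g[2:6, 2:6] <- 1L
  g[10:16, 10:18] <- 1L
  g[2:3, 20:21] <- 4L                  # 4 px wattle speck, below min_area
  m <- label_mask(g, "rgb")
  expect_identical(extract_contours(m, "eye"), list())
  expect_length(extract_contours(m, "comb"), 2L)
  expect_length(extract_contours(m, "wattle"), 0L)
  expect_length(extract_contours(m, "wattle", min_area = 4), 1L)
})

test_that("diagonally-touching pixels form one 8-connected component", {
  g <- matrix(0L, 10, 10)
  g[2:4, 2:4] <- 1L
  g[5:7, 5:7] <- 1L                    # touches the first block at a corner
  cs <- extract_contours(label_mask(g, "rgb"), "comb")
  expect_length(cs, 1L)
})

test_that("rasterization follows the edge-inclusive nonzero winding rule", {
  sq <- rbind(c(1, 1), c(4, 1), c(4, 4), c(1, 4))
  m <- rasterize_contour(sq, 10, 10)
  expect_equal(sum(m), 16L)
  expect_true(all(m[2:5, 2:5]))
  # fully outside the grid
  expect_equal(sum(rasterize_contour(sq + 100, 10, 10)), 0L)
  # degenerate 2-point contour
  expect_warning(m2 <- rasterize_contour(rbind(c(1, 1), c(4, 4)), 10, 10),
                 "degenerate")
  expect_equal(sum(m2), 0L)
})

test_that("scanline rasterization matches the per-pixel winding oracle", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    pts <- cbind(runif(n, -6, 40), runif(n, -6, 28))   # often self-intersecting
    expect_identical(rasterize_contour(pts, 30, 44),
                     thermomap:::.rasterize_winding_matrix(pts, 30, 44))
  }
})

test_that("rasterization of convex contours is idempotent", {
  disk <- disk_mask(40, 50, 24, 19, 11)
  g <- matrix(0L, 40, 50); g[disk] <- 1L
  c1 <- extract_contours(label_mask(g, "rgb"), "comb")[[1]]
  m1 <- rasterize_contour(c1, 40, 50)
  g2 <- matrix(0L, 40, 50); g2[m1] <- 1L
  c2 <- extract_contours(label_mask(g2, "rgb"), "comb")[[1]]
  m2 <- rasterize_contour(c2, 40, 50)
  expect_identical(m1, m2)
})

test_that("contour mapping preserves order and flags out-of-bounds points", {
  rig <- identity_rig()
  g <- matrix(0L, 120, 160); g[30:60, 40:80] <- 1L
  ct <- extract_contours(label_mask(g, "rgb"), "comb")[[1]]
  mc <- map_contour(ct, rig, 600)
  expect_equal(mc$points, ct$points, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mc$region, "comb")
  expect_false(any(attr(mc$points, "out_of_bounds")))
})

test_that("mask mapping through the identity rig reproduces the mask", {
  rig <- identity_rig()
  mask <- block_label_mask()
  roi <- map_label_mask(mask, rig, 600)
  tab <- region_labels()
  for (r in head_regions()) {
    input <- mask$grid == tab$code[tab$name == r]
    expect_gte(mask_iou(roi$masks[[r]], input), 0.99)
  }
  expect_equal(roi$depth_used, 600)
})

test_that("mapped outputs always live on the IR grid", {
  spec <- scene_spec("reduced", seed = 4)
  scene <- make_scene(spec)
  roi <- map_label_mask(scene$rgb_mask, scene$rig, 600)
  for (r in head_regions())
    expect_equal(dim(roi$masks[[r]]),
                 c(scene$rig$ir$intrinsics$height,
                   scene$rig$ir$intrinsics$width))
})

test_that("mapping a synthetic scene agrees with the ground-truth projection", {
  scene <- make_scene(scene_spec("paper-like", seed = 7, render_color = FALSE))
  roi <- map_label_mask(scene$rgb_mask, scene$rig, 600)
  for (r in head_regions())
    expect_gte(mask_iou(roi$masks[[r]], scene$ir_gt$masks[[r]]), 0.95)
  expect_true(all(roi$out_of_bounds_fraction == 0))
})

test_that("regions never receive pixels from another region's contours", {
  rig <- identity_rig()
  mask <- block_label_mask()
  roi <- map_label_mask(mask, rig, 600)
  tab <- region_labels()
  for (r in head_regions()) {
    others <- mask$grid != tab$code[tab$name == r] & mask$grid != 0L
    # identity mapping: a region's output must not cover other regions
    expect_equal(sum(roi$masks[[r]] & others), 0L)
  }
})

test_that("a background-only mask maps to four empty regions", {
  rig <- identity_rig()
  mask <- label_mask(matrix(0L, 120, 160), "rgb")
  roi <- map_label_mask(mask, rig, 600)
  expect_true(all(!vapply(roi$masks, any, logical(1))))
  expect_true(all(roi$out_of_bounds_fraction == 0))
})

test_that("mask frame and depth preconditions are enforced", {
  rig <- identity_rig()
  m_ir <- label_mask(matrix(0L, 120, 160), "ir")
  expect_error(map_label_mask(m_ir, rig, 600), "rgb")
  expect_error(map_label_mask(block_label_mask(), rig, 0), "depth")
})

test_that("flattening writes regions so the smallest structures win", {
  masks <- list(comb = matrix(FALSE, 5, 5), eye = matrix(FALSE, 5, 5),
                beak = matrix(FALSE, 5, 5), wattle = matrix(FALSE, 5, 5))
  masks$comb[1:4, 1:4] <- TRUE
  masks$eye[2:3, 2:3] <- TRUE           # overlaps the comb; eye must win
  flat <- flatten_roi_set(roi_set(masks, depth_used = 600))
  expect_equal(flat$frame, "ir")
  expect_equal(sum(flat$grid == 2L), 4L)
  expect_equal(sum(flat$grid == 1L), 12L)
})
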