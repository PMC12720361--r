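test_that("rig generation is a pure function of the seed", {
  a <- make_rig(scene_spec("paper-like", seed = 123))
  b <- make_rig(scene_spec("paper-like", seed = 123))
  expect_identical(a, b)
  c_ <- make_rig(scene_spec("paper-like", seed = 124))
  expect_false(identical(a$rgb$intrinsics$fx, c_$rgb$intrinsics$fx))
})

test_that("the paper-like preset uses the dual-channel camera resolutions", {
  rig <- make_rig(scene_spec("paper-like", seed = 1))
  expect_equal(c(rig$rgb$intrinsics$width, rig$rgb$intrinsics$height),
               c(2688L, 1520L))
  expect_equal(c(rig$ir$intrinsics$width, rig$ir$intrinsics$height),
               c(384L, 288L))
  expect_equal(rig$emissivity, 0.96)
  expect_equal(rig$temperature_accuracy, 0.5)
  expect_gt(abs(rig$extrinsics$translation[1]), 40)   # X-dominant baseline
})

test_that("the zero-baseline preset maps independently of depth", {
  rig <- make_rig(scene_spec("zero-baseline", seed = 2))
  set.seed(1)
  p <- cbind(runif(20, 0, 2687), runif(20, 0, 1519))
  expect_equal(map_pixel_rgb_to_ir(p, rig, 200),
               map_pixel_rgb_to_ir(p, rig, 2000), tolerance = 1e-12)
})

test_that("checkerboard observations have full grids in both channels", {
  rig <- make_rig(scene_spec("paper-like", seed = 4))
  obs <- make_checkerboard_observations(rig, n_poses = 3, seed = 7)
  expect_equal(obs$n_poses, 3L)
  cnt <- table(obs$corners$pose_id, obs$corners$channel)
  expect_true(all(cnt == 210L))       # 14 x 15 inner corners per channel
  w <- rig$rgb$intrinsics$width; h <- rig$rgb$intrinsics$height
  rgb <- obs$corners[obs$corners$channel == "rgb", ]
  expect_true(all(rgb$u >= 0 & rgb$u <= w - 1 & rgb$v >= 0 & rgb$v <= h - 1))
  ir <- obs$corners[obs$corners$channel == "ir", ]
  expect_true(all(ir$u >= 0 & ir$u <= 383 & ir$v >= 0 & ir$v <= 287))
})

test_that("observations are seeded deterministically, noise included", {
  rig <- make_rig(scene_spec("paper-like", seed = 4))
  a <- make_checkerboard_observations(rig, n_poses = 2, noise_sd_px = 0.1,
                                      seed = 5)
  b <- make_checkerboard_observations(rig, n_poses = 2, noise_sd_px = 0.1,
                                      seed = 5)
  expect_identical(a, b)
  clean <- make_checkerboard_observations(rig, n_poses = 2, seed = 5)
  expect_false(identical(a$corners$u, clean$corners$u))
  expect_error(make_checkerboard_observations(rig, n_poses = 2),
               "seed")
})

test_that("scenes are a pure function of the spec and seed", {
  a <- make_scene(scene_spec("reduced", seed = 77))
  b <- make_scene(scene_spec("reduced", seed = 77))
  expect_identical(a$rgb_mask$grid, b$rgb_mask$grid)
  expect_identical(a$temps$grid, b$temps$grid)
  c_ <- make_scene(scene_spec("reduced", seed = 78))
  expect_false(identical(a$temps$grid, c_$temps$grid))
})

test_that("scenes carry all four regions in mask and ground truth", {
  scene <- make_scene(scene_spec("reduced", seed = 15))
  tab <- region_labels()
  for (r in head_regions()) {
    expect_gt(sum(scene$rgb_mask$grid == tab$code[tab$name == r]), 0)
    expect_gt(sum(scene$ir_gt$masks[[r]]), 0)
  }
  expect_equal(scene$ir_gt$depth_used, scene$spec$depth)
  # temperature grid matches the IR resolution
  expect_equal(dim(scene$temps$grid), dim(scene$ir_gt$masks$comb))
})

test_that("heat-stress scene pairs shift only the configured regions", {
  base <- scene_spec("reduced", seed = 20, noise_sd_c = 0,
                     render_color = FALSE)
  hot_t <- base$region_temp_c + c(comb = 2.5, eye = 0, beak = 0, wattle = 2.5)
  hot <- scene_spec("reduced", seed = 20, noise_sd_c = 0,
                    region_temp_c = hot_t, render_color = FALSE)
  s0 <- make_scene(base); s1 <- make_scene(hot)
  expect_identical(s0$rgb_mask$grid, s1$rgb_mask$grid)   # same geometry
  st0 <- region_stats(s0$temps, s0$ir_gt)
  st1 <- region_stats(s1$temps, s1$ir_gt)
  expect_equal(st1$mean_c[st1$region == "comb"] -
                 st0$mean_c[st0$region == "comb"], 2.5)
  expect_equal(st1$mean_c[st1$region == "eye"],
               st0$mean_c[st0$region == "eye"])
})

test_that("a written scene reads back faithfully", {
  dir <- withr::local_tempdir()
  scene <- make_scene(scene_spec("reduced", seed = 30))
  write_scene(scene, dir)
  rig2 <- read_camera_rig(file.path(dir, "rig.json"))
  expect_equal(rig2$rgb$intrinsics$fx, scene$rig$rgb$intrinsics$fx,
               tolerance = 0)
  mask2 <- read_label_mask(file.path(dir, "rgb_mask.png"), frame = "rgb")
  expect_identical(mask2$grid, scene$rgb_mask$grid)
  tm2 <- read_temperature_matrix(file.path(dir, "temps.csv"))
  expect_equal(tm2$grid, scene$temps$grid, tolerance = 0)
  expect_true(file.exists(file.path(dir, "ir_gt_comb.png")))
  expect_true(file.exists(file.path(dir, "scene.json")))
})
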