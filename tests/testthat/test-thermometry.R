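test_that("region statistics summarize masked pixels", {
  g <- matrix(30, 10, 12)
  tm <- temperature_matrix(g)
  masks <- list(comb = matrix(FALSE, 10, 12), eye = matrix(FALSE, 10, 12),
                beak = matrix(FALSE, 10, 12), wattle = matrix(FALSE, 10, 12))
  masks$comb[2:4, 2:4] <- TRUE
  roi <- roi_set(masks, depth_used = 600)
  st <- suppressWarnings(region_stats(tm, roi))
  expect_equal(st$mean_c[st$region == "comb"], 30)
  expect_equal(st$min_c[st$region == "comb"], 30)
  expect_equal(st$max_c[st$region == "comb"], 30)
  expect_equal(st$pixel_count[st$region == "comb"], 9L)

  g2 <- g; g2[2, 2] <- 32
  masks$comb[] <- FALSE; masks$comb[2, c(2, 3)] <- TRUE  # pixels at 32 and 30
  roi2 <- roi_set(masks, depth_used = 600)
  st2 <- suppressWarnings(region_stats(temperature_matrix(g2), roi2))
  expect_equal(st2$mean_c, 31)
  expect_equal(st2$min_c, 30)
  expect_equal(st2$max_c, 32)
})

test_that("empty regions warn and an all-empty ROI set errors", {
  tm <- temperature_matrix(matrix(30, 5, 5))
  masks <- list(comb = matrix(FALSE, 5, 5), eye = matrix(FALSE, 5, 5))
  masks$comb[2, 2] <- TRUE
  expect_warning(st <- region_stats(tm, roi_set(masks, 600)), "eye")
  expect_equal(attr(st, "empty_regions"), "eye")
  masks$comb[] <- FALSE
  expect_error(suppressWarnings(region_stats(tm, roi_set(masks, 600))),
               "empty")
  expect_error(region_stats(temperature_matrix(matrix(30, 4, 4)),
                            roi_set(list(comb = matrix(TRUE, 5, 5)), 600)),
               "mismatch")
})

test_that("noiseless scenes yield exactly the generating region means", {
  spec <- scene_spec("reduced", seed = 8, noise_sd_c = 0, render_color = FALSE)
  scene <- make_scene(spec)
  st <- region_stats(scene$temps, scene$ir_gt)
  for (r in st$region)
    expect_identical(st$mean_c[st$region == r],
                     unname(spec$region_temp_c[[r]]))
})

test_that("noisy scenes recover region means within sampling error", {
  spec <- scene_spec("paper-like", seed = 12, render_color = FALSE)
  scene <- make_scene(spec)
  st <- region_stats(scene$temps, scene$ir_gt)
  for (r in st$region) {
    se <- spec$noise_sd_c / sqrt(st$pixel_count[st$region == r])
    expect_lt(abs(st$mean_c[st$region == r] - spec$region_temp_c[[r]]),
              3 * se)
  }
})

test_that("growing a mask moves min and max outward and mean within range", {
  set.seed(42)
  g <- matrix(rnorm(400, 35, 2), 20, 20)
  tm <- temperature_matrix(g)
  small <- list(comb = disk_mask(20, 20, 9, 9, 4))
  big <- list(comb = disk_mask(20, 20, 9, 9, 7))
  st_s <- region_stats(tm, roi_set(small, 600))
  st_b <- region_stats(tm, roi_set(big, 600))
  expect_lte(st_b$min_c, st_s$min_c)
  expect_gte(st_b$max_c, st_s$max_c)
  expect_gte(st_b$mean_c, st_b$min_c)
  expect_lte(st_b$mean_c, st_b$max_c)
})

test_that("group report averages per-bird means within cells", {
  rec <- data.frame(
    density = c(4, 4, 4), age_weeks = c(5, 5, 5),
    condition = "experimental", bird_id = c("b1", "b2", "b1"),
    region = "comb", mean_c = c(38, 40, 38))
  one <- group_report(rec[1, ])
  expect_equal(one$mean_c, 38)
  expect_equal(one$n, 1)
  two <- group_report(rec[1:2, ])
  expect_equal(two$mean_c, 39)
  expect_equal(two$n, 2)
  # b1 contributes two frames: per-bird averaging keeps n at 2 birds
  all3 <- group_report(rec)
  expect_equal(all3$n, 2)
  expect_equal(all3$mean_c, 39)
  pooled <- group_report(rec, per_bird = FALSE)
  expect_equal(pooled$n, 3)
  expect_equal(pooled$mean_c, mean(c(38, 40, 38)))
})

test_that("group report is permutation-invariant and never imputes", {
  set.seed(31)
  rec <- expand.grid(density = c(4, 8), age_weeks = c(5, 6),
                     condition = c("experimental", "control"),
                     bird_id = paste0("b", 1:3),
                     region = c("comb", "wattle"),
                     stringsAsFactors = FALSE)
  rec$mean_c <- rnorm(nrow(rec), 38, 1)
  a <- group_report(rec)
  b <- group_report(rec[sample(nrow(rec)), ])
  expect_equal(a, b)
  # drop one full cell: it must be absent, not imputed
  drop <- !(rec$density == 8 & rec$age_weeks == 6 &
              rec$condition == "control" & rec$region == "wattle")
  a2 <- group_report(rec[drop, ])
  expect_equal(nrow(a2), nrow(a) - 1L)
  expect_error(group_report(rec[0, ]), "record")
})

test_that("temperature matrices validate and round-trip through CSV", {
  expect_warning(temperature_matrix(matrix(c(30, 95), 1, 2)), "plausible")
  expect_error(temperature_matrix(matrix(c(30, NA), 1, 2)), "finite")
  tm <- temperature_matrix(matrix(rnorm(12, 30, 1), 3, 4), frame_id = "f1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_temperature_matrix(tm, path)
  back <- read_temperature_matrix(path)
  expect_equal(back$grid, tm$grid, tolerance = 0)
})
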