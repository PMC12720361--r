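# Shared synthetic fixtures, built in code at test time.

# A degenerate rig: both channels share intrinsics, no distortion,
# identity extrinsics. The mapping chain must be the identity on it.
identity_rig <- function(width = 160, height = 120, f = 200) {
  ii <- intrinsics(f, f, (width - 1) / 2, (height - 1) / 2, width, height)
  camera_rig(rgb = list(intrinsics = ii), ir = list(intrinsics = ii))
}

# Small RGB label mask with one solid block per head region.
block_label_mask <- function(width = 160, height = 120) {
  g <- matrix(0L, height, width)
  g[20:45, 30:70] <- 1L     # comb
  g[55:70, 40:55] <- 2L     # eye
  g[60:75, 80:115] <- 3L    # beak
  g[85:110, 45:70] <- 4L    # wattle
  label_mask(g, frame = "rgb")
}

# Disk in a logical mask, 0-based center coordinates.
disk_mask <- function(height, width, cu, cv, r) {
  u <- matrix(rep(0:(width - 1), each = height), height, width)
  v <- matrix(rep(0:(height - 1), times = width), height, width)
  (u - cu)^2 + (v - cv)^2 <= r^2
}

expect_rig_close <- function(fit, truth, tol_intr_pct, tol_t_mm) {
  for (ch in c("rgb", "ir")) for (f in c("fx", "fy", "cx", "cy")) {
    rel <- abs(fit[[ch]]$intrinsics[[f]] - truth[[ch]]$intrinsics[[f]]) /
      abs(truth[[ch]]$intrinsics[[f]])
    expect_lt(100 * rel, tol_intr_pct)
  }
  expect_lt(max(abs(fit$extrinsics$translation - truth$extrinsics$translation)),
            tol_t_mm)
}
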