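# Full spherical shell image built directly (no basal opening), for
# detector tests over the complete solid angle.  Edges follow an analytic
# erf profile of width `blur_sd` (a blur much smaller than the wall),
# matching a softly resolved shell without any convolution step.
sphere_shell_image <- function(r_in = 4.61, wall = 2, voxel = 0.5, n = 44,
                               bg = 0.1, center = c(0, 0, 0),
                               blur_sd = 0.3) {
  co <- (seq_len(n) - (n + 1) / 2) * voxel
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    r <- sqrt(outer((co - center[1])^2, (co - center[2])^2, "+") +
                (co[k] - center[3])^2)
    shell <- pnorm((r - r_in) / blur_sd) - pnorm((r - r_in - wall) / blur_sd)
    arr[, , k] <- bg + (1 - bg) * shell
  }
  pet_image(arr, voxel)
}

test_that("the LV center is the centroid of the largest hot component", {
  # Single hot voxel.
  arr <- array(0, c(9, 9, 9))
  arr[3, 7, 5] <- 4
  ctr <- find_lv_center(pet_image(arr, 1))
  expect_equal(ctr, c(3 - 5, 7 - 5, 5 - 5))

  # Two disjoint blobs: only the larger one counts.
  arr2 <- array(0, c(16, 16, 16))
  arr2[2:4, 2:4, 2:4] <- 1          # 27 voxels
  arr2[12:13, 12:13, 12:13] <- 1    # 8 voxels
  ctr2 <- find_lv_center(pet_image(arr2, 1))
  expect_equal(ctr2, c(3, 3, 3) - (16 + 1) / 2)

  # Symmetric shell: center within half a voxel of the geometric center.
  img <- sphere_shell_image()
  expect_lt(max(abs(find_lv_center(img))), 0.25)

  expect_error(find_lv_center(pet_image(array(0, c(4, 4, 4)), 1)))
})

test_that("radial detection recovers a spherical shell radius on all rays", {
  img <- sphere_shell_image(r_in = 4.61, wall = 2)
  up <- upsample_image(img, 3)
  cfg <- seg_config(upsample_factor = 3, n_directions = 400,
                    basal_exclusion_deg = 0)
  surf <- detect_endocardium(up, c(0, 0, 0), cfg)
  expect_true(all(!surf$excluded))
  expect_gte(mean(surf$valid), 0.8)
  expect_lt(max(abs(surf$radii - 4.61) / 4.61), 0.05)
  # Full-solid-angle cone sum against the closed-form sphere volume.
  v <- cavity_volume(surf)
  expect_lt(abs(v - 4 / 3 * pi * 4.61^3) / (4 / 3 * pi * 4.61^3), 0.03)
})

test_that("detection is invariant to translation and intensity scale", {
  off <- c(1.5, -1, 0.5)
  img0 <- sphere_shell_image()
  img1 <- sphere_shell_image(center = off)
  cfg <- seg_config(upsample_factor = 3, n_directions = 300,
                    basal_exclusion_deg = 0)
  s0 <- detect_endocardium(upsample_image(img0, 3), c(0, 0, 0), cfg)
  s1 <- detect_endocardium(upsample_image(img1, 3), off, cfg)
  expect_equal(s1$radii, s0$radii, tolerance = 0.02)

  img5 <- pet_image(img0$data * 5, img0$voxel_size, img0$origin)
  s5 <- detect_endocardium(upsample_image(img5, 3), c(0, 0, 0), cfg)
  expect_equal(s5$radii, s0$radii, tolerance = 1e-8)
})

test_that("a uniform image yields an unreliable-gate error", {
  img <- pet_image(array(1, c(20, 20, 20)), 1)
  expect_error(detect_endocardium(img, c(0, 0, 0),
                                  seg_config(upsample_factor = 1)),
               class = "gatedlv_unreliable_gate")
})

test_that("cone-sum volumetry has closed-form behaviour", {
  dirs <- gatedlv:::fibonacci_directions(600)
  r <- 4.61
  sphere <- list(directions = dirs, radii = rep(r, 600),
                 solid_angle = 4 * pi / 600)
  expect_lt(abs(cavity_volume(sphere) - 4 / 3 * pi * r^3) /
              (4 / 3 * pi * r^3), 0.01)
  # Homogeneity: scaling all radii by k scales volume by k^3.
  k <- 1.37
  scaled <- sphere
  scaled$radii <- sphere$radii * k
  expect_equal(cavity_volume(scaled), k^3 * cavity_volume(sphere),
               tolerance = 1e-10)
  # Hemisphere with a flat cap h above the center, bounded by radius r:
  # V = (2/3) pi r^3 + pi r^2 h.
  h <- 0.8
  hemi <- list(directions = dirs, radii = rep(r, 600),
               solid_angle = 4 * pi / 600,
               excluded = dirs[, "z"] > 0,
               basal_exclusion_deg = 90, cap_height = h)
  expect_lt(abs(cavity_volume(hemi) - (2 / 3 * pi * r^3 + pi * r^2 * h)) /
              (2 / 3 * pi * r^3), 0.015)
})

test_that("frame volumetry is accurate, monotone and scale-free", {
  cfg <- fast_phantom()
  scfg <- fast_seg()
  vols <- c(180, 280, 410)
  est <- vapply(vols, function(v)
    as.numeric(segment_frame(voxelize_frame(cfg, v), scfg)), numeric(1))
  expect_true(all(abs(est - vols) / vols < 0.05))
  expect_true(all(diff(est) > 0))

  img <- voxelize_frame(cfg, 280)
  img2 <- pet_image(img$data * 7.3, img$voxel_size, img$origin)
  expect_equal(as.numeric(segment_frame(img2, scfg)), est[2],
               tolerance = 1e-6)
})

test_that("volumetry error shrinks as voxel size and PSF shrink", {
  res <- vapply(list(c(2, 1.6), c(1, 0.8), c(0.6, 0.5)), function(s) {
    cfg <- phantom_config(wall_thickness = 2, long_axis_ratio = 1.8,
                          psf_fwhm = s[2], voxel_size = s[1],
                          grid_shape = rep(round(32 / s[1]), 3))
    v <- segment_frame(voxelize_frame(cfg, 300),
                       seg_config(upsample_factor = 3, n_directions = 400))
    abs(v - 300) / 300
  }, numeric(1))
  expect_gt(res[1], res[2])
  expect_lt(res[2], 0.05)
  expect_lt(res[3], 0.05)
})

test_that("series segmentation gives identical volumes on identical frames", {
  cfg <- fast_phantom()
  frame <- voxelize_frame(cfg, 300)$data
  arr <- array(rep(frame, 4), c(dim(frame), 4))
  series <- gatedlv:::new_gated_series(
    arr, voxel_size = cfg$voxel_size,
    origin = -(cfg$grid_shape - 1) / 2 * cfg$voxel_size,
    period = 0.2, gate_times = (1:4 - 0.5) / 4 * 0.2,
    accepted_beats = NA_integer_, rejected_beats = NA_integer_)
  vc <- segment_series(series, fast_seg())
  expect_true(all(vc$reliable))
  expect_lt(diff(range(vc$volume_ul)), 1e-9)
})
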