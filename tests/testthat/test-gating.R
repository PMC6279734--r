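test_that("heart rate is 60 over the mean accepted R-R interval", {
  expect_equal(estimate_heart_rate(seq(0, 2, by = 0.2))$hr, 300)
  hr <- estimate_heart_rate(cumsum(c(0, rep(0.18127, 20))))$hr
  expect_equal(signif(hr, 4), 331.0)
  # A 900 ms pause among 180 ms beats is rejected by the 30% median window.
  tr <- cumsum(c(0, 0.18, 0.18, 0.18, 0.9, 0.18))
  est <- estimate_heart_rate(tr)
  expect_equal(est$n_rejected, 1L)
  expect_equal(est$hr, 60 / 0.18, tolerance = 1e-9)
  # Without rejection the pause drags the mean down.
  expect_lt(estimate_heart_rate(tr, reject = FALSE)$hr, est$hr)
  expect_error(estimate_heart_rate(c(0, 0.2)), "at least 3")
})

test_that("gate assignment follows the half-open per-beat phase convention", {
  triggers <- tibble::tibble(t_s = c(0, 0.2, 0.4, 0.6))
  ev <- tibble::tibble(t_s = c(0.1, 0.2, 0.4 - 1e-9, -0.05, 0.65),
                       x_mm = 0, y_mm = 0, z_mm = 0)
  out <- assign_gates(ev, triggers, n_gates = 16)
  expect_equal(out$gate[1], 8L)        # mid-beat -> gate 8 of 0..15
  expect_equal(out$gate[2], 0L)        # exactly on a trigger -> gate 0
  expect_equal(out$gate[3], 15L)       # just before the next trigger
  expect_equal(out$status[4], "out_of_range")
  expect_equal(out$status[5], "out_of_range")
})

test_that("uniform event times fill gates uniformly", {
  set.seed(7)
  n <- 16000
  ev <- tibble::tibble(t_s = runif(n, 0, 0.2), x_mm = 0, y_mm = 0, z_mm = 0)
  out <- assign_gates(ev, c(0, 0.2, 0.4), n_gates = 16)
  counts <- table(factor(out$gate[out$status == "accepted" &
                                    out$beat == 1], levels = 0:15))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("histogramming deposits counts on nearest voxels and conserves them", {
  ev <- tibble::tibble(t_s = 0, x_mm = 0, y_mm = 0, z_mm = 0)
  img <- histogram_gate(ev, dim = c(5, 5, 5), voxel_size = 1)
  expect_equal(img$data[3, 3, 3], 1)
  expect_equal(sum(img$data), 1)

  dup <- ev[rep(1, 7), ]
  expect_equal(max(histogram_gate(dup, c(5, 5, 5), 1)$data), 7)

  set.seed(1)
  rnd <- tibble::tibble(t_s = 0, x_mm = runif(500, -6, 6),
                        y_mm = runif(500, -6, 6), z_mm = runif(500, -6, 6))
  img2 <- histogram_gate(rnd, c(5, 5, 5), 1)
  expect_equal(sum(img2$data) + attr(img2, "out_of_grid"), 500)
  expect_error(histogram_gate(ev, c(5, 5, 5), 0), "positive")
})

test_that("gating conserves every input event across gates and discards", {
  cfg <- fast_phantom(total_counts = 3e4)
  cv <- synthesize_curve(curve_spec(edv = 400, esv = 180, heart_rate = 320))
  lm <- simulate_listmode(cfg, cv, duration_s = 4, rr_jitter_sd = 0.004,
                          seed = 5)
  out <- assign_gates(lm$events, lm$triggers)
  expect_equal(sum(!is.na(out$gate)) + sum(out$status != "accepted"),
               nrow(lm$events))
  gs <- gate_series(lm$events, lm$triggers, dim = cfg$grid_shape,
                    voxel_size = cfg$voxel_size)
  expect_equal(sum(gs$data) + gs$discarded_events + gs$out_of_grid,
               nrow(lm$events))
})

test_that("per-gate counts track the per-gate activity integral", {
  cfg <- fast_phantom(total_counts = 2e5)
  cv <- synthesize_curve(curve_spec(edv = 420, esv = 160, heart_rate = 300))
  lm <- simulate_listmode(cfg, cv, duration_s = 8, rr_jitter_sd = 0,
                          seed = 11, n_phase = 16)
  out <- assign_gates(lm$events, lm$triggers)
  counts <- table(factor(out$gate, levels = 0:15))
  # Expected share per gate: activity-map totals at the gate midpoints.
  mids <- (0:15 + 0.5) / 16 * cv$period
  act <- vapply(mids, function(t)
    sum(voxelize_frame(cfg, eval_volume(cv, t))$data), numeric(1))
  expected <- sum(counts) * act / sum(act)
  z <- (as.numeric(counts) - expected) / sqrt(expected)
  expect_lt(max(abs(z)), 5)
})

test_that("jitter-free trigger heart rate is exact to floating point", {
  tr <- simulate_triggers(20, 331, rr_jitter_sd = 0, seed = 3)
  expect_equal(estimate_heart_rate(tr)$hr, 331, tolerance = 1e-12)
})
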