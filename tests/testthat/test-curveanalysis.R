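test_that("the Fourier fit recovers exact coefficients on a uniform gate grid", {
  g <- sample_gate_volumes(cosine_curve(), 16, "point")
  fit <- fit_fourier(g, n_harmonics = 4)
  expect_equal(fit$dc, 300, tolerance = 1e-10)
  expect_equal(fit$cos_coef, c(100, 0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$sin_coef, rep(0, 4), tolerance = 1e-10)

  flat <- tibble::tibble(t_s = g$t_s, volume_ul = rep(250, 16))
  ffit <- fit_fourier(flat, n_harmonics = 4, period = 0.2)
  expect_equal(ffit$dc, 250)
  expect_equal(ffit$cos_coef, rep(0, 4), tolerance = 1e-12)

  expect_error(fit_fourier(g, n_harmonics = 8), "harmonics")
})

test_that("ejection fraction follows its defining formula and bounds", {
  expect_equal(compute_ef(410.8, 155.1), 100 * 255.7 / 410.8)
  expect_equal(compute_ef(400, 0), 100)
  expect_equal(compute_ef(400, 400), 0)
  expect_error(compute_ef(0, 0))
  expect_error(compute_ef(300, 400))
})

test_that("extrema location is equivariant to offsets and time shifts", {
  cv <- cosine_curve()
  ee <- find_ed_es(cv)
  expect_lt(phase_dist(ee$ed_phase, 0, 0.2), 1e-6)
  expect_lt(phase_dist(ee$es_phase, 0.1, 0.2), 1e-6)

  off <- fourier_curve(0.2, 350, 100, 0)   # + 50 uL offset
  eo <- find_ed_es(off)
  expect_lt(phase_dist(eo$ed_phase, ee$ed_phase, 0.2), 1e-6)
  expect_equal(eo$edv, ee$edv + 50, tolerance = 1e-7)

  # cos(w(t - dt)) expansion: shift every phase by dt = 0.05 s.
  sh <- fourier_curve(0.2, 300, 100 * cos(2 * pi / 0.2 * 0.05),
                      100 * sin(2 * pi / 0.2 * 0.05))
  es <- find_ed_es(sh)
  expect_lt(phase_dist(es$ed_phase, 0.05, 0.2), 1e-6)
  expect_lt(phase_dist(es$es_phase, 0.15, 0.2), 1e-6)
})

test_that("TPFR is a cycle-modular time difference", {
  expect_equal(compute_tpfr(0.10, 0.15, 0.2), 50)
  expect_equal(compute_tpfr(0.10, 0.10, 0.2), 0)
  # Wraparound: ES late in the cycle, peak filling after the wrap.
  wrap <- compute_tpfr(0.18, 0.03, 0.2)
  expect_gt(wrap, 0)
  expect_lt(wrap, 200)
  expect_equal(wrap, 50)
})

test_that("filling rates are normalized and mean-bounded", {
  cv <- cosine_curve()
  m <- measure_curve(cv)
  p <- compute_pfr(cv, m$edv, m$es_phase, m$ed_phase)
  expect_equal(p$pfr, 7.853982, tolerance = 1e-6)
  expect_equal(p$t_pfr_abs, 0.15, tolerance = 1e-6)
  tm <- compute_third_mfr(cv, m$edv, m$es_phase, m$ed_phase)
  expect_equal(tm, 3.75, tolerance = 1e-6)
  expect_lte(tm, p$pfr)

  # Volume rescaling leaves the normalized rates and TPFR unchanged.
  k <- 3.7
  cvk <- fourier_curve(0.2, 300 * k, 100 * k, 0)
  mk <- measure_curve(cvk)
  expect_equal(mk$pfr, m$pfr, tolerance = 1e-9)
  expect_equal(mk$third_mfr, m$third_mfr, tolerance = 1e-9)
  expect_equal(mk$tpfr_ms, m$tpfr_ms, tolerance = 1e-6)
  expect_equal(mk$ef, m$ef, tolerance = 1e-9)
})

test_that("the 16-gate sample-and-fit pipeline matches the analytic oracle", {
  for (seed in c(3, 11, 27)) {
    rf <- random_feasible_curve(seed)
    cv <- rf$curve
    truth <- measure_curve(cv)
    got <- analyze_volume_curve(sample_gate_volumes(cv, 16, "point"),
                                hr = rf$spec$heart_rate, n_harmonics = 6)
    for (col in c("edv", "esv", "ef", "pfr", "third_mfr"))
      expect_lt(rel_err(got[[col]], truth[[col]]), 0.005)
    expect_lt(abs(got$tpfr_ms - truth$tpfr_ms), 0.005 * cv$period * 1000)
  }
})

test_that("shifting gate times shifts phases but not functional parameters", {
  cv <- random_feasible_curve(5)$curve
  g <- sample_gate_volumes(cv, 16, "point")
  dt <- 0.031
  shifted <- g
  shifted$t_s <- g$t_s + dt
  a0 <- analyze_volume_curve(g, n_harmonics = 6)
  a1 <- analyze_volume_curve(shifted, n_harmonics = 6,
                             period = attr(g, "period"))
  expect_equal((a1$ed_phase - a0$ed_phase) %% a0$period, dt,
               tolerance = 1e-5)
  for (col in c("edv", "esv", "ef", "pfr", "third_mfr", "tpfr_ms"))
    expect_equal(a1[[col]], a0[[col]], tolerance = 1e-6)
})

test_that("analysis of a constant curve reports degeneracy", {
  flat <- tibble::tibble(t_s = (0:15 + 0.5) / 16 * 0.2,
                         volume_ul = rep(300, 16))
  expect_error(analyze_volume_curve(flat, period = 0.2),
               class = "gatedlv_degenerate")
})
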