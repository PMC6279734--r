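test_that("a one-harmonic spec yields the closed-form cosine curve", {
  cv <- synthesize_curve(curve_spec(edv = 400, esv = 200, heart_rate = 300,
                                    n_harmonics = 1))
  expect_equal(cv$dc, 300, tolerance = 1e-8)
  expect_equal(cv$cos_coef, 100, tolerance = 1e-8)
  expect_equal(cv$sin_coef, 0, tolerance = 1e-6)
})

test_that("synthesized curves are periodic with exact analytic derivatives", {
  cv <- synthesize_curve(curve_spec(edv = 410.8, esv = 155.1,
                                    heart_rate = 331, pfr = 12.1,
                                    tpfr = 35.4))
  t <- seq(0, cv$period, length.out = 101)
  expect_equal(eval_volume(cv, t + cv$period), eval_volume(cv, t),
               tolerance = 1e-10)
  # Central finite differences agree with the closed-form derivative.
  h <- 1e-6
  fd <- (eval_volume(cv, t + h) - eval_volume(cv, t - h)) / (2 * h)
  expect_equal(fd, eval_dvdt(cv, t), tolerance = 1e-4)
  expect_true(min(eval_volume(cv, seq(0, cv$period, length.out = 4096))) >= 0)
})

test_that("generator and analytic measurement are self-consistent on random feasible specs", {
  for (seed in 1:12) {
    rf <- random_feasible_curve(seed)
    spec <- rf$spec
    m <- measure_curve(rf$curve)
    expect_lt(rel_err(m$edv, spec$edv), 0.005)
    expect_lt(rel_err(m$esv, spec$esv), 0.005)
    expect_lt(rel_err(m$pfr, spec$pfr), 0.005)
    expect_lt(abs(m$tpfr_ms - spec$tpfr) / (60000 / spec$heart_rate), 0.005)
    # Peak rate dominates the first-third mean on every curve.
    expect_gte(m$pfr, m$third_mfr)
  }
})

test_that("curves constrained on the one-third mean filling rate attain it", {
  spec <- curve_spec(edv = zl_truth$edv, esv = zl_truth$esv,
                     heart_rate = zl_truth$hr, third_mfr = zl_truth$third_mfr)
  m <- measure_curve(synthesize_curve(spec))
  expect_lt(rel_err(m$third_mfr, zl_truth$third_mfr), 0.005)
})

test_that("infeasible specs fail with explicit infeasibility errors", {
  # Zero stroke volume.
  expect_error(curve_spec(edv = 300, esv = 300, heart_rate = 300),
               class = "gatedlv_infeasible")
  # Peak filling rate below the forced mean filling rate.
  expect_error(
    synthesize_curve(curve_spec(edv = 400, esv = 100, heart_rate = 300,
                                pfr = 3, tpfr = 40)),
    class = "gatedlv_infeasible")
  # Near-square filling wave: a mean over the first third of filling at
  # ~99% of the peak is unattainable for a band-limited curve.
  expect_error(
    synthesize_curve(curve_spec(edv = zl_truth$edv, esv = zl_truth$esv,
                                heart_rate = zl_truth$hr, pfr = zl_truth$pfr,
                                tpfr = zl_truth$tpfr,
                                third_mfr = zl_truth$third_mfr)),
    class = "gatedlv_infeasible")
})
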