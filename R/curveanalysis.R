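#' Fit a periodic Fourier series to a gated volume curve
#'
#' Least-squares trigonometric fit of the 16-point (or `n_gates`-point)
#' gated volume samples. On a uniform gate grid the harmonics are mutually
#' orthogonal, so noiseless samples of a curve with at most
#' `floor((n_gates - 1) / 2)` harmonics are interpolated exactly and the
#' analytic derivative of the fit equals the true filling-rate curve.
#'
#' @param curve A gated volume curve: data frame with columns `t_s` and
#'   `volume_ul` (as returned by [sample_gate_volumes()] or
#'   [segment_series()]), with a `period` attribute or `period` supplied.
#' @param n_harmonics Harmonics to fit (default 4, a bias/variance
#'   compromise for noisy 16-gate data; use 6 for noiseless recovery).
#' @param period Cycle length, s (defaults to the curve's attribute).
#' @return A [fourier_curve()].
#' @export
fit_fourier <- function(curve, n_harmonics = 4, period = NULL) {
  period <- period %||% attr(curve, "period")
  if (is.null(period)) abort("`period` is required (attribute or argument).")
  t <- curve$t_s
  v <- curve$volume_ul
  n <- length(t)
  if (n_harmonics > floor((n - 1) / 2))
    abort(sprintf(
      "too many harmonics: %d samples support at most %d.",
      n, floor((n - 1) / 2)))
  w <- 2 * pi / period
  k <- seq_len(n_harmonics)
  X <- cbind(1, cos(outer(t, k * w)), sin(outer(t, k * w)))
  coef <- lm.fit(X, v)$coefficients
  fourier_curve(period, coef[1], coef[1 + k], coef[1 + n_harmonics + k])
}

#' Ejection fraction from the volume extrema
#'
#' EF = 100 (EDV - ESV) / EDV, the stroke volume as a percentage of the
#' end-diastolic volume.
#'
#' @param edv,esv End-diastolic and end-systolic volumes, µL.
#' @return EF in percent.
#' @examples
#' compute_ef(410.8, 155.1) # 62.24
#' @export
compute_ef <- function(edv, esv) {
  if (edv <= 0) abort("`edv` must be positive.")
  if (esv < 0 || esv > edv) abort("`esv` must lie in [0, edv].")
  100 * (edv - esv) / edv
}

#' Locate the fitted end-diastolic and end-systolic extrema
#'
#' Global maximum (end-diastole) and minimum (end-systole) of the fitted
#' volume curve over a dense grid, refined by local optimization.
#'
#' @param fit A [fourier_curve()].
#' @return A one-row tibble with `ed_phase`, `edv`, `es_phase`, `esv`.
#' @export
find_ed_es <- function(fit) {
  m <- measure_curve(fit)
  tibble(ed_phase = m$ed_phase, edv = m$edv,
         es_phase = m$es_phase, esv = m$esv)
}

#' Peak filling rate of a fitted curve
#'
#' Maximum of the analytic dV/dt over the filling interval (end-systole to
#' the next end-diastole), normalized by EDV.
#'
#' @param fit A [fourier_curve()].
#' @param edv End-diastolic volume, µL.
#' @param es_phase,ed_phase Phases of end-systole/end-diastole, s.
#' @return A one-row tibble with `pfr` (EDV/s) and `t_pfr_abs` (s, the
#'   arg-max time).
#' @export
compute_pfr <- function(fit, edv, es_phase, ed_phase) {
  T <- fit$period
  t_fill <- (ed_phase - es_phase) %% T
  if (t_fill == 0) abort("empty filling interval.", class = "gatedlv_degenerate")
  fs <- es_phase + seq(0, t_fill, length.out = 2048)
  dv <- eval_dvdt(fit, fs)
  pk <- refine_extremum(function(t) eval_dvdt(fit, t), fs, which.max(dv),
                        maximum = TRUE)
  tibble(pfr = pk$value / edv, t_pfr_abs = pk$t)
}

#' Time from end-systole to peak filling
#'
#' @param es_phase End-systolic phase, s.
#' @param t_pfr_abs Time of peak filling, s (same cycle convention).
#' @param period Cycle length, s.
#' @return TPFR in milliseconds, in `[0, period)`.
#' @export
compute_tpfr <- function(es_phase, t_pfr_abs, period) {
  ((t_pfr_abs - es_phase) %% period) * 1000
}

#' One-third mean filling rate of a fitted curve
#'
#' Mean of dV/dt over the first third of the filling time, evaluated
#' exactly as a volume chord (fundamental theorem of calculus), normalized
#' by EDV.
#'
#' @inheritParams compute_pfr
#' @return 1/3MFR in EDV/s.
#' @export
compute_third_mfr <- function(fit, edv, es_phase, ed_phase) {
  T <- fit$period
  t_fill <- (ed_phase - es_phase) %% T
  if (t_fill == 0) abort("empty filling interval.", class = "gatedlv_degenerate")
  (eval_volume(fit, es_phase + t_fill / 3) - eval_volume(fit, es_phase)) /
    (t_fill / 3) / edv
}

#' Analyze a gated volume curve
#'
#' The full curve-analysis stage: Fourier fit of the gated samples, location
#' of the volume extrema, and computation of the systolic and diastolic
#' functional parameters (EF, PFR, 1/3MFR, TPFR) from the fit's analytic
#' derivative.
#'
#' @inheritParams fit_fourier
#' @param hr Heart rate, bpm (default `60 / period`, exact for
#'   noiselessly sampled curves; pass the gating estimate for real streams).
#' @return A one-row tibble (see [measure_curve()] for columns).
#' @examples
#' cv <- synthesize_curve(curve_spec(edv = 400, esv = 200, heart_rate = 300,
#'                                   n_harmonics = 1))
#' analyze_volume_curve(sample_gate_volumes(cv), n_harmonics = 6)
#' @export
analyze_volume_curve <- function(curve, hr = NULL, n_harmonics = 4,
                                 period = NULL) {
  period <- period %||% attr(curve, "period") %||% (if (!is.null(hr)) 60 / hr)
  if (is.null(period)) abort("need `period` or `hr`.")
  fit <- fit_fourier(curve, n_harmonics = n_harmonics, period = period)
  out <- measure_curve(fit)
  if (!is.null(hr)) out$hr <- hr
  out
}
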