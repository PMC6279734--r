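#' Measure cardiac functional parameters of a continuous volume curve
#'
#' Evaluates a [fourier_curve()] on a dense grid (with local refinement of
#' every extremum) and returns the functional parameters of one cardiac
#' cycle: EDV and ESV from the global volume extrema, ejection fraction,
#' peak filling rate (max analytic dV/dt over the filling interval,
#' normalized by EDV), the one-third mean filling rate (exact mean of dV/dt
#' over the first third of the filling time, via the fundamental theorem of
#' calculus), the time from end-systole to peak filling, and heart rate.
#' This is the analytic oracle against which the gated sample-and-fit
#' pipeline ([analyze_volume_curve()]) is validated.
#'
#' @param curve A [fourier_curve()].
#' @param grid_n Dense-grid size per period (default 4096, at least 2048).
#' @return A one-row tibble with columns `edv`, `esv`, `stroke_volume`,
#'   `ef` (%), `pfr` (EDV/s), `third_mfr` (EDV/s), `tpfr_ms`, `hr` (bpm),
#'   `ed_phase`, `es_phase`, `t_pfr` (s), `period` (s).
#' @examples
#' cv <- fourier_curve(period = 0.2, dc = 300, cos_coef = 100, sin_coef = 0)
#' measure_curve(cv) # EDV 400, ESV 200, EF 50%, PFR 7.854 EDV/s, TPFR 50 ms
#' @export
measure_curve <- function(curve, grid_n = 4096) {
  stopifnot(inherits(curve, "fourier_curve"), grid_n >= 2048)
  T <- curve$period
  ts <- seq(0, T, length.out = grid_n + 1)[-(grid_n + 1)]
  vs <- eval_volume(curve, ts)

  if ((max(vs) - min(vs)) < 0.01 * abs(mean(vs)))
    abort("degenerate curve: volume range below 1% of mean; no filling phase.",
          class = "gatedlv_degenerate")

  ed <- refine_extremum(function(t) eval_volume(curve, t), ts, which.max(vs),
                        maximum = TRUE)
  es <- refine_extremum(function(t) eval_volume(curve, t), ts, which.min(vs),
                        maximum = FALSE)
  edv <- ed$value; esv <- es$value

  # Filling interval: end-systole to the next end-diastole.
  t_fill <- (ed$t - es$t) %% T
  if (t_fill == 0) t_fill <- T
  fs <- es$t + seq(0, t_fill, length.out = 2048)
  dv <- eval_dvdt(curve, fs)
  pk <- refine_extremum(function(t) eval_dvdt(curve, t), fs, which.max(dv),
                        maximum = TRUE)
  pfr <- pk$value / edv
  tpfr_ms <- ((pk$t - es$t) %% T) * 1000

  third <- (eval_volume(curve, es$t + t_fill / 3) - esv) / (t_fill / 3) / edv

  tibble(
    edv = edv, esv = esv, stroke_volume = edv - esv,
    ef = 100 * (edv - esv) / edv,
    pfr = pfr, third_mfr = third, tpfr_ms = tpfr_ms,
    hr = 60 / T,
    ed_phase = ed$t %% T, es_phase = es$t %% T, t_pfr = pk$t %% T,
    period = T)
}

# Refine a grid extremum by golden-section search in the bracketing interval.
refine_extremum <- function(f, ts, i, maximum) {
  n <- length(ts)
  dt <- ts[2] - ts[1]
  lo <- ts[i] - dt
  hi <- ts[i] + dt
  opt <- optimize(f, c(lo, hi), maximum = maximum, tol = 1e-12)
  if (maximum) list(t = opt$maximum, value = opt$objective)
  else list(t = opt$minimum, value = opt$objective)
}
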