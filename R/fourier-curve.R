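#' Band-limited periodic volume curve
#'
#' A `fourier_curve` is a truncated Fourier series
#' \deqn{V(t) = a_0 + \sum_{k=1}^{K} a_k \cos(k\omega t) + b_k \sin(k\omega t)}
#' with \eqn{\omega = 2\pi/T}. It represents a continuous periodic LV
#' time-volume curve with a closed-form analytic derivative, and serves both
#' as phantom ground truth and as the result of fitting gated volume samples.
#'
#' @param period Cycle length, s.
#' @param dc Constant (mean) coefficient \eqn{a_0}, µL.
#' @param cos_coef,sin_coef Numeric vectors of cosine/sine coefficients
#'   (µL), one per harmonic; must have equal length.
#'
#' @return An object of class `fourier_curve`.
#' @export
fourier_curve <- function(period, dc, cos_coef = numeric(), sin_coef = numeric()) {
  stopifnot(period > 0, length(cos_coef) == length(sin_coef))
  structure(list(period = as.numeric(period), dc = as.numeric(dc),
                 cos_coef = as.numeric(cos_coef),
                 sin_coef = as.numeric(sin_coef)),
            class = "fourier_curve")
}

n_harmonics <- function(curve) length(curve$cos_coef)

#' Evaluate a Fourier volume curve
#'
#' `eval_volume()` returns V(t) in µL; `eval_dvdt()` returns the exact
#' analytic derivative dV/dt in µL/s. Both are periodic in `period`.
#'
#' @param curve A [fourier_curve()].
#' @param t Times, s (any length; values outside one period wrap).
#' @return Numeric vector of the same length as `t`.
#' @export
eval_volume <- function(curve, t) {
  w <- 2 * pi / curve$period
  v <- rep(curve$dc, length(t))
  for (k in seq_along(curve$cos_coef)) {
    v <- v + curve$cos_coef[k] * cos(k * w * t) +
      curve$sin_coef[k] * sin(k * w * t)
  }
  v
}

#' @rdname eval_volume
#' @export
eval_dvdt <- function(curve, t) {
  w <- 2 * pi / curve$period
  v <- rep(0, length(t))
  for (k in seq_along(curve$cos_coef)) {
    v <- v + k * w * (-curve$cos_coef[k] * sin(k * w * t) +
                        curve$sin_coef[k] * cos(k * w * t))
  }
  v
}

# Antiderivative of V (µL·s), used for exact window averages.
eval_volume_integral <- function(curve, t) {
  w <- 2 * pi / curve$period
  v <- curve$dc * t
  for (k in seq_along(curve$cos_coef)) {
    v <- v + (curve$cos_coef[k] * sin(k * w * t) -
                curve$sin_coef[k] * cos(k * w * t)) / (k * w)
  }
  v
}

#' @export
print.fourier_curve <- function(x, ...) {
  cat(sprintf("<fourier_curve> period %.4f s, %d harmonic(s)\n",
              x$period, n_harmonics(x)))
  cat(sprintf("  dc %.2f uL; harmonic amplitude(s): %s uL\n", x$dc,
              paste(sprintf("%.2f", sqrt(x$cos_coef^2 + x$sin_coef^2)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.fourier_curve <- function(x, ...) {
  k <- seq_along(x$cos_coef)
  tibble(
    term = c("dc", paste0("cos", k), paste0("sin", k)),
    harmonic = c(0L, k, k),
    estimate = c(x$dc, x$cos_coef, x$sin_coef))
}

#' @export
glance.fourier_curve <- function(x, ...) {
  m <- measure_curve(x)
  m$n_harmonics <- n_harmonics(x)
  m
}

#' Plot a continuous volume curve and its filling-rate curve
#'
#' Draws V(t) over one cycle with the end-diastolic/end-systolic extrema and
#' the peak-filling instant marked, plus the analytic dV/dt trace.
#'
#' @param object A [fourier_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fourier_curve <- function(object, ...) {
  m <- measure_curve(object)
  ts <- seq(0, object$period, length.out = 512)
  df <- tibble(t_ms = rep(ts * 1000, 2),
               value = c(eval_volume(object, ts), eval_dvdt(object, ts)),
               panel = rep(c("Volume (uL)", "dV/dt (uL/s)"), each = length(ts)))
  marks <- tibble(
    t_ms = c(m$ed_phase, m$es_phase, m$t_pfr) * 1000,
    value = c(m$edv, m$esv, eval_dvdt(object, m$t_pfr)),
    panel = c("Volume (uL)", "Volume (uL)", "dV/dt (uL/s)"),
    label = c("ED", "ES", "PFR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, colour = "red") +
    ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$label),
                       vjust = -0.8, colour = "red", size = 3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time in cycle (ms)", y = NULL,
                  title = "LV time-volume curve") +
    ggplot2::theme_minimal()
}
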