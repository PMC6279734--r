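#' Sample a continuous volume curve at gate times
#'
#' Emulates the temporal discretization of cardiac gating: the cycle is cut
#' into `n_gates` equal windows and the curve is either read at the window
#' midpoints (`mode = "point"`) or averaged analytically over each window
#' (`mode = "window"`, the exact time-average via the curve's
#' antiderivative). Point sampling of a curve with at most
#' `floor((n_gates - 1)/2)` harmonics is information-complete: the Fourier
#' refit ([fit_fourier()]) recovers the coefficients exactly.
#'
#' @param curve A [fourier_curve()].
#' @param n_gates Number of gates per cycle (default 16, at least 4).
#' @param mode `"point"` or `"window"`.
#' @return A gated volume curve: tibble with columns `gate` (1-based),
#'   `t_s` (gate midpoint, s) and `volume_ul`, carrying attributes
#'   `period` and `gate_mode`.
#' @export
sample_gate_volumes <- function(curve, n_gates = 16, mode = c("point", "window")) {
  stopifnot(inherits(curve, "fourier_curve"), n_gates >= 4)
  mode <- match.arg(mode)
  T <- curve$period
  k <- seq_len(n_gates) - 1
  mid <- (k + 0.5) * T / n_gates
  vols <- if (mode == "point") {
    eval_volume(curve, mid)
  } else {
    lo <- k * T / n_gates
    hi <- (k + 1) * T / n_gates
    (eval_volume_integral(curve, hi) - eval_volume_integral(curve, lo)) /
      (T / n_gates)
  }
  new_volume_curve(gate = k + 1L, t_s = mid, volume_ul = vols,
                   period = T, gate_mode = mode)
}

new_volume_curve <- function(gate, t_s, volume_ul, period, gate_mode = "point") {
  out <- tibble(gate = as.integer(gate), t_s = t_s, volume_ul = volume_ul)
  attr(out, "period") <- period
  attr(out, "gate_mode") <- gate_mode
  class(out) <- c("volume_curve", class(out))
  out
}

curve_period <- function(vc) {
  p <- attr(vc, "period")
  if (is.null(p)) abort("volume curve lacks a `period` attribute.")
  p
}

#' Plot a gated volume curve
#'
#' @param data A gated volume-curve tibble (see [sample_gate_volumes()] or
#'   [segment_series()]), with an optional fitted [fourier_curve()] overlay.
#' @param fit Optional [fourier_curve()] drawn as a smooth line.
#' @return A ggplot object.
#' @export
plot_volume_curve <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$t_s * 1000,
                                          y = .data$volume_ul)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time in cycle (ms)", y = "Cavity volume (uL)",
                  title = "Gated LV volume curve") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    ts <- seq(0, fit$period, length.out = 512)
    p <- p + ggplot2::geom_line(
      data = tibble(t_s = ts, volume_ul = eval_volume(fit, ts)),
      colour = "steelblue")
  }
  p
}
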