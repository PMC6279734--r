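#' Simulate an ECG trigger stream
#'
#' R-R intervals are drawn i.i.d. Gaussian with mean `60 / mean_hr` and SD
#' `rr_jitter_sd`, truncated below at half the mean interval (redrawn), and
#' accumulated from time 0 until `duration_s` is covered. Zero jitter gives
#' a metronomic stream.
#'
#' @param duration_s Acquisition duration, s.
#' @param mean_hr Mean heart rate, bpm.
#' @param rr_jitter_sd SD of the R-R interval, s.
#' @param seed Integer seed; all randomness of the call flows from it.
#' @return Tibble with column `t_s`.
#' @export
simulate_triggers <- function(duration_s, mean_hr, rr_jitter_sd = 0, seed = 1) {
  stopifnot(duration_s > 0, mean_hr > 0, rr_jitter_sd >= 0)
  mean_rr <- 60 / mean_hr
  n_guess <- ceiling(duration_s / mean_rr * 1.5) + 10
  with_seed(seed, {
    rr <- numeric(0)
    while (sum(rr) < duration_s) {
      new <- rnorm(n_guess, mean_rr, rr_jitter_sd)
      while (any(bad <- new < 0.5 * mean_rr))
        new[bad] <- rnorm(sum(bad), mean_rr, rr_jitter_sd)
      rr <- c(rr, new)
    }
    t <- cumsum(c(0, rr))
    tibble(t_s = t[t <= duration_s])
  })
}

#' Simulate a gated list-mode acquisition of the beating phantom
#'
#' Generates an ECG trigger stream ([simulate_triggers()]) and an
#' annihilation-event stream from an inhomogeneous Poisson process whose
#' spatial density at time t is the phantom activity map at the cavity
#' volume V(phase(t)). The cycle is discretized into `n_phase` activity
#' maps; the total event count is Poisson with mean `config$total_counts`,
#' and each event receives a beat and phase bin (probability proportional
#' to time spent times map activity), a uniform time within that bin, a
#' voxel drawn from the map, and a uniform position within the voxel.
#'
#' @param config A [phantom_config()]; `total_counts` sets the expected
#'   total number of events.
#' @param curve A [fourier_curve()] ground-truth volume curve.
#' @param duration_s Acquisition duration, s (at least 10 cycles).
#' @param mean_hr Mean heart rate, bpm (default: the curve's `60/period`).
#' @param rr_jitter_sd R-R jitter SD, s.
#' @param seed Integer seed (single source of randomness).
#' @param n_phase Number of phase bins used to discretize the cycle.
#' @return A list with tibbles `events` (`t_s`, `x_mm`, `y_mm`, `z_mm`)
#'   and `triggers` (`t_s`).
#' @export
simulate_listmode <- function(config, curve, duration_s,
                              mean_hr = 60 / curve$period,
                              rr_jitter_sd = 0, seed = 1, n_phase = 32) {
  stopifnot(inherits(config, "phantom_config"), inherits(curve, "fourier_curve"))
  if (duration_s < 10 * 60 / mean_hr)
    abort("`duration_s` must cover at least 10 cardiac cycles.")

  triggers <- simulate_triggers(duration_s, mean_hr, rr_jitter_sd, seed = seed)
  t <- triggers$t_s
  rr <- diff(t)
  n_beats <- length(rr)

  # Per-phase-bin activity maps at the bin-midpoint cavity volume.
  phase_mid <- (seq_len(n_phase) - 0.5) / n_phase
  maps <- lapply(phase_mid, function(ph)
    voxelize_frame(config, eval_volume(curve, ph * curve$period))$data)
  map_sums <- vapply(maps, sum, numeric(1))
  dim3 <- config$grid_shape
  v <- config$voxel_size
  origin <- -(dim3 - 1) / 2 * v

  with_seed(seed + 1L, {
    n_events <- rpois(1, config$total_counts)
    # Joint (beat, bin) weights: time in bin (rr_i / n_phase) x bin activity.
    wt <- outer(rr / n_phase, map_sums)
    cell <- sample.int(length(wt), n_events, replace = TRUE,
                       prob = as.vector(wt))
    beat_i <- (cell - 1) %% n_beats + 1
    bin_i <- (cell - 1) %/% n_beats + 1
    t_ev <- t[beat_i] + (bin_i - 1 + runif(n_events)) / n_phase * rr[beat_i]

    # Spatial draw: voxel index from the bin's map, uniform within voxel.
    vox <- integer(n_events)
    for (b in seq_len(n_phase)) {
      sel <- bin_i == b
      if (!any(sel)) next
      vox[sel] <- sample.int(prod(dim3), sum(sel), replace = TRUE,
                             prob = as.vector(maps[[b]]))
    }
    ijk <- arrayInd(vox, dim3)
    x <- origin[1] + (ijk[, 1] - 1) * v + (runif(n_events) - 0.5) * v
    y <- origin[2] + (ijk[, 2] - 1) * v + (runif(n_events) - 0.5) * v
    z <- origin[3] + (ijk[, 3] - 1) * v + (runif(n_events) - 0.5) * v

    ord <- order(t_ev)
    list(events = tibble(t_s = t_ev[ord], x_mm = x[ord], y_mm = y[ord],
                         z_mm = z[ord]),
         triggers = triggers)
  })
}
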