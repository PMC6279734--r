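#' Gated image series container
#'
#' Gate-indexed 3D count (or activity) volumes with grid geometry and
#' gating metadata. Built by [gate_series()] from list-mode events or by
#' [phantom_gated_series()] from the noiseless phantom.
#'
#' @param data 4D array (x, y, z, gate).
#' @param voxel_size Isotropic voxel size, mm.
#' @param origin mm coordinates of voxel (1,1,1)'s center.
#' @param period Cycle length estimate, s.
#' @param gate_times Gate midpoint times within the cycle, s.
#' @param accepted_beats,rejected_beats Beat counts from gating.
#' @param extra Optional named list merged into the object.
#' @return An object of class `gated_series`.
#' @keywords internal
new_gated_series <- function(data, voxel_size, origin, period, gate_times,
                             accepted_beats, rejected_beats, extra = list()) {
  obj <- c(list(data = data, n_gates = dim(data)[4], voxel_size = voxel_size,
                origin = as.numeric(origin), period = period,
                gate_times = gate_times, accepted_beats = accepted_beats,
                rejected_beats = rejected_beats), extra)
  structure(obj, class = "gated_series")
}

#' @export
print.gated_series <- function(x, ...) {
  cat(sprintf("<gated_series> %s voxels x %d gates @ %.3g mm, period %.4g s\n",
              paste(dim(x$data)[1:3], collapse = "x"), x$n_gates,
              x$voxel_size, x$period))
  if (!is.na(x$accepted_beats))
    cat(sprintf("  beats: %d accepted, %d rejected; total counts %.4g\n",
                x$accepted_beats, x$rejected_beats, sum(x$data)))
  invisible(x)
}

# One gate as a pet_image.
gate_image <- function(series, gate) {
  pet_image(series$data[, , , gate], series$voxel_size, series$origin)
}

# Gate-summed image (used for the shared LV center).
sum_image <- function(series) {
  d <- dim(series$data)
  arr <- array(rowSums(matrix(series$data, prod(d[1:3]), d[4])), dim = d[1:3])
  pet_image(arr, series$voxel_size, series$origin)
}

# R-R rejection shared by HR estimation and gate assignment: a beat is
# accepted when its R-R interval deviates from the median of all intervals
# by at most `window` (fractional).
accept_rr <- function(rr, reject = TRUE, window = 0.3) {
  if (!reject) return(rep(TRUE, length(rr)))
  med <- median(rr)
  abs(rr - med) <= window * med
}

#' Estimate heart rate from an ECG trigger stream
#'
#' HR is 60 over the mean accepted R-R interval. Beats whose R-R interval
#' deviates more than `window` (default 30%) from the median interval are
#' rejected as arrhythmic/mistriggered and excluded from the mean.
#'
#' @param triggers Data frame with column `t_s` (strictly increasing R-wave
#'   times, s), or a numeric vector of times.
#' @param reject Apply R-R rejection (default TRUE).
#' @param window Fractional rejection window around the median R-R.
#' @return One-row tibble: `hr` (bpm), `rr_mean_s`, `rr_sd_s`, `n_beats`,
#'   `n_rejected`.
#' @examples
#' estimate_heart_rate(tibble::tibble(t_s = seq(0, 2, by = 0.2))) # 300 bpm
#' @export
estimate_heart_rate <- function(triggers, reject = TRUE, window = 0.3) {
  t <- trigger_times(triggers)
  if (length(t) < 3) abort("need at least 3 triggers (2 beats).")
  rr <- diff(t)
  keep <- accept_rr(rr, reject, window)
  if (!any(keep)) abort("all beats rejected; no R-R intervals left.")
  if (sum(keep) < 2) abort("fewer than 2 accepted R-R intervals.")
  tibble(hr = 60 / mean(rr[keep]), rr_mean_s = mean(rr[keep]),
         rr_sd_s = sd(rr[keep]), n_beats = sum(keep),
         n_rejected = sum(!keep))
}

trigger_times <- function(triggers) {
  t <- if (is.data.frame(triggers)) triggers$t_s else as.numeric(triggers)
  if (length(t) == 0) abort("empty trigger stream.")
  if (any(diff(t) <= 0)) abort("trigger times must be strictly increasing.")
  t
}

#' Assign list-mode events to cardiac gates
#'
#' Each event is located in its enclosing beat `[T_i, T_(i+1))`; accepted
#' beats are divided into `n_gates` equal phase bins of their own R-R
#' interval, and the event's gate is `floor(n_gates * phase)` (0-based,
#' clamped to `n_gates - 1`). Events before the first trigger, at or after
#' the last, or inside rejected beats are kept in the output with a status
#' label but no gate, so that counts are conserved and auditable.
#'
#' @param events Data frame with columns `t_s`, `x_mm`, `y_mm`, `z_mm`.
#' @param triggers Trigger stream (see [estimate_heart_rate()]).
#' @param n_gates Gates per cycle (default 16, at least 4).
#' @inheritParams estimate_heart_rate
#' @return The events tibble plus columns `beat` (1-based), `gate`
#'   (0-based phase index, `NA` for discarded events) and `status`
#'   (`"accepted"`, `"rejected_beat"`, `"out_of_range"`).
#' @export
assign_gates <- function(events, triggers, n_gates = 16, reject = TRUE,
                         window = 0.3) {
  stopifnot(n_gates >= 4)
  t <- trigger_times(triggers)
  ev <- as_tibble(events)
  rr <- diff(t)
  keep <- accept_rr(rr, reject, window)

  beat <- findInterval(ev$t_s, t)
  in_range <- beat >= 1 & beat <= length(rr) & ev$t_s < t[length(t)]
  status <- ifelse(!in_range, "out_of_range",
                   ifelse(keep[pmax(beat, 1)], "accepted", "rejected_beat"))
  phase <- rep(NA_real_, nrow(ev))
  ok <- status == "accepted"
  phase[ok] <- (ev$t_s[ok] - t[beat[ok]]) / rr[beat[ok]]
  gate <- ifelse(ok, pmin(floor(n_gates * phase), n_gates - 1), NA_real_)

  ev$beat <- ifelse(in_range, beat, NA_integer_)
  ev$gate <- as.integer(gate)
  ev$status <- status
  attr(ev, "n_gates") <- as.integer(n_gates)
  attr(ev, "accepted_beats") <- sum(keep)
  attr(ev, "rejected_beats") <- sum(!keep)
  ev
}

#' Histogram one gate's events onto a voxel grid
#'
#' Nearest-voxel deposition: each event increments the voxel whose center
#' is closest to its position. Events falling outside the grid are counted
#' in the `out_of_grid` attribute, never silently dropped.
#'
#' @param events Data frame with `x_mm`, `y_mm`, `z_mm`.
#' @param dim Integer vector of 3 voxel counts.
#' @param voxel_size Isotropic voxel size, mm (must be positive).
#' @param origin mm coordinates of voxel (1,1,1)'s center (default:
#'   grid centered on 0).
#' @return A [pet_image()] of counts with attribute `out_of_grid`.
#' @export
histogram_gate <- function(events, dim, voxel_size, origin = NULL) {
  if (voxel_size <= 0) abort("`voxel_size` must be positive.")
  dim <- as.integer(dim)
  if (is.null(origin)) origin <- -(dim - 1) / 2 * voxel_size
  i <- round((events$x_mm - origin[1]) / voxel_size) + 1
  j <- round((events$y_mm - origin[2]) / voxel_size) + 1
  k <- round((events$z_mm - origin[3]) / voxel_size) + 1
  ok <- i >= 1 & i <= dim[1] & j >= 1 & j <= dim[2] & k >= 1 & k <= dim[3]
  idx <- (i[ok] - 1) + (j[ok] - 1) * dim[1] + (k[ok] - 1) * dim[1] * dim[2] + 1
  arr <- array(tabulate(idx, nbins = prod(dim)), dim = dim)
  img <- pet_image(arr, voxel_size, origin)
  attr(img, "out_of_grid") <- sum(!ok)
  img
}

#' Gate a list-mode acquisition into an image series
#'
#' The gating stage: R-R rejection and heart-rate estimation from the
#' trigger stream, phase assignment of every event, and per-gate
#' nearest-voxel histogramming into a 4D count series.
#'
#' @inheritParams assign_gates
#' @inheritParams histogram_gate
#' @return A `gated_series`; attributes of interest include per-gate
#'   counts and the discarded-event count.
#' @export
gate_series <- function(events, triggers, dim, voxel_size, origin = NULL,
                        n_gates = 16, reject = TRUE, window = 0.3) {
  hr <- estimate_heart_rate(triggers, reject, window)
  ev <- assign_gates(events, triggers, n_gates, reject, window)
  dim <- as.integer(dim)
  if (is.null(origin)) origin <- -(dim - 1) / 2 * voxel_size
  arr <- array(0, dim = c(dim, n_gates))
  out_of_grid <- 0L
  for (g in seq_len(n_gates) - 1L) {
    sub <- ev[!is.na(ev$gate) & ev$gate == g, ]
    img <- histogram_gate(sub, dim, voxel_size, origin)
    arr[, , , g + 1] <- img$data
    out_of_grid <- out_of_grid + attr(img, "out_of_grid")
  }
  new_gated_series(
    arr, voxel_size = voxel_size, origin = origin, period = 60 / hr$hr,
    gate_times = (seq_len(n_gates) - 0.5) / n_gates * (60 / hr$hr),
    accepted_beats = attr(ev, "accepted_beats"),
    rejected_beats = attr(ev, "rejected_beats"),
    extra = list(hr = hr$hr,
                 discarded_events = sum(ev$status != "accepted"),
                 out_of_grid = out_of_grid))
}
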