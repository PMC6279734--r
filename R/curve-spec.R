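#' Specify a ground-truth left-ventricular time-volume curve
#'
#' A `curve_spec` collects the functional parameters a synthesized
#' time-volume curve must attain: the end-diastolic and end-systolic cavity
#' volumes, the heart rate, and optionally the diastolic indices (peak filling
#' rate, time to peak filling, one-third mean filling rate).  It is the
#' ground-truth record against which every downstream recovery test is judged.
#'
#' @param edv End-diastolic volume, µL. Must exceed `esv`.
#' @param esv End-systolic volume, µL. Must be positive.
#' @param heart_rate Heart rate, beats per minute. The cycle length is
#'   `60 / heart_rate` seconds.
#' @param pfr Optional peak filling rate: maximum dV/dt during filling,
#'   normalized by EDV (units 1/s, conventionally written EDV/s).
#' @param tpfr Optional time from end-systole to peak filling, ms. Must be
#'   shorter than the cycle. Required context for `pfr` placement; if `pfr`
#'   is given without `tpfr` the synthesizer places the peak freely.
#' @param third_mfr Optional one-third mean filling rate: mean dV/dt over the
#'   first third of the filling time, normalized by EDV (EDV/s). When both
#'   are given, `pfr >= third_mfr` is required (a maximum dominates the mean
#'   over a sub-interval).
#' @param n_harmonics Number of Fourier harmonics available to the
#'   synthesizer (default 6, at most 7: the Nyquist limit for 16 gates).
#'
#' @return An object of class `curve_spec` (a named list).
#' @examples
#' curve_spec(edv = 400, esv = 200, heart_rate = 300)
#' @export
curve_spec <- function(edv, esv, heart_rate, pfr = NULL, tpfr = NULL,
                       third_mfr = NULL, n_harmonics = 6) {
  spec <- structure(
    list(edv = as.numeric(edv), esv = as.numeric(esv),
         heart_rate = as.numeric(heart_rate),
         pfr = if (!is.null(pfr)) as.numeric(pfr),
         tpfr = if (!is.null(tpfr)) as.numeric(tpfr),
         third_mfr = if (!is.null(third_mfr)) as.numeric(third_mfr),
         n_harmonics = as.integer(n_harmonics)),
    class = "curve_spec")
  validate_curve_spec(spec)
  spec
}

validate_curve_spec <- function(spec) {
  period_ms <- 60 / spec$heart_rate * 1000
  if (!is.finite(spec$edv) || !is.finite(spec$esv) || spec$esv <= 0)
    abort("`esv` must be positive and finite.", class = "gatedlv_infeasible")
  if (spec$edv <= spec$esv)
    abort(sprintf(
      "infeasible curve spec: edv (%.3g) must exceed esv (%.3g); zero or negative stroke volume.",
      spec$edv, spec$esv), class = "gatedlv_infeasible")
  if (spec$heart_rate <= 0)
    abort("`heart_rate` must be positive.", class = "gatedlv_infeasible")
  if (!is.null(spec$tpfr) && (spec$tpfr <= 0 || spec$tpfr >= period_ms))
    abort(sprintf(
      "infeasible curve spec: tpfr (%.3g ms) must lie strictly inside the cycle (%.3g ms).",
      spec$tpfr, period_ms), class = "gatedlv_infeasible")
  if (!is.null(spec$pfr) && !is.null(spec$third_mfr) &&
      spec$pfr < spec$third_mfr)
    abort(sprintf(
      "infeasible curve spec: pfr (%.3g) < third_mfr (%.3g); the peak rate cannot be below the mean over the first third of filling.",
      spec$pfr, spec$third_mfr), class = "gatedlv_infeasible")
  if (spec$n_harmonics < 1 || spec$n_harmonics > 7)
    abort("`n_harmonics` must be between 1 and 7 (Nyquist limit for 16 gates).")
  invisible(spec)
}

#' @export
print.curve_spec <- function(x, ...) {
  cat("<curve_spec>\n")
  cat(sprintf("  EDV %.1f uL, ESV %.1f uL, HR %.1f bpm (period %.1f ms)\n",
              x$edv, x$esv, x$heart_rate, 60000 / x$heart_rate))
  if (!is.null(x$pfr)) cat(sprintf("  PFR %.2f EDV/s\n", x$pfr))
  if (!is.null(x$tpfr)) cat(sprintf("  TPFR %.1f ms\n", x$tpfr))
  if (!is.null(x$third_mfr)) cat(sprintf("  1/3MFR %.2f EDV/s\n", x$third_mfr))
  cat(sprintf("  harmonics available: %d\n", x$n_harmonics))
  invisible(x)
}

#' Read or write a curve specification as YAML
#'
#' Field names in the YAML file match the arguments of [curve_spec()]
#' (`edv`, `esv`, `heart_rate`, `pfr`, `tpfr`, `third_mfr`, `n_harmonics`).
#'
#' @param path File path.
#' @return `read_curve_spec()` returns a `curve_spec`;
#'   `write_curve_spec()` returns `path` invisibly.
#' @export
read_curve_spec <- function(path) {
  y <- yaml::read_yaml(path)
  curve_spec(edv = y$edv, esv = y$esv, heart_rate = y$heart_rate,
             pfr = y$pfr, tpfr = y$tpfr, third_mfr = y$third_mfr,
             n_harmonics = y$n_harmonics %||% 6)
}

#' @param spec A `curve_spec`.
#' @rdname read_curve_spec
#' @export
write_curve_spec <- function(spec, path) {
  stopifnot(inherits(spec, "curve_spec"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(spec)), path)
  invisible(path)
}
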