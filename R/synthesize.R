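#' Synthesize a band-limited volume curve attaining specified parameters
#'
#' Constructs a truncated Fourier series V(t) (end-diastole at t = 0) whose
#' measured functional parameters reproduce a [curve_spec()]. For a candidate
#' end-systolic phase the requested parameters are linear equality
#' constraints on the Fourier coefficients (volumes and slopes at fixed
#' phases, stationarity at the extrema and at the filling peak, and the
#' chord identity defining the one-third mean filling rate); the
#' coefficients minimizing a spectral roughness penalty subject to those
#' constraints come from the KKT system in closed form. The end-systolic
#' phase itself is found by an outer one-dimensional search minimizing the
#' worst relative deviation between the curve's *measured* parameters
#' ([measure_curve()]) and the spec. If no phase brings every deviation
#' within `tol` the spec is declared infeasible.
#'
#' Feasibility is a real constraint, not a formality: a smooth band-limited
#' curve has dV/dt = 0 at end-systole, so specs demanding a one-third mean
#' filling rate at (or within a fraction of a percent of) the peak filling
#' rate request a near-square filling wave no low-harmonic curve can attain,
#' and are rejected with an explicit error.
#'
#' @param spec A [curve_spec()].
#' @param n_harmonics Harmonics to use (default: the spec's, usually 6).
#' @param tol Verification tolerance, relative (default 0.005 = 0.5%;
#'   TPFR is judged relative to the cycle length).
#' @return A [fourier_curve()] with attributes `spec` (the input) and
#'   `achieved` (the [measure_curve()] row of the returned curve).
#' @examples
#' cv <- synthesize_curve(curve_spec(edv = 400, esv = 200, heart_rate = 300,
#'                                   n_harmonics = 1))
#' measure_curve(cv)$ef # 50
#' @export
synthesize_curve <- function(spec, n_harmonics = spec$n_harmonics, tol = 0.005) {
  validate_curve_spec(spec)
  K <- n_harmonics
  T <- 60 / spec$heart_rate
  sv <- spec$edv - spec$esv
  tpfr_s <- if (!is.null(spec$tpfr)) spec$tpfr / 1000

  # Necessary condition: the peak filling rate must exceed the mean filling
  # rate forced by the stroke volume and the longest plausible filling time.
  if (!is.null(spec$pfr)) {
    min_pfr <- sv / (0.85 * T) / spec$edv
    if (spec$pfr < min_pfr)
      abort(sprintf(
        "infeasible curve spec: pfr (%.3g EDV/s) is below the mean filling rate (>= %.3g EDV/s) forced by the stroke volume and available filling time.",
        spec$pfr, min_pfr), class = "gatedlv_infeasible")
  }

  score_at <- function(t_es) {
    curve <- solve_coefficients(spec, K, T, t_es, tpfr_s)
    m <- tryCatch(measure_curve(curve), error = function(e) NULL)
    if (is.null(m)) return(list(viol = Inf, curve = curve, m = NULL, worst = "degenerate curve"))
    dev <- c(
      edv = abs(m$edv - spec$edv) / spec$edv,
      esv = abs(m$esv - spec$esv) / spec$esv,
      if (!is.null(spec$pfr)) c(pfr = abs(m$pfr - spec$pfr) / spec$pfr),
      if (!is.null(spec$tpfr)) c(tpfr = abs(m$tpfr_ms - spec$tpfr) / (T * 1000)),
      if (!is.null(spec$third_mfr))
        c(third_mfr = abs(m$third_mfr - spec$third_mfr) / spec$third_mfr))
    v <- max(dev)
    # A curve dipping below zero volume is unphysical however well it scores.
    if (min(eval_volume(curve, seq(0, T, length.out = 2048))) < 0) v <- Inf
    list(viol = v, curve = curve, m = m, worst = names(dev)[which.max(dev)])
  }

  # Candidate end-systolic phases; the filling peak (if placed) must fit
  # strictly inside the filling interval.
  frac <- seq(0.15, 0.70, by = 0.0125)
  if (!is.null(tpfr_s)) frac <- frac[tpfr_s < (1 - frac) * T * 0.95]
  if (length(frac) == 0)
    abort("infeasible curve spec: tpfr leaves no room for a filling interval.",
          class = "gatedlv_infeasible")

  scores <- lapply(frac * T, score_at)
  viols <- map_dbl(scores, "viol")
  i <- which.min(viols)
  best <- scores[[i]]

  # Local refinement of the end-systolic phase around the best grid point.
  lo <- frac[max(1, i - 1)] * T
  hi <- frac[min(length(frac), i + 1)] * T
  if (hi > lo && is.finite(best$viol) && best$viol > 1e-12) {
    opt <- optimize(function(t_es) score_at(t_es)$viol, c(lo, hi), tol = T * 1e-6)
    cand <- score_at(opt$minimum)
    if (cand$viol < best$viol) best <- cand
  }

  if (!is.finite(best$viol) || best$viol > tol)
    abort(sprintf(
      "infeasible curve spec: no band-limited curve (%d harmonics) attains the targets; worst residual %.2g%% on '%s' (tolerance %.2g%%).",
      K, 100 * best$viol, best$worst, 100 * tol),
      class = "gatedlv_infeasible")

  structure(best$curve, spec = spec, achieved = best$m)
}

# Penalized constrained least squares for fixed end-systolic phase.
# Coefficients c = (a0, a1..aK, b1..bK); minimize c' P c  s.t.  A c = b,
# with P a spectral roughness penalty (k^4, the curvature energy weight).
solve_coefficients <- function(spec, K, T, t_es, tpfr_s) {
  w <- 2 * pi / T
  basis_row <- function(t, deriv = 0) {
    k <- seq_len(K)
    switch(as.character(deriv),
      "0" = c(1, cos(k * w * t), sin(k * w * t)),
      "1" = c(0, -k * w * sin(k * w * t), k * w * cos(k * w * t)),
      "2" = c(0, -(k * w)^2 * cos(k * w * t), -(k * w)^2 * sin(k * w * t)))
  }

  A <- rbind(basis_row(0), basis_row(0, 1), basis_row(t_es), basis_row(t_es, 1))
  b <- c(spec$edv, 0, spec$esv, 0)

  has_peak <- !is.null(spec$pfr) || !is.null(spec$tpfr)
  if (has_peak) {
    t_fill <- T - t_es
    t_p <- t_es + (if (!is.null(tpfr_s)) tpfr_s else 0.3 * t_fill)
    A <- rbind(A, basis_row(t_p, 2))
    b <- c(b, 0)
    if (!is.null(spec$pfr)) {
      A <- rbind(A, basis_row(t_p, 1))
      b <- c(b, spec$pfr * spec$edv)
    }
  }
  if (!is.null(spec$third_mfr)) {
    t_fill <- T - t_es
    t13 <- t_es + t_fill / 3
    A <- rbind(A, basis_row(t13) - basis_row(t_es))
    b <- c(b, spec$third_mfr * spec$edv * t_fill / 3)
  }

  # Regularized least squares: the lambda -> 0 limit of
  # ||A c - b||^2 + lambda c' P c is the P-minimal solution among
  # least-squares minimizers, i.e. the roughness-minimal curve satisfying
  # every satisfiable constraint; inconsistent constraint sets (too few
  # harmonics for the requested shape) degrade gracefully and are caught by
  # the measurement-based verification.
  rn <- sqrt(rowSums(A^2))
  As <- A / rn
  bs <- b / rn
  P <- diag(c(1, rep((seq_len(K))^4, 2)))
  coef <- drop(solve(crossprod(As) + 1e-9 * P, crossprod(As, bs)))
  fourier_curve(T, coef[1], coef[2:(K + 1)], coef[(K + 2):(2 * K + 1)])
}
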