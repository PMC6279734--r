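# Shared fixtures: reference study-condition values and small fast phantoms.

# Lean-control (ZL) group means used as recovery truths throughout.
zl_truth <- list(edv = 410.8, esv = 155.1, hr = 331, ef = 62.5,
                 pfr = 12.1, third_mfr = 12.0, tpfr = 35.4)
zdf_truth <- list(edv = 478.8, esv = 194.1, hr = 309, ef = 59.4,
                  pfr = 10.2, third_mfr = 9.9, tpfr = 40.0)

# Closed-form single-harmonic curve V(t) = 300 + 100 cos(2 pi t / 0.2) uL.
cosine_curve <- function() fourier_curve(0.2, 300, 100, 0)

# Small phantom configuration for fast segmentation tests.
fast_phantom <- function(total_counts = 1e5, ...) {
  phantom_config(wall_thickness = 2, long_axis_ratio = 1.8,
                 psf_fwhm = 0.8, voxel_size = 1,
                 grid_shape = c(28, 28, 28), total_counts = total_counts,
                 ...)
}

fast_seg <- function(...) {
  seg_config(upsample_factor = 3, n_directions = 500, ...)
}

# Random feasible curve for property-style tests: parameters are drawn
# from physiological ranges and redrawn until the generator accepts them
# (feasibility is solver-defined), mirroring how cohorts are sampled.
random_feasible_curve <- function(seed) {
  set.seed(seed)
  for (try in 1:50) {
    edv <- runif(1, 300, 520)
    esv <- edv * (1 - runif(1, 0.40, 0.70))
    hr <- runif(1, 250, 400)
    T <- 60 / hr
    tpfr <- runif(1, 0.15, 0.30) * T * 1000
    pfr <- runif(1, 1.9, 2.8) * (edv - esv) / (0.65 * T) / edv
    spec <- curve_spec(edv = edv, esv = esv, heart_rate = hr,
                       pfr = pfr, tpfr = tpfr)
    cv <- tryCatch(synthesize_curve(spec), gatedlv_infeasible = function(e) NULL)
    if (!is.null(cv)) return(list(spec = spec, curve = cv))
  }
  stop("no feasible random spec after 50 draws")
}

# Circular phase distance within a period.
phase_dist <- function(a, b, period) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
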