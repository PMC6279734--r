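---
title: "Methods: phantom-verified assessment of LV systolic and diastolic function from gated PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-verified assessment of LV systolic and diastolic function from gated PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

ECG-gated ^18^F-FDG PET can measure left-ventricular (LV) function beyond
glucose utilization: sorting list-mode coincidences by cardiac phase into 16
frames per cycle yields a time-volume curve V(t), from which both systolic
indices (end-diastolic and end-systolic volume EDV/ESV, ejection fraction
EF) and diastolic filling indices are read. The diastolic set is the
interesting one in diabetic cardiomyopathy, where impaired filling precedes
any fall in EF:

* **PFR** — peak filling rate, the maximum of dV/dt during filling,
  normalized by EDV (units EDV/s);
* **1/3MFR** — mean dV/dt over the first third of the filling time,
  normalized by EDV;
* **TPFR** — time from end-systole to the instant of peak filling (ms).

In rats these are produced by commercial edge-detection software whose
algorithm is unpublished, and raw animal data are generally unavailable.
This package therefore rebuilds the whole measurement chain as open,
testable code and verifies every stage by *parameter recovery* against a
digital beating-LV phantom whose ground truth is known exactly. The
default study conditions — the cohort means and SDs in
`cohort_spec_zl()` / `cohort_spec_zdf()` — emulate reported gated FDG-PET
values in lean control and diabetic fatty Zucker rats (preserved EF and
HR, reduced PFR and 1/3MFR, prolonged TPFR in the diabetic phenotype).

## The volume-curve model

All continuous curves are truncated Fourier series with end-diastole at
phase zero,

$$V(t) = a_0 + \sum_{k=1}^{K} a_k \cos(k\omega t) + b_k \sin(k\omega t),
\qquad \omega = 2\pi/T,$$

with $K \le 7$, the Nyquist limit for 16 gates. Band-limitation is the
load-bearing choice: 16 uniform point samples determine such a curve
*exactly* (discrete orthogonality of the harmonics), so the
sample-and-fit analysis stage is information-complete on noiseless
phantoms and recovery tests have sharp expected values instead of fuzzy
ones. dV/dt is always the closed-form derivative of the fit, never a
finite difference of 16 samples, which would bias PFR low.

### Synthesis as constrained least squares

`synthesize_curve()` turns a target parameter set (EDV, ESV, HR, and
optionally PFR, TPFR, 1/3MFR) into coefficients. For a *fixed*
end-systolic phase $t_{es}$ every target is a linear functional of the
coefficients: volumes and stationarity at $t = 0$ and $t_{es}$, slope
value and stationarity at the filling peak $t_{es} + \mathrm{TPFR}$, and
the chord identity
$V(t_{es} + T_f/3) - V(t_{es}) = \tfrac{T_f}{3}\,\mathrm{1/3MFR}\cdot\mathrm{EDV}$
that *defines* the one-third mean filling rate through the fundamental
theorem of calculus. Among all coefficient vectors satisfying the
constraints we take the one minimizing a spectral roughness penalty
$\sum_k k^4 (a_k^2+b_k^2)$, computed as the $\lambda \to 0$ limit of ridge
regression (row-normalized constraints, $\lambda = 10^{-9}$), which is
numerically robust even when a constraint set is unsatisfiable at the
requested harmonic budget. $t_{es}$ itself is found by an outer
one-dimensional search (grid at 1.25% of the cycle plus golden-section
refinement) minimizing the worst *measured* deviation — measurement
meaning `measure_curve()`: dense-grid (4096/period) extrema with local
optimizer refinement, exactly the oracle used by the tests.

A spec is **infeasible** when no end-systolic phase brings every measured
parameter within 0.5% of target (TPFR judged against the cycle length).
This is a real physical boundary, not bookkeeping. A smooth periodic
curve has dV/dt = 0 at end-systole, so the mean filling rate over the
first third of filling can only approach the *peak* rate if dV/dt rises
almost instantaneously — and a band-limited curve cannot rise faster than
its highest harmonic allows. Specifying PFR = 12.1 EDV/s together with
1/3MFR = 12.0 EDV/s (values that a 16-gate commercial analysis can
plausibly print, since its discrete first-third average never sees the
true zero-slope instant) requests exactly such a square wave, and the
generator rejects it with an explicit error naming the worst residual.
Consequently the package recovers PFR/TPFR and 1/3MFR on *separate*
ground-truth curves — one constrained on the peak, one on the chord — and
cohort simulation imposes {EDV, ESV, HR, PFR, TPFR} and lets each
subject's 1/3MFR be whatever its smooth curve achieves. The drawn 1/3MFR
is recorded for reference. Group separation in 1/3MFR survives because it
is strongly coupled to PFR.

## The phantom

`voxelize_frame()` renders the LV as a prolate half-ellipsoid shell, apex
down, open at the basal plane: cavity semi-axes $(a, a, \lambda a)$ with
$\lambda$ = `long_axis_ratio` (default 1.8), so the cavity volume is
$\tfrac{2}{3}\pi\lambda a^3$ and the semi-axes for any requested volume
are closed-form — the analytic truth stored with every frame. The
myocardium lies between this surface and an outer ellipsoid offset by
`wall_thickness` (default 2 mm; the offset surface is itself an
ellipsoid, so wall thickness varies by a few percent with latitude, which
is harmless for volumetry and keeps every geometric query closed-form).
Myocardium has relative activity 1, cavity and exterior
`background_ratio` (default 0.1, an FDG blood-pool-to-myocardium contrast
typical of insulin-clamped acquisitions). Rendering samples a 3× subgrid,
applies the Gaussian PSF (`psf_fwhm`, default 0.8 mm, small-animal-PET
scale) by separable convolution on that subgrid, and block-averages to
the target voxel size — i.e. blur acts on the continuous object before
sampling, as in a real system.

What the phantom deliberately does *not* model: sinogram formation and
OSEM reconstruction (events are deposited in image space), attenuation,
scatter, randoms, dead time, decay, respiratory motion, right-heart and
atrial structures, and regional wall-motion abnormality (motion is purely
radial). Passing recovery tests therefore demonstrates correctness of the
gating/segmentation/curve mathematics under idealized imaging, not
robustness to reconstruction artifacts of real scanners.

`simulate_listmode()` draws R-R intervals Gaussian
(`60/mean_hr`, `rr_jitter_sd`, truncated below at half the mean — a
simple, controllable arrhythmia surrogate), then draws events from an
inhomogeneous Poisson process whose spatial density at time $t$ is the
activity map at cavity volume $V(\mathrm{phase}(t))$, discretized at 32
phase bins. Expected totals follow `total_counts`; every operation takes
one explicit seed and restores the caller's RNG state.

## Gating

`assign_gates()` locates each event in its beat $[T_i, T_{i+1})$ and bins
it at `floor(n_gates * phase)` of that beat's own R-R interval (0-based
internally; reports label gates from 1). Beats whose R-R deviates more
than 30% from the median interval are rejected; partial beats at the
stream edges are discarded. Nothing vanishes silently: every event
carries a status (`accepted`, `rejected_beat`, `out_of_range`) and the
conservation identity (gated + discarded = input) is asserted by tests.
Heart rate is 60 over the mean accepted R-R interval, which on jitter-free
streams is exact to floating point.

## Segmentation

`segment_series()` mirrors count-based cardiac volumetry practice:

1. **Upsample** each gate 5× by trilinear interpolation (the rat-heart
   adaptation of clinical analysis software), intensity-preserving.
2. **One shared center** from the gate-summed image — the
   intensity-weighted centroid of voxels above 50% of the 99th percentile
   (computed over positive voxels), restricted to the largest 6-connected
   component. A shared center stabilizes low-count gates; motion is
   radial in the phantom.
3. **Sampling origin on the valve plane.** The basal plane is estimated
   as the top of the thresholded myocardial mask (with symmetric blur the
   50% boundary sits on the true edge), and the radial origin is placed
   0.5 mm below it on the long axis. From there the cavity is star-shaped
   and the *apical hemisphere* of rays sees myocardium everywhere, so a
   hemispheric cone sum plus a thin basal cap integrates the volume
   exactly in the continuum — whereas sampling from the activity centroid
   leaves a wide basal cone with no wall and, closed at the 30° ring,
   loses a large basal slab of cavity. The basal exclusion half-angle is
   configurable (`basal_exclusion_deg`, default 90).
4. **Radial wall fits.** Along ~700 Fibonacci-lattice directions
   (≥ 300 in the sampled hemisphere) the profile is read at half-fine-voxel
   steps and a Gaussian over background is fit to the dominant peak; R²
   < 0.8 or an out-of-range peak flags the ray invalid (imputed as the
   median of its 10 nearest valid neighbours; a gate with < 80% valid
   rays is unreliable and reported, not guessed).
5. **Edge convention.** The endocardial radius defaults to the
   *inflection point of an error-function edge model* fit to the
   cavity-side flank. The classical alternative — the inner half-maximum
   of the wall Gaussian, $\mu - \sigma\sqrt{2\ln 2}$, available as
   `seg_config(edge_method = "half_max")` — is biased inward whenever the
   wall is not fully resolved: partial-volume averaging attenuates the
   peak, the half-max level drops, and the crossing moves inside the true
   edge by $\sigma_b\,\Phi^{-1}(f/2)$ for attenuation factor $f$. At the
   package's reference resolution (2 mm wall, 0.8 mm PSF, 1 mm voxels,
   effective profile sigma ≈ 0.6 mm) that costs 6–9% of cavity volume.
   The inflection of a blurred step sits on the interface *irrespective
   of amplitude*, which restores volumetric accuracy to within ±3%
   across the EDV–ESV range; the recovery tests assert 5%.
6. **Volume** is the solid-angle-weighted cone sum
   $V = \sum_d \tfrac{\Delta\Omega_d}{3} r_d^3$ (1 mm³ = 1 µL), plus the
   basal cap: each excluded ray ends at the nearer of the cap plane and
   the cylinder bounded by the basal ring of detected radii, which
   integrates the 0.5 mm slab above the sampling origin.

The long axis is taken as the grid z axis, matching the phantom's
orientation convention; real data would need a reorientation step before
this stage.

## Curve analysis

`analyze_volume_curve()` fits the gated volumes (least squares on the
harmonic design matrix; default 4 harmonics for noisy count data, 6 for
noiseless oracle work — a bias/variance trade-off at 16 gates), locates
ED/ES as dense-grid-plus-refinement extrema of the fit, and computes
EF = 100(EDV−ESV)/EDV, PFR as the maximum analytic dV/dt over the filling
interval (ES to next ED) normalized by EDV, TPFR as the modular time gap
from ES to that maximum, and 1/3MFR as the exact chord mean over the
first third of filling. Gate values are treated as point samples at gate
midpoints; the generator's window-averaging mode exists precisely to
quantify that approximation (a $\mathrm{sinc}(\pi k/16)$ attenuation per
harmonic, about 0.6% at the fundamental).

## Statistics

Group comparisons use the classic pooled-variance two-tailed Student
t-test (Welch available as a flag), in both raw-data form (delegated to
`stats::t.test`) and summary-statistics form (the hand formula, needed to
reproduce significance claims from published mean ± SD tables; the two
forms agree exactly by construction and by test). Zero pooled variance
with equal means returns p = 1; with unequal means it is an error. No
multiple-testing correction is applied — each parameter is reported at
its own alpha, as is common in small-animal functional studies — and the
serialized report says so in its footer. `run_cohort_experiment()` ties
the loop: draw both cohorts, synthesize each subject, run the 16-gate
analysis, compare. With n = 6 per group and the default effect sizes,
the analytic power at alpha = 0.01 is ≈ 0.67 for PFR, so the diastolic
deficit is detected in most but not all simulated studies; the test suite
asserts detection rates at alpha = 0.05 (power ≈ 0.9) over a dozen seeds.

## Numerical choices and problem sizes

* Dense measurement grids: 4096 points/period (2048 over the filling
  interval), each extremum refined by `optimize()` in its bracketing
  interval; degenerate curves (range < 1% of mean) error out rather than
  returning noise-driven phases.
* Synthesis verification tolerance: 0.5% relative per parameter (TPFR
  relative to the cycle), the same bound the recovery tests assert.
* Ray profiles: step = half a fine voxel; Gaussian and erf fits via
  Levenberg–Marquardt with box bounds; fit windows are the contiguous
  run above 20% (Gaussian) / 10% (erf flank) of peak amplitude.
* Routine tests run phantoms at 28³ voxels of 1 mm with 3× upsampling
  and 400–500 rays; the reference volumetric recovery uses 32³ at 1 mm
  with 5× upsampling (0.2 mm effective) and 700 rays. List-mode tests
  use 2×10⁴–2×10⁵ events over 3–20 s. These sizes were chosen so the
  full suite exercises every stage, including two end-to-end noisy
  pipelines, in a few minutes on one CPU.
* All randomness flows through per-operation integer seeds; no global
  RNG state leaks (`with_seed` saves and restores `.Random.seed`).

## Known limitations

* The phantom's idealizations listed above; in particular there is no
  reconstruction model, so resolution effects enter only through the
  PSF and voxel chain.
* The basal cap assumes an approximately planar valve ring orthogonal to
  the grid z axis.
* The erf edge convention assumes symmetric blur and similar backgrounds
  on both sides of the wall; strong cavity-to-exterior contrast
  asymmetry would bias it.
* Cohort parameters are drawn independently per subject, whereas real
  EDV and ESV are strongly correlated within animals; derived per-subject
  EF therefore scatters more than the group summaries it emulates, making
  the simulated "EF not significant" outcome conservative.
* Specs combining a peak and a first-third constraint near equality are
  rejected as infeasible rather than approximated; users wanting "as
  close as possible" behaviour must relax one constraint explicitly.
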