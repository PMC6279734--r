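#' Segmentation configuration
#'
#' Tunable parameters of the count-based LV cavity volumetry stage
#' ([segment_series()] and friends).
#'
#' @param upsample_factor Integer magnification of the voxel grid before
#'   edge detection (default 5, matching the rat-heart adaptation of
#'   clinical gated analysis software).
#' @param n_directions Number of quasi-uniform ray directions over the full
#'   sphere before basal exclusion (default 400, leaving >= 300 sampled).
#' @param basal_exclusion_deg Half-angle (degrees) of the cone around the
#'   basal long axis (+z) excluded from ray detection; the open base of the
#'   half-ellipsoid shell has no wall there. Closed by a flat cap bounded
#'   by the basal ring. The default 90 excludes the whole basal hemisphere:
#'   [segment_series()] places the sampling origin on the valve plane, from
#'   where every apical-hemisphere ray meets myocardium and the cavity is
#'   star-shaped, so the hemispheric cone sum plus a thin cap is exact.
#' @param basal_margin How far below the estimated basal plane the sampling
#'   origin is placed, mm (default 0.5); the slab above it is recovered by
#'   the cap term of [cavity_volume()].
#' @param window_frac Profile fit window: the contiguous region around the
#'   dominant peak above `window_frac` of the peak amplitude over
#'   background.
#' @param r2_min Minimum R^2 of a ray's Gaussian wall fit to count as
#'   valid.
#' @param min_valid_frac Minimum fraction of valid rays per gate; below it
#'   the gate is flagged unreliable.
#' @param edge_method Endocardial radius convention. `"erf"` (default)
#'   takes the inflection point of an error-function edge model fit to the
#'   cavity-side flank of the wall profile — amplitude-free, hence
#'   unbiased when blur attenuates the peak of a thin wall.
#'   `"half_max"` takes the inner half-maximum of the fitted wall
#'   Gaussian, `mu - sigma * sqrt(2 log 2)`; it underestimates the cavity
#'   when the wall is not fully resolved (see the package vignette).
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(upsample_factor = 5, n_directions = 700,
                       basal_exclusion_deg = 90, basal_margin = 0.5,
                       window_frac = 0.2, r2_min = 0.8,
                       min_valid_frac = 0.8,
                       edge_method = c("erf", "half_max")) {
  structure(list(upsample_factor = as.integer(upsample_factor),
                 n_directions = as.integer(n_directions),
                 basal_exclusion_deg = basal_exclusion_deg,
                 basal_margin = basal_margin,
                 window_frac = window_frac, r2_min = r2_min,
                 min_valid_frac = min_valid_frac,
                 edge_method = match.arg(edge_method)),
            class = "seg_config")
}

#' Upsample an image by trilinear interpolation
#'
#' Interpolates onto a grid with `voxel_size / factor`, covering the same
#' physical extent (edge voxels extend as constants). The result is
#' rescaled so total intensity times voxel volume is preserved.
#'
#' @param image A [pet_image()].
#' @param factor Integer magnification (>= 1).
#' @return A [pet_image()] on the finer grid.
#' @export
upsample_image <- function(image, factor = 5) {
  stopifnot(inherits(image, "pet_image"), factor >= 1,
            factor == as.integer(factor))
  factor <- as.integer(factor)
  if (factor == 1) return(image)
  v <- image$voxel_size
  vf <- v / factor
  d <- dim(image$data)
  out <- image$data
  origin_f <- numeric(3)
  for (axi in 1:3) {
    xc <- image$origin[axi] + (seq_len(d[axi]) - 1) * v
    n_f <- d[axi] * factor
    xf <- (image$origin[axi] - v / 2 + vf / 2) + (seq_len(n_f) - 1) * vf
    origin_f[axi] <- xf[1]
    out <- apply_along(out, linear_interp_matrix(xc, xf), axi)
  }
  integral_in <- sum(image$data) * v^3
  integral_out <- sum(out) * vf^3
  if (integral_out > 0) out <- out * (integral_in / integral_out)
  pet_image(out, vf, origin_f)
}

# Sparse-in-spirit 1D linear interpolation matrix from coarse centers `xc`
# to fine centers `xf`, constant extrapolation at the edges.
linear_interp_matrix <- function(xc, xf) {
  n <- length(xc)
  i0 <- findInterval(xf, xc)
  i0 <- pmin(pmax(i0, 1), n - 1)
  frac <- (xf - xc[i0]) / (xc[i0 + 1] - xc[i0])
  frac <- pmin(pmax(frac, 0), 1)
  M <- matrix(0, length(xf), n)
  M[cbind(seq_along(xf), i0)] <- 1 - frac
  M[cbind(seq_along(xf), i0 + 1)] <- M[cbind(seq_along(xf), i0 + 1)] + frac
  M
}

# Trilinear sampling of a pet_image at arbitrary mm points (n x 3 matrix);
# points outside the grid return 0.
sample_trilinear <- function(image, pts) {
  d <- dim(image$data)
  v <- image$voxel_size
  fx <- (pts[, 1] - image$origin[1]) / v + 1
  fy <- (pts[, 2] - image$origin[2]) / v + 1
  fz <- (pts[, 3] - image$origin[3]) / v + 1
  inside <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  out <- numeric(nrow(pts))
  if (!any(inside)) return(out)
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  i0 <- pmin(floor(fx), d[1] - 1); wx <- fx - i0
  j0 <- pmin(floor(fy), d[2] - 1); wy <- fy - j0
  k0 <- pmin(floor(fz), d[3] - 1); wz <- fz - k0
  at <- function(i, j, k) image$data[cbind(i, j, k)]
  val <-
    at(i0,     j0,     k0)     * (1 - wx) * (1 - wy) * (1 - wz) +
    at(i0 + 1, j0,     k0)     * wx       * (1 - wy) * (1 - wz) +
    at(i0,     j0 + 1, k0)     * (1 - wx) * wy       * (1 - wz) +
    at(i0 + 1, j0 + 1, k0)     * wx       * wy       * (1 - wz) +
    at(i0,     j0,     k0 + 1) * (1 - wx) * (1 - wy) * wz +
    at(i0 + 1, j0,     k0 + 1) * wx       * (1 - wy) * wz +
    at(i0,     j0 + 1, k0 + 1) * (1 - wx) * wy       * wz +
    at(i0 + 1, j0 + 1, k0 + 1) * wx       * wy       * wz
  out[inside] <- val
  out
}

#' Locate the LV center in a myocardial activity image
#'
#' Intensity-weighted centroid of the voxels above 50% of the 99th
#' percentile intensity (percentile taken over the positive voxels, so
#' that sparse count images are not thresholded at zero), restricted to
#' the largest 6-connected component of that mask — disjoint hot
#' structures do not drag the center.
#'
#' @param image A [pet_image()] with positive maximum.
#' @return Length-3 mm coordinates.
#' @export
find_lv_center <- function(image) {
  stopifnot(inherits(image, "pet_image"))
  if (max(image$data) <= 0) abort("image has no positive intensity.")
  thr <- 0.5 * quantile(image$data[image$data > 0], 0.99, names = FALSE)
  mask <- image$data >= thr
  if (!any(mask)) abort("empty mask at 50% of the 99th percentile.")
  comp <- largest_component(mask)
  w <- image$data * comp
  tot <- sum(w)
  d <- dim(image$data)
  ctr <- vapply(1:3, function(axi) {
    co <- image$origin[axi] + (seq_len(d[axi]) - 1) * image$voxel_size
    grid <- switch(axi,
                   array(co, d),
                   array(rep(co, each = d[1]), d),
                   array(rep(co, each = d[1] * d[2]), d))
    sum(w * grid) / tot
  }, numeric(1))
  ctr
}

# Largest 6-connected component of a logical 3D mask, via vectorized
# breadth-first flooding over linear indices.
largest_component <- function(mask) {
  d <- dim(mask)
  nxy <- d[1] * d[2]
  remaining <- which(mask)
  labels <- integer(length(mask))
  lab <- 0L
  in_mask <- mask
  visited <- array(FALSE, d)
  neighbor_shift <- function(idx) {
    k <- (idx - 1) %/% nxy + 1
    r <- (idx - 1) %% nxy
    j <- r %/% d[1] + 1
    i <- r %% d[1] + 1
    c(idx[i > 1] - 1L, idx[i < d[1]] + 1L,
      idx[j > 1] - d[1], idx[j < d[2]] + d[1],
      idx[k > 1] - nxy, idx[k < d[3]] + nxy)
  }
  best_size <- 0L
  best <- NULL
  while (length(remaining) > 0) {
    lab <- lab + 1L
    seedv <- remaining[1]
    comp <- integer(0)
    frontier <- seedv
    visited[frontier] <- TRUE
    while (length(frontier) > 0) {
      comp <- c(comp, frontier)
      nb <- unique(neighbor_shift(frontier))
      nb <- nb[in_mask[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
    if (length(comp) > best_size) {
      best_size <- length(comp)
      best <- comp
    }
    remaining <- remaining[!visited[remaining]]
  }
  out <- array(FALSE, d)
  out[best] <- TRUE
  out
}

# Quasi-uniform unit vectors on the sphere (Fibonacci lattice); each
# carries solid angle 4*pi/n.
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Detect the endocardial surface by radial profile fitting
#'
#' From the LV center, the intensity profile along each of a quasi-uniform
#' set of ray directions is extracted (step: half a fine voxel) and a
#' Gaussian (over a locally estimated background) is fit to its dominant
#' peak — the mid-myocardial wall crossing at radius mu with width sigma.
#' The endocardial radius is the inner half-maximum of that Gaussian,
#' `mu - sigma * sqrt(2 log 2)`. Rays whose fit fails the quality gates
#' (R^2, peak inside the search range) are flagged invalid and their radius
#' imputed as the median of the nearest valid neighbors. Rays within the
#' basal exclusion cone (open base of the shell) are not fit at all; the
#' cavity there is closed by a flat cap in [cavity_volume()].
#'
#' @param image A [pet_image()] (typically upsampled; see
#'   [upsample_image()]).
#' @param center Length-3 mm coordinates of the radial sampling origin
#'   (see [find_lv_center()] and [basal_plane_z()]).
#' @param config A [seg_config()].
#' @param cap_height Height of the basal closure plane above `center`, mm
#'   (stored for [cavity_volume()]; `NULL` to estimate from the basal ring).
#' @return An object of class `endocardial_surface`: directions, radii
#'   (mm), validity flags, solid-angle weight, exclusion info.
#' @export
detect_endocardium <- function(image, center, config = seg_config(),
                               cap_height = NULL) {
  stopifnot(inherits(image, "pet_image"))
  dirs <- fibonacci_directions(config$n_directions)
  cos_excl <- cos(config$basal_exclusion_deg * pi / 180)
  excluded <- dirs[, "z"] > cos_excl & config$basal_exclusion_deg > 0

  step <- image$voxel_size / 2
  d <- dim(image$data)
  r_max <- min((d - 1) * image$voxel_size) / 2
  radii <- seq(step, r_max, by = step)

  fit_radius <- rep(NA_real_, nrow(dirs))
  valid <- rep(FALSE, nrow(dirs))
  for (di in which(!excluded)) {
    pts <- cbind(center[1] + radii * dirs[di, 1],
                 center[2] + radii * dirs[di, 2],
                 center[3] + radii * dirs[di, 3])
    prof <- sample_trilinear(image, pts)
    f <- fit_wall_profile(radii, prof, window_frac = config$window_frac,
                          r2_min = config$r2_min,
                          edge_method = config$edge_method)
    if (!is.null(f)) {
      fit_radius[di] <- f$radius
      valid[di] <- TRUE
    }
  }

  n_sampled <- sum(!excluded)
  if (sum(valid) < config$min_valid_frac * n_sampled)
    abort(sprintf(
      "unreliable gate: only %d/%d rays produced a valid wall fit.",
      sum(valid), n_sampled), class = "gatedlv_unreliable_gate")

  # Impute invalid rays from the nearest valid directions.
  for (di in which(!excluded & !valid)) {
    sim <- dirs[valid, , drop = FALSE] %*% dirs[di, ]
    nn <- order(sim, decreasing = TRUE)[seq_len(min(10, sum(valid)))]
    fit_radius[di] <- median(fit_radius[valid][nn])
  }

  structure(list(center = center, directions = dirs, radii = fit_radius,
                 valid = valid, excluded = excluded,
                 solid_angle = 4 * pi / nrow(dirs),
                 basal_exclusion_deg = config$basal_exclusion_deg,
                 cap_height = cap_height),
            class = "endocardial_surface")
}

# Wall fit for one radial intensity profile.  A Gaussian over background is
# fit to the contiguous region around the dominant peak (above
# `window_frac` of the amplitude) to localize the wall and gate quality;
# the endocardial radius then comes from the configured edge convention.
fit_wall_profile <- function(r, y, window_frac = 0.2, r2_min = 0.8,
                             edge_method = "erf") {
  if (all(y <= 0) || length(r) < 8) return(NULL)
  b0 <- quantile(y, 0.05, names = FALSE)
  ipk <- which.max(y)
  amp <- y[ipk] - b0
  if (amp <= 0) return(NULL)
  thr <- b0 + window_frac * amp
  lo <- ipk
  while (lo > 1 && y[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk
  while (hi < length(y) && y[hi + 1] >= thr) hi <- hi + 1
  if (hi - lo + 1 < 5) return(NULL)
  # Plateau-like profiles (uniform image) have no localized peak.
  if ((hi - lo + 1) > 0.8 * length(y)) return(NULL)
  rw <- r[lo:hi]
  yw <- y[lo:hi]
  sg0 <- max((rw[length(rw)] - rw[1]) / 2.355, diff(r)[1])
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      yw ~ b + a * exp(-0.5 * ((rw - mu) / sg)^2),
      start = list(b = b0, a = amp, mu = r[ipk], sg = sg0),
      lower = c(0, 0, rw[1], diff(r)[1] / 2),
      upper = c(max(y), 2 * max(y), rw[length(rw)], diff(range(r))),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((yw - mean(yw))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  if (r2 < r2_min) return(NULL)
  if (cf["mu"] <= rw[1] || cf["mu"] >= rw[length(rw)]) return(NULL)
  radius_hm <- unname(cf["mu"] - cf["sg"] * sqrt(2 * log(2)))
  radius <- if (edge_method == "half_max") radius_hm
            else fit_edge_inflection(r, y, b0, amp, ipk, radius_hm) %||%
              radius_hm
  if (!is.finite(radius) || radius <= 0) return(NULL)
  list(radius = radius, mu = unname(cf["mu"]), sg = unname(cf["sg"]),
       r2 = r2)
}

# Inflection point of an error-function edge model fit to the cavity-side
# flank (background through peak).  The inflection of a blurred step sits
# on the true interface irrespective of amplitude, so this convention is
# robust to the partial-volume attenuation of an unresolved wall.
fit_edge_inflection <- function(r, y, b0, amp, ipk, m0) {
  thr <- b0 + 0.1 * amp
  lo <- ipk
  while (lo > 1 && y[lo - 1] >= thr) lo <- lo - 1
  lo <- max(1, lo - 4)
  win <- lo:ipk
  if (length(win) < 6) return(NULL)
  rw <- r[win]
  yw <- y[win]
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      yw ~ b + c * pnorm((rw - m) / s),
      start = list(b = b0, c = amp, m = max(min(m0, max(rw)), min(rw)),
                   s = max(2 * diff(r)[1], 0.3)),
      lower = c(0, 0, rw[1], diff(r)[1] / 2),
      upper = c(max(y), 3 * max(y), rw[length(rw)], diff(range(rw))),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  m <- stats::coef(fit)[["m"]]
  if (m <= rw[1] || m >= rw[length(rw)]) return(NULL)
  m
}

#' Cavity volume of a detected endocardial surface
#'
#' Solid-angle-weighted cone sum over the sampled directions,
#' \eqn{V = \sum_d (\Delta\Omega_d / 3) r_d^3}, in µL (1 mm³ = 1 µL).
#' Directions inside the basal exclusion cone are closed with a flat cap:
#' the disk bounded by the basal ring of detected radii (each excluded ray
#' ends at the nearer of the ring plane and the ring's bounding cylinder).
#'
#' @param surface An `endocardial_surface` from [detect_endocardium()], or
#'   any list with `directions`, `radii`, `solid_angle` (and optionally
#'   `excluded`, `center`).
#' @return Volume in µL.
#' @export
cavity_volume <- function(surface) {
  dirs <- surface$directions
  r <- surface$radii
  dOm <- surface$solid_angle
  excl <- surface$excluded %||% rep(FALSE, nrow(dirs))
  v <- sum(dOm / 3 * r[!excl]^3)
  if (any(excl)) {
    # Basal ring: sampled directions closest to the exclusion boundary;
    # they bound the disk that closes the open base.
    cosz <- dirs[, "z"]
    cos_excl <- cos(surface$basal_exclusion_deg * pi / 180)
    ring <- which(!excl & cosz > cos_excl - 0.12 & is.finite(r))
    if (length(ring) < 3)
      abort("cannot close the basal cap: no ring of valid rays.")
    rho_cap <- mean(r[ring] * sqrt(pmax(0, 1 - cosz[ring]^2)))
    z_cap <- surface$cap_height %||%
      max(0, mean(r[ring] * cosz[ring]))
    ct <- cosz[excl]
    st <- sqrt(pmax(0, 1 - ct^2))
    r_cap <- pmin(ifelse(ct > 1e-9, z_cap / ct, Inf),
                  ifelse(st > 1e-9, rho_cap / st, Inf))
    r_cap[!is.finite(r_cap)] <- 0
    v <- v + sum(dOm / 3 * r_cap^3)
  }
  v
}

#' Estimate the basal (valve) plane of the LV shell
#'
#' The half-ellipsoid myocardium ends at the basal plane; with a symmetric
#' blur, the 50%-of-peak mask boundary sits on the true edge, so the top of
#' the thresholded myocardial mask (largest connected component) estimates
#' the basal z coordinate.
#'
#' @param image A [pet_image()] (typically the upsampled gate-summed
#'   image).
#' @return Basal plane z, mm.
#' @export
basal_plane_z <- function(image) {
  thr <- 0.5 * quantile(image$data[image$data > 0], 0.99, names = FALSE)
  mask <- image$data >= thr
  if (!any(mask)) abort("empty myocardial mask.")
  comp <- largest_component(mask)
  kz <- which(apply(comp, 3, any))
  image$origin[3] + (max(kz) - 1) * image$voxel_size
}

#' Cavity volume of a single frame
#'
#' Convenience wrapper running the full volumetry chain on one image:
#' upsample, locate the LV center and basal plane, place the radial
#' sampling origin on the long axis just below the base, detect the
#' endocardium over the apical hemisphere and integrate the cavity volume
#' with its basal cap.
#'
#' @param image A [pet_image()] (original resolution).
#' @param config A [seg_config()].
#' @return Volume in µL, with attribute `surface`.
#' @export
segment_frame <- function(image, config = seg_config()) {
  up <- upsample_image(image, config$upsample_factor)
  ctr <- find_lv_center(up)
  z_base <- basal_plane_z(up)
  origin <- c(ctr[1], ctr[2], z_base - config$basal_margin)
  surf <- detect_endocardium(up, origin, config,
                             cap_height = config$basal_margin)
  v <- cavity_volume(surf)
  attr(v, "surface") <- surf
  v
}

#' Segment a gated image series into a volume curve
#'
#' The full volumetry stage: the gate-summed image is upsampled and used to
#' locate one shared LV center (stabilizing low-count gates); each gate is
#' then upsampled, its endocardial surface detected, and its cavity volume
#' integrated. Gates whose detection is unreliable are reported with
#' `NA` volume and flagged.
#'
#' @param series A `gated_series`.
#' @param config A [seg_config()].
#' @return A gated volume curve (tibble `gate`, `t_s`, `volume_ul`, plus
#'   `n_valid_rays` and `reliable`), with attributes `period`, `center`.
#' @export
segment_series <- function(series, config = seg_config()) {
  stopifnot(inherits(series, "gated_series"))
  total <- upsample_image(sum_image(series), config$upsample_factor)
  ctr <- find_lv_center(total)
  z_base <- basal_plane_z(total)
  center <- c(ctr[1], ctr[2], z_base - config$basal_margin)
  res <- lapply(seq_len(series$n_gates), function(g) {
    img <- upsample_image(gate_image(series, g), config$upsample_factor)
    surf <- tryCatch(detect_endocardium(img, center, config,
                                        cap_height = config$basal_margin),
                     error = function(e) {
                       if (inherits(e, "gatedlv_unreliable_gate")) NULL
                       else stop(e)
                     })
    if (is.null(surf)) {
      warn(sprintf("gate %d: unreliable edge detection; volume set NA.", g))
      return(tibble(gate = g, volume_ul = NA_real_, n_valid_rays = 0L,
                    reliable = FALSE))
    }
    tibble(gate = g, volume_ul = cavity_volume(surf),
           n_valid_rays = sum(surf$valid), reliable = TRUE)
  })
  out <- list_rbind(res)
  out$t_s <- series$gate_times
  out <- out[, c("gate", "t_s", "volume_ul", "n_valid_rays", "reliable")]
  attr(out, "period") <- series$period
  attr(out, "gate_mode") <- "point"
  attr(out, "center") <- center
  class(out) <- c("volume_curve", class(out))
  out
}
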