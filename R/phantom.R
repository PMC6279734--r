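#' Configure the beating-LV shell phantom
#'
#' The left ventricle is modeled as a prolate half-ellipsoid shell: the
#' cavity is the lower half (apex down) of an ellipsoid with equal short
#' semi-axes `a` and long semi-axis `b = long_axis_ratio * a`, open at the
#' basal plane; the myocardium is the region between that surface and an
#' outer ellipsoid offset by `wall_thickness`. FDG-avid myocardium sits at
#' `myocardial_activity`; cavity and exterior at `background_ratio` times
#' that. Cavity volume is `(2/3) * pi * long_axis_ratio * a^3`, so the
#' semi-axes for any requested volume are solved in closed form.
#'
#' @param wall_thickness Myocardial wall thickness, mm.
#' @param long_axis_ratio Semi-long to semi-short axis ratio (default 1.8,
#'   a typical rat-LV base-to-apex proportion).
#' @param myocardial_activity Relative myocardial tracer concentration.
#' @param background_ratio Cavity/exterior concentration as a fraction of
#'   the myocardial one (default 0.1).
#' @param psf_fwhm Isotropic Gaussian resolution blur, FWHM in mm.
#' @param voxel_size Isotropic voxel size, mm.
#' @param grid_shape Integer vector of 3 voxel counts (x, y, z).
#' @param total_counts Expected number of coincidence events in a simulated
#'   list-mode acquisition (see [simulate_listmode()]).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(wall_thickness = 2, long_axis_ratio = 1.8,
                           myocardial_activity = 1, background_ratio = 0.1,
                           psf_fwhm = 0.8, voxel_size = 1,
                           grid_shape = c(32, 32, 32), total_counts = 5e5) {
  stopifnot(wall_thickness > 0, long_axis_ratio > 0,
            background_ratio >= 0, background_ratio < 1,
            voxel_size > 0, length(grid_shape) == 3, all(grid_shape >= 4))
  structure(list(wall_thickness = wall_thickness,
                 long_axis_ratio = long_axis_ratio,
                 myocardial_activity = myocardial_activity,
                 background_ratio = background_ratio,
                 psf_fwhm = psf_fwhm, voxel_size = voxel_size,
                 grid_shape = as.integer(grid_shape),
                 total_counts = total_counts),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @param path YAML file with exactly the fields of [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(phantom_config, y)
}

# Inner semi-axes (a, b) of the half-ellipsoid cavity holding `volume_ul`.
cavity_semi_axes <- function(volume_ul, long_axis_ratio) {
  a <- (3 * volume_ul / (2 * pi * long_axis_ratio))^(1 / 3)
  c(a = a, b = long_axis_ratio * a)
}

#' 3D image container
#'
#' A minimal geometry-aware wrapper for a 3D voxel array: isotropic voxel
#' size in mm and the mm coordinate of the first voxel's center. Phantom
#' images place the basal plane of the LV at the grid center.
#'
#' @param data 3D numeric array.
#' @param voxel_size Isotropic voxel size, mm.
#' @param origin Length-3 mm coordinates of voxel (1,1,1)'s center
#'   (default: grid centered on 0).
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(data, voxel_size, origin = NULL) {
  stopifnot(length(dim(data)) == 3, voxel_size > 0)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel_size
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image> %s voxels @ %.3g mm; total intensity %.4g\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size,
              sum(x$data)))
  invisible(x)
}

# Voxel-center coordinates along one axis.
axis_coords <- function(img, axis) {
  img$origin[axis] + (seq_len(dim(img$data)[axis]) - 1) * img$voxel_size
}

# Multiply a 3D array along one axis by matrix M (rows = new length):
# the workhorse for separable interpolation and separable Gaussian blur.
apply_along <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(d[axis], prod(d[-axis]))
  y <- M %*% x
  dim(y) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(y, order(perm))
}

# Row-normalized Gaussian convolution matrix for grid coordinates `x`.
gaussian_matrix <- function(x, sigma) {
  if (sigma <= 0) return(diag(length(x)))
  M <- exp(-outer(x, x, "-")^2 / (2 * sigma^2))
  M / rowSums(M)
}

#' Voxelize one frame of the shell phantom
#'
#' Renders the half-ellipsoid shell whose enclosed cavity volume equals
#' `cavity_volume` (semi-axes solved analytically, so the true volume is
#' exact and stored as metadata). The continuous phantom is sampled on a
#' 3x-finer subgrid, blurred there with the configured Gaussian PSF, and
#' block-averaged to the target grid, which models resolution loss and
#' partial-volume averaging of the scanner/reconstruction chain.
#'
#' @param config A [phantom_config()].
#' @param cavity_volume Cavity volume for this frame, µL.
#' @param blur Apply the PSF blur (default TRUE; set FALSE for geometric
#'   ground-truth images).
#' @param subsample Subgrid refinement factor for antialiased rendering.
#' @return A [pet_image()] with attribute `cavity_volume_ul` (the analytic
#'   truth) and `semi_axes`.
#' @export
voxelize_frame <- function(config, cavity_volume, blur = TRUE, subsample = 3L) {
  stopifnot(inherits(config, "phantom_config"), cavity_volume > 0)
  ax <- cavity_semi_axes(cavity_volume, config$long_axis_ratio)
  a <- ax[["a"]]; b <- ax[["b"]]
  ao <- a + config$wall_thickness
  bo <- b + config$wall_thickness
  v <- config$voxel_size
  n <- config$grid_shape
  half <- n * v / 2
  if (ao >= half[1] || ao >= half[2] || bo >= half[3])
    abort(sprintf(
      "phantom exceeds grid: outer semi-axes (%.2f, %.2f) mm vs half-extents (%s) mm.",
      ao, bo, paste(sprintf("%.1f", half), collapse = ", ")))

  s <- as.integer(subsample)
  vf <- v / s
  nf <- n * s
  coords <- lapply(1:3, function(i) (seq_len(nf[i]) - (nf[i] + 1) / 2) * vf)

  # Occupancy on the fine grid (basal plane z = 0, apex at z = -b).
  x2 <- coords[[1]]^2
  y2 <- coords[[2]]^2
  z <- coords[[3]]
  r2 <- outer(x2, y2, "+")
  act <- array(config$background_ratio, dim = nf)
  for (kz in seq_len(nf[3])) {
    if (z[kz] > 0) next
    u_in <- r2 / a^2 + z[kz]^2 / b^2
    u_out <- r2 / ao^2 + z[kz]^2 / bo^2
    sl <- act[, , kz]
    sl[u_out <= 1 & u_in > 1] <- 1
    act[, , kz] <- sl
  }
  act <- act * config$myocardial_activity

  if (blur && config$psf_fwhm > 0) {
    sigma <- config$psf_fwhm / (2 * sqrt(2 * log(2)))
    for (axi in 1:3)
      act <- apply_along(act, gaussian_matrix(coords[[axi]], sigma), axi)
  }

  # Block-average s^3 subvoxels into each target voxel.
  agg <- matrix(0, n[1], nf[1])
  for (i in seq_len(n[1])) agg[i, ((i - 1) * s + 1):(i * s)] <- 1 / s
  out <- apply_along(act, agg, 1)
  if (n[2] != n[1] || any(dim(out)[2] != n[2])) {
    agg2 <- matrix(0, n[2], nf[2])
    for (i in seq_len(n[2])) agg2[i, ((i - 1) * s + 1):(i * s)] <- 1 / s
  } else agg2 <- agg
  out <- apply_along(out, agg2, 2)
  if (n[3] != n[2]) {
    agg3 <- matrix(0, n[3], nf[3])
    for (i in seq_len(n[3])) agg3[i, ((i - 1) * s + 1):(i * s)] <- 1 / s
  } else agg3 <- agg2
  out <- apply_along(out, agg3, 3)

  img <- pet_image(out, v)
  attr(img, "cavity_volume_ul") <- cavity_volume
  attr(img, "semi_axes") <- c(a = a, b = b)
  img
}

#' Noiseless gated image series of a beating phantom
#'
#' Voxelizes one frame per gate at the cavity volumes of a continuous
#' curve sampled by [sample_gate_volumes()]; the idealized stand-in for a
#' gated reconstruction with infinite counts.
#'
#' @param config A [phantom_config()].
#' @param curve A [fourier_curve()].
#' @param n_gates Number of gates (default 16).
#' @param mode Gate sampling mode, `"point"` or `"window"`.
#' @param blur Apply the PSF (default TRUE).
#' @return A `gated_series` (see [gate_series()]) with element
#'   `true_volumes_ul`, the analytic per-gate truth.
#' @export
phantom_gated_series <- function(config, curve, n_gates = 16,
                                 mode = "point", blur = TRUE) {
  gv <- sample_gate_volumes(curve, n_gates, mode)
  frames <- lapply(gv$volume_ul, function(vol)
    voxelize_frame(config, vol, blur = blur)$data)
  arr <- array(unlist(frames), dim = c(config$grid_shape, n_gates))
  new_gated_series(arr, voxel_size = config$voxel_size,
                   origin = -(config$grid_shape - 1) / 2 * config$voxel_size,
                   period = curve$period, gate_times = gv$t_s,
                   accepted_beats = NA_integer_, rejected_beats = NA_integer_,
                   extra = list(true_volumes_ul = gv$volume_ul))
}
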