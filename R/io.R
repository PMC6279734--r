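#' Read and write list-mode event and trigger streams as CSV
#'
#' Events use columns `t_s,x_mm,y_mm,z_mm`; triggers a single column
#' `t_s`. Headers are required.
#'
#' @param path CSV file path.
#' @return Read functions return tibbles; write functions return `path`
#'   invisibly.
#' @export
read_events_csv <- function(path) {
  ev <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double(), x_mm = readr::col_double(),
    y_mm = readr::col_double(), z_mm = readr::col_double())))
  need <- c("t_s", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(ev)))
    abort(sprintf("event CSV must have columns %s.",
                  paste(need, collapse = ", ")))
  pr <- readr::problems(ev)
  if (nrow(pr) > 0)
    abort(sprintf("event CSV parse error at data line %d: expected %s.",
                  pr$row[1] - 1, pr$expected[1]))
  bad <- which(!stats::complete.cases(ev[need]) |
                 !apply(is.finite(as.matrix(ev[need])), 1, all))
  if (length(bad) > 0)
    abort(sprintf("event CSV parse error: non-finite record at data line %d.",
                  bad[1]))
  ev
}

#' @param events Tibble with `t_s`, `x_mm`, `y_mm`, `z_mm`.
#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(events[, c("t_s", "x_mm", "y_mm", "z_mm")], path)
  invisible(path)
}

#' @rdname read_events_csv
#' @export
read_triggers_csv <- function(path) {
  tr <- readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double()))
  if (!"t_s" %in% names(tr)) abort("trigger CSV must have column t_s.")
  if (any(!is.finite(tr$t_s)))
    abort("trigger CSV parse error: non-finite trigger time.")
  tr
}

#' @param triggers Tibble with `t_s`.
#' @rdname read_events_csv
#' @export
write_triggers_csv <- function(triggers, path) {
  readr::write_csv(triggers["t_s"], path)
  invisible(path)
}

#' Read and write a gated image series as 4D NIfTI
#'
#' The series is stored as NIfTI-1 with dimension order x, y, z, gate and
#' the voxel size in the header; gating metadata (`period_s`, `n_gates`,
#' `gate_mode`, beat counts) lives in a sidecar JSON with the same
#' basename.
#'
#' @param series A `gated_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_gated_nifti()` returns `path` invisibly;
#'   `read_gated_nifti()` returns a `gated_series`.
#' @export
write_gated_nifti <- function(series, path) {
  stopifnot(inherits(series, "gated_series"))
  img <- RNifti::asNifti(series$data,
                         pixdim = c(rep(series$voxel_size, 3), 1))
  RNifti::writeNifti(img, path)
  meta <- list(period_s = series$period, n_gates = series$n_gates,
               gate_mode = "point", voxel_size_mm = series$voxel_size,
               origin_mm = series$origin,
               accepted_beats = series$accepted_beats,
               rejected_beats = series$rejected_beats)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gated_nifti
#' @export
read_gated_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4) abort("expected a 4D gated NIfTI volume.")
  n_gates <- meta$n_gates %||% dim(arr)[4]
  period <- meta$period_s
  new_gated_series(
    arr, voxel_size = meta$voxel_size_mm %||% RNifti::pixdim(img)[1],
    origin = meta$origin_mm %||% (-(dim(arr)[1:3] - 1) / 2 *
                                    (meta$voxel_size_mm %||% 1)),
    period = period,
    gate_times = (seq_len(n_gates) - 0.5) / n_gates * period,
    accepted_beats = meta$accepted_beats %||% NA_integer_,
    rejected_beats = meta$rejected_beats %||% NA_integer_)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
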