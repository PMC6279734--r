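#' Specify a simulated cohort of subjects
#'
#' Per-parameter Gaussian distributions (mean and SD) for the functional
#' parameters of a group of subjects, emulating the between-animal spread
#' of a study group. [sample_cohort()] draws per-subject [curve_spec()]s
#' from it.
#'
#' @param edv,esv,hr,pfr,tpfr,third_mfr Length-2 numeric vectors
#'   `c(mean, sd)`; `third_mfr` may be `NULL`. Units as in [curve_spec()].
#' @param n_subjects Number of subjects (at least 2).
#' @param seed Integer seed.
#' @param label Optional cohort label.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(edv, esv, hr, pfr, tpfr, third_mfr = NULL,
                        n_subjects = 6, seed = 1, label = NULL) {
  pars <- list(edv = edv, esv = esv, hr = hr, pfr = pfr, tpfr = tpfr)
  if (!is.null(third_mfr)) pars$third_mfr <- third_mfr
  for (nm in names(pars)) {
    p <- pars[[nm]]
    if (length(p) != 2 || p[2] < 0)
      abort(sprintf("`%s` must be c(mean, sd) with sd >= 0.", nm))
  }
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  structure(c(pars, list(n_subjects = as.integer(n_subjects),
                         seed = as.integer(seed), label = label)),
            class = "cohort_spec")
}

#' Reference cohorts: lean control and diabetic phenotype
#'
#' Convenience [cohort_spec()]s with the package's reference study
#' conditions: gated FDG-PET functional values typical of lean control
#' (ZL) and diabetic fatty (ZDF) Zucker rats — preserved ejection fraction
#' in both groups but reduced peak filling rate and one-third mean filling
#' rate and prolonged time to peak filling in the diabetic phenotype.
#'
#' @param n_subjects Subjects per group (default 6).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec_zl <- function(n_subjects = 6, seed = 1) {
  cohort_spec(edv = c(410.8, 60.3), esv = c(155.1, 31.4), hr = c(331, 35),
              pfr = c(12.1, 0.8), tpfr = c(35.4, 2.7),
              third_mfr = c(12.0, 0.7),
              n_subjects = n_subjects, seed = seed, label = "ZL")
}

#' @rdname cohort_spec_zl
#' @export
cohort_spec_zdf <- function(n_subjects = 6, seed = 2) {
  cohort_spec(edv = c(478.8, 77.9), esv = c(194.1, 36.6), hr = c(309, 24),
              pfr = c(10.2, 1.0), tpfr = c(40.0, 4.2),
              third_mfr = c(9.9, 1.2),
              n_subjects = n_subjects, seed = seed, label = "ZDF")
}

#' @rdname cohort_spec
#' @param path YAML file whose fields are those of `cohort_spec` with
#'   per-parameter `mean`/`sd` sub-fields.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  ms <- function(p) if (!is.null(p)) c(p$mean, p$sd)
  cohort_spec(edv = ms(y$edv), esv = ms(y$esv), hr = ms(y$hr),
              pfr = ms(y$pfr), tpfr = ms(y$tpfr),
              third_mfr = ms(y$third_mfr),
              n_subjects = y$n_subjects, seed = y$seed %||% 1L,
              label = y$label)
}

#' Draw per-subject curve specifications from a cohort
#'
#' Each functional parameter is drawn independently Gaussian from the
#' cohort distribution; a subject is redrawn until its [curve_spec()] is
#' feasible — it passes the structural rules (EDV > ESV > 0, TPFR inside
#' the cycle, PFR at or above the drawn 1/3MFR) and [synthesize_curve()]
#' verifies a band-limited curve attaining it (feasibility is
#' solver-defined). More than 100 consecutive infeasible draws raise an
#' error. The drawn 1/3MFR is recorded on each spec but is not imposed as
#' a synthesis equality (see the package vignette): a subject's true
#' 1/3MFR is the one its band-limited curve achieves.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `n_subjects` [curve_spec()]s, each with attributes
#'   `subject`, `drawn_third_mfr` and `curve` (the verified ground-truth
#'   [fourier_curve()]).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    out <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      tries <- 0
      repeat {
        tries <- tries + 1
        if (tries > 100)
          abort("more than 100 consecutive infeasible cohort draws.")
        nms <- c("edv", "esv", "hr", "pfr", "tpfr")
        if (!is.null(spec$third_mfr)) nms <- c(nms, "third_mfr")
        draw <- lapply(setNames(nms, nms), function(nm)
          rnorm(1, spec[[nm]][1], spec[[nm]][2]))
        cs <- tryCatch(
          curve_spec(edv = draw$edv, esv = draw$esv, heart_rate = draw$hr,
                     pfr = draw$pfr, tpfr = draw$tpfr),
          error = function(e) NULL)
        if (is.null(cs)) next
        if (!is.null(draw$third_mfr) && cs$pfr < draw$third_mfr) next
        curve <- tryCatch(synthesize_curve(cs),
                          gatedlv_infeasible = function(e) NULL)
        if (is.null(curve)) next
        break
      }
      attr(cs, "subject") <- s
      attr(cs, "drawn_third_mfr") <- draw$third_mfr
      attr(cs, "curve") <- curve
      out[[s]] <- cs
    }
    out
  })
}
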