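#' Two-tailed Student t-tests for cohort comparisons
#'
#' Classic pooled-variance (equal-variance) Student t-tests, two-tailed
#' throughout — the convention recommended for small groups and used for
#' all comparisons in this package. `ttest_independent()` compares two
#' independent samples (df = n_a + n_b - 2); `ttest_paired()` compares two
#' dependent samples via a one-sample t on the differences (df = n - 1);
#' `ttest_independent_summary()` evaluates the identical pooled formula
#' from group summary statistics only, for comparisons against published
#' mean +/- SD tables where raw values are unavailable.
#'
#' Degenerate inputs follow the convention: zero pooled variance with
#' equal means gives t = 0, p = 1; zero variance with unequal means is an
#' error (an infinite t statistic).
#'
#' @param a,b Numeric vectors (for the paired test, equal length).
#' @param welch Use the Welch (unequal-variance) variant instead
#'   (default FALSE).
#' @return A one-row tibble: `t`, `df`, `p` (two-tailed), `kind`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' ttest_independent_summary(12.1, 0.8, 6, 10.2, 1.0, 6) # p ~ 0.0046
#' @export
ttest_independent <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group.")
  if (sd(a) == 0 && sd(b) == 0) {
    return(degenerate_ttest(mean(a), mean(b), length(a) + length(b) - 2,
                            "independent"))
  }
  ht <- stats::t.test(a, b, var.equal = !welch, paired = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, kind = "independent",
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b))
}

#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics
#'   (sample SD, n - 1 denominator).
#' @rdname ttest_independent
#' @export
ttest_independent_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                      welch = FALSE) {
  if (n_a < 2 || n_b < 2) abort("need at least 2 subjects per group.")
  if (sd_a < 0 || sd_b < 0) abort("SDs must be non-negative.")
  if (sd_a == 0 && sd_b == 0)
    return(degenerate_ttest(mean_a, mean_b, n_a + n_b - 2, "independent"))
  if (welch) {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    t <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df), kind = "independent",
         mean_a = mean_a, mean_b = mean_b, n_a = n_a, n_b = n_b)
}

#' @rdname ttest_independent
#' @export
ttest_paired <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples must have equal length.")
  if (length(a) < 2) abort("need at least 2 pairs.")
  d <- a - b
  if (sd(d) == 0)
    return(degenerate_ttest(mean(a), mean(b), length(a) - 1, "paired"))
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, kind = "paired",
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b))
}

degenerate_ttest <- function(mean_a, mean_b, df, kind) {
  if (mean_a != mean_b)
    abort("zero variance with unequal means: t statistic is infinite.")
  tibble(t = 0, df = df, p = 1, kind = kind,
         mean_a = mean_a, mean_b = mean_b, n_a = NA_integer_,
         n_b = NA_integer_)
}

#' Parameter-by-parameter comparison of two cohorts
#'
#' For each functional parameter (EF, PFR, 1/3MFR, TPFR, HR, EDV, ESV —
#' whichever columns both result sets share), reports mean +/- SD per
#' group, the independent pooled-variance Student t-test and a
#' significance flag. No multiple-testing correction is applied; each
#' parameter is tested at `alpha` on its own, which mirrors common
#' reporting practice in small-animal functional studies and is noted in
#' the serialized report footer.
#'
#' @param results_a,results_b Data frames of per-subject results (one row
#'   per subject; see [analyze_volume_curve()]).
#' @param alpha Significance level (default 0.05).
#' @param parameters Columns to compare (default: the functional set).
#' @return A tibble of class `lv_comparison` with one row per parameter:
#'   group means/SDs, `t`, `df`, `p`, `significant`.
#' @export
compare_cohorts <- function(results_a, results_b, alpha = 0.05,
                            parameters = c("ef", "pfr", "third_mfr",
                                           "tpfr_ms", "hr", "edv", "esv")) {
  if (nrow(results_a) < 2 || nrow(results_b) < 2)
    abort("need at least 2 subjects per cohort.")
  parameters <- intersect(parameters,
                          intersect(names(results_a), names(results_b)))
  if (length(parameters) == 0) abort("no shared parameter columns.")
  rows <- map(parameters, function(pp) {
    a <- results_a[[pp]]
    b <- results_b[[pp]]
    ht <- ttest_independent(a, b)
    tibble(parameter = pp,
           mean_a = mean(a), sd_a = sd(a), n_a = length(a),
           mean_b = mean(b), sd_b = sd(b), n_b = length(b),
           t = ht$t, df = ht$df, p = ht$p,
           significant = ht$p < alpha)
  })
  out <- list_rbind(rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("lv_comparison", class(out))
  out
}

#' Plot a two-cohort comparison
#'
#' Group means with SD error bars per functional parameter, faceted;
#' significant parameters are marked.
#'
#' @param object An `lv_comparison` from [compare_cohorts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("mean_a", "mean_b"),
    names_to = "group", values_to = "mean")
  long$sd <- ifelse(long$group == "mean_a", long$sd_a, long$sd_b)
  long$group <- ifelse(long$group == "mean_a", "A", "B")
  lab <- dplyr::distinct(as_tibble(object)[, c("parameter", "significant")])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = 1.5, y = Inf,
                                    label = ifelse(.data$significant,
                                                   "*", "")),
                       vjust = 1.5, inherit.aes = FALSE, size = 6) +
    ggplot2::labs(x = NULL, y = "Mean +/- SD",
                  title = "Cohort comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
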