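#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for scenario results
#'
#' Every scenario object returned by the experiment harness supports
#' [generics::tidy()] (the per-replicate results table) and
#' [generics::glance()] (a one-row summary of the scenario's headline
#' quantities).
#'
#' @param x A scenario result (`clonedyn_intervals`, `clonedyn_adjuvant`,
#'   `clonedyn_ith_cor`, `clonedyn_metric_summary` or
#'   `clonedyn_tumorigenesis`).
#' @param ... Unused, for generic consistency.
#' @return `tidy()` returns a tibble of per-replicate (or per-time) rows;
#'   `glance()` returns a one-row tibble.
#' @name clonedyn_tidiers
NULL

#' @rdname clonedyn_tidiers
#' @exportS3Method
tidy.clonedyn_intervals <- function(x, ...) x$results

#' @rdname clonedyn_tidiers
#' @exportS3Method
glance.clonedyn_intervals <- function(x, ...) {
  med <- dplyr::summarise(dplyr::group_by(x$results, interval),
                          median_log10_fc = stats::median(log10_fold_change),
                          .groups = "drop")
  med <- dplyr::arrange(med, interval)
  out <- tidyr::pivot_wider(med, names_from = "interval",
                            values_from = "median_log10_fc",
                            names_prefix = "median_log10_fc_")
  out$monotone_worsening <- !is.unsorted(med$median_log10_fc)
  out$reps <- x$reps
  out
}

#' @rdname clonedyn_tidiers
#' @exportS3Method
tidy.clonedyn_adjuvant <- function(x, ...) x$results

#' @rdname clonedyn_tidiers
#' @exportS3Method
glance.clonedyn_adjuvant <- function(x, ...) {
  med <- tapply(x$results$log10_fold_change, x$results$arm, stats::median)
  p <- x$test$p.value
  tibble::tibble(
    median_log10_fc_adjuvant = unname(med[["adjuvant"]]),
    median_log10_fc_neoadjuvant = unname(med[["neoadjuvant"]]),
    wilcox_p = p,
    stars = significance_stars(p),
    reps = x$reps
  )
}

#' @rdname clonedyn_tidiers
#' @exportS3Method
tidy.clonedyn_ith_cor <- function(x, ...) x$results

#' @rdname clonedyn_tidiers
#' @exportS3Method
glance.clonedyn_ith_cor <- function(x, ...) {
  tibble::tibble(
    rho_dominant = unname(x$cor_dominant$estimate),
    p_dominant = x$cor_dominant$p.value,
    rho_off_target = unname(x$cor_off_target$estimate),
    p_off_target = x$cor_off_target$p.value,
    n_founders = x$n_founders,
    reps = x$reps
  )
}

#' @rdname clonedyn_tidiers
#' @exportS3Method
tidy.clonedyn_metric_summary <- function(x, ...) x$summary

#' @rdname clonedyn_tidiers
#' @exportS3Method
glance.clonedyn_metric_summary <- function(x, ...) {
  off <- x$summary[x$summary$metric == "off_target_probability", ]
  t_max <- max(off$time)
  mid <- off$median[off$time >= t_max * 0.25 & off$time <= t_max * 0.75]
  tibble::tibble(
    peak_off_target_median = max(off$median, na.rm = TRUE),
    mid_off_target_median = stats::median(mid, na.rm = TRUE),
    early_off_target_median = off$median[off$time == min(10, t_max)],
    late_off_target_median = off$median[off$time == t_max],
    reps = x$reps
  )
}

#' @rdname clonedyn_tidiers
#' @exportS3Method
tidy.clonedyn_tumorigenesis <- function(x, ...) x$results

#' @rdname clonedyn_tidiers
#' @exportS3Method
glance.clonedyn_tumorigenesis <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, DR, MR),
    median_years = stats::median(years, na.rm = TRUE),
    min_years = suppressWarnings(min(years, na.rm = TRUE)),
    max_years = suppressWarnings(max(years, na.rm = TRUE)),
    censored_fraction = mean(!detected),
    reps = dplyr::n(),
    .groups = "drop"
  )
}

#' @export
print.clonedyn_intervals <- function(x, ...) {
  cat("Therapy-interval study (", x$reps, " replicates per interval)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.clonedyn_adjuvant <- function(x, ...) {
  cat("Adjuvant vs neoadjuvant general therapy around surgery (",
      x$reps, " replicates per arm)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.clonedyn_ith_cor <- function(x, ...) {
  cat("Heterogeneity metrics vs targeted-therapy outcome (",
      x$n_founders, " founders, ", x$reps, " replicates)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.clonedyn_metric_summary <- function(x, ...) {
  cat("Heterogeneity-metric trajectories (", x$reps, " replicates, ",
      x$iterations, " iterations)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.clonedyn_tumorigenesis <- function(x, ...) {
  cat("Tumorigenesis detection-time study (", x$reps,
      " replicates per point)\n", sep = "")
  print(glance(x))
  invisible(x)
}
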