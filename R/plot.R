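#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stream (Muller-style) plot of subclone sizes
#'
#' Draws the trajectory as centered stacked ribbons — one per subclone,
#' stacked in order of origin so descendant clones appear to grow out of
#' the tumor body, with the total height equal to the tumor size `N(t)`.
#'
#' @param object A `tumor_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' traj <- simulate_tumor(founders(), iterations = 100, seed = 7)
#' autoplot(traj)
#' @exportS3Method
autoplot.tumor_trajectory <- function(object, ...) {
  wide <- export_stream_table(object)
  long <- tidyr::pivot_longer(wide, cols = -"time",
                              names_to = "subclone", values_to = "size")
  long$subclone <- factor(long$subclone,
                          levels = setdiff(names(wide), "time"))
  # center the stack so the plot reads as a stream: offset each time by -N/2
  totals <- dplyr::summarise(dplyr::group_by(long, time), N = sum(size),
                             .groups = "drop")
  long <- dplyr::left_join(long, totals, by = "time")
  long <- dplyr::arrange(long, time, subclone)
  long <- dplyr::mutate(dplyr::group_by(long, time),
                        ymax = cumsum(size) - N / 2,
                        ymin = ymax - size)
  long <- dplyr::ungroup(long)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, ymin = .data$ymin,
                                     ymax = .data$ymax,
                                     fill = .data$subclone)) +
    ggplot2::geom_ribbon(alpha = 0.9, linewidth = 0) +
    ggplot2::labs(x = "iteration", y = "subclone size (centered)",
                  fill = "subclone") +
    ggplot2::theme_minimal()
}

#' Plot the heterogeneity metrics of one trajectory
#'
#' @param object An `ith_metric_series` from [ith_metrics()].
#' @param ... Unused.
#' @return A ggplot object with one line per metric.
#' @exportS3Method
autoplot.ith_metric_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("dominant_clone_proportion", "off_target_probability"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "iteration", y = "metric value", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate-summarized metric trajectories
#'
#' Median line and interquartile ribbon of both heterogeneity metrics over
#' time, across the replicates of [metric_trajectory_summary()].
#'
#' @param object A `clonedyn_metric_summary`.
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @exportS3Method
autoplot.clonedyn_metric_summary <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), color = "steelblue4") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "iteration", y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot tumor size over time
#'
#' @param traj A `tumor_trajectory`.
#' @param log10 Show the size axis on a log10 scale.
#' @return A ggplot object of total size `N(t)`.
#' @export
plot_tumor_size <- function(traj, log10 = TRUE) {
  sizes <- tumor_size(traj)
  p <- ggplot2::ggplot(sizes, ggplot2::aes(x = .data$time, y = .data$N)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "iteration", y = "total tumor size N") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}
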