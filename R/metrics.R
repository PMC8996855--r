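#' Dominant clone proportion
#'
#' The "absolute heterogeneity" metric: the size of the largest living
#' subclone divided by the total tumor size. 1 for a clonal tumor, small for
#' a highly mixed one; scale-invariant in the subclone sizes.
#'
#' @param x Either a `clonedyn_state` or a data frame holding one time
#'   point of a trajectory (columns `size`, and `subpop_id`/`drivers` for
#'   [off_target_probability()]).
#' @return A fraction in `(0, 1]`, or `NA` when the tumor is empty.
#' @examples
#' dominant_clone_proportion(data.frame(size = c(60, 30, 10)))  # 0.6
#' @export
dominant_clone_proportion <- function(x) {
  size <- if (is.data.frame(x)) x$size else x$size
  size <- size[size > 0]
  if (length(size) == 0) return(NA_real_)
  max(size) / sum(size)
}

#' Off-target probability
#'
#' The "potential heterogeneity" metric: the fraction of extant driver
#' mutations that are *not* carried by the predominant subclone, among all
#' driver mutations carried by living subclones. It proxies the chance that
#' a therapy targeted at the dominant clone misses a subclonal driver.
#' Ties for the dominant clone are broken by lowest subclone id; drivers
#' private to extinct subclones are excluded.
#'
#' @param x A `clonedyn_state`, or a one-time-point data frame with columns
#'   `size`, `subpop_id` and a `drivers` list-column.
#' @return A fraction in `[0, 1]`; `NA` when no living subclone (or no
#'   driver event) exists.
#' @examples
#' slice <- tibble::tibble(
#'   subpop_id = 1:3, size = c(100, 10, 10),
#'   drivers = list(1L, c(1L, 2L), c(1L, 3L))
#' )
#' off_target_probability(slice)  # 2/3
#' @export
off_target_probability <- function(x) {
  if (is.data.frame(x)) {
    alive <- x$size > 0
    size <- x$size[alive]
    id <- x$subpop_id[alive]
    drivers <- x$drivers[alive]
  } else {
    alive <- x$size > 0
    size <- x$size[alive]
    id <- x$id[alive]
    drivers <- x$drivers[alive]
  }
  if (length(size) == 0) return(NA_real_)
  ord <- order(-size, id)           # largest first, ties by lowest id
  dominant <- drivers[[ord[1]]]
  all_drivers <- unique(unlist(drivers))
  if (length(all_drivers) == 0) return(NA_real_)
  length(setdiff(all_drivers, dominant)) / length(all_drivers)
}

#' Per-time intra-tumor heterogeneity metrics
#'
#' Computes both heterogeneity metrics — dominant clone proportion and
#' off-target probability — at every recorded time point of a trajectory,
#' along with the total size, the number of living subclones and the number
#' of distinct extant driver events.
#'
#' @param traj A `tumor_trajectory`.
#' @return A tibble of class `ith_metric_series` with columns `time`,
#'   `dominant_clone_proportion`, `off_target_probability`, `N`,
#'   `living_subclones`, `total_driver_events`; metrics are `NA` where
#'   undefined (empty tumor).
#' @examples
#' traj <- simulate_tumor(founders(), iterations = 30, seed = 1)
#' ith_metrics(traj)
#' @export
ith_metrics <- function(traj) {
  df <- tibble::as_tibble(traj)
  rows <- lapply(split(df, df$time), function(slice) {
    alive <- slice$size > 0
    live <- slice[alive, , drop = FALSE]
    tibble::tibble(
      time = slice$time[1],
      dominant_clone_proportion = dominant_clone_proportion(slice),
      off_target_probability = off_target_probability(slice),
      N = sum(slice$size),
      living_subclones = nrow(live),
      total_driver_events = length(unique(unlist(live$drivers)))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), time)
  # fill times after total extinction (no records) with an empty-tumor row
  horizon <- attr(traj, "iterations") %||% max(out$time)
  missing <- setdiff(0:horizon, out$time)
  if (length(missing) > 0) {
    out <- dplyr::arrange(dplyr::bind_rows(out, tibble::tibble(
      time = as.integer(missing),
      dominant_clone_proportion = NA_real_,
      off_target_probability = NA_real_,
      N = 0, living_subclones = 0L, total_driver_events = 0L
    )), time)
  }
  class(out) <- c("ith_metric_series", class(out))
  out
}

#' Fold change of tumor size between two time points
#'
#' Treatment-outcome measure: the ratio of total tumor size at `t1` to that
#' at `t0`, and its base-10 logarithm (the scale on which therapy outcomes
#' are compared; values below 0 mean the tumor shrank).
#'
#' @param traj A `tumor_trajectory`.
#' @param t0,t1 Time points with `t0 < t1`, both recorded in the
#'   trajectory. The canonical therapy-outcome window compares size at time
#'   170 against size at time 100 (therapy starting at 100).
#' @return A one-row tibble: `t0`, `t1`, `N0`, `N1`, `fold_change`,
#'   `log10_fold_change`.
#' @examples
#' traj <- simulate_tumor(founders(), iterations = 120, seed = 1)
#' fold_change(traj, 100, 120)
#' @export
fold_change <- function(traj, t0 = 100, t1 = 170) {
  stopifnot(t0 < t1)
  sizes <- tumor_size(traj)
  n0 <- sizes$N[match(t0, sizes$time)]
  n1 <- sizes$N[match(t1, sizes$time)]
  if (is.na(n0) || is.na(n1)) {
    rlang::abort("both t0 and t1 must be recorded in the trajectory")
  }
  if (n0 == 0) rlang::abort("tumor size at t0 is zero; fold change undefined")
  tibble::tibble(t0 = t0, t1 = t1, N0 = n0, N1 = n1,
                 fold_change = n1 / n0,
                 log10_fold_change = log10(n1 / n0))
}

#' Time for the tumor to reach a detectable size
#'
#' Finds the first recorded time at which the total size `N` reaches the
#' detection threshold, and converts it to years via the real-time length
#' of one iteration (`years = t * iteration_days / 365`). Runs that never
#' reach the threshold are censored.
#'
#' @param traj A `tumor_trajectory` (typically run with
#'   `stop_at_size = threshold`).
#' @param threshold Detectable tumor size (default 10000).
#' @param iteration_days Real-time length of one iteration in days
#'   (default 10).
#' @return A one-row tibble: `detected` (logical), `iteration` (first
#'   crossing time, `NA` if censored), `years` (`NA` if censored).
#' @examples
#' traj <- simulate_tumor(founders(), iterations = 100, seed = 1,
#'                        stop_at_size = 10000)
#' detection_time(traj)
#' @export
detection_time <- function(traj, threshold = 10000, iteration_days = 10) {
  stopifnot(threshold > 0)
  sizes <- tumor_size(traj)
  hit <- which(sizes$N >= threshold)
  if (length(hit) == 0) {
    return(tibble::tibble(detected = FALSE, iteration = NA_integer_,
                          years = NA_real_))
  }
  t_hit <- sizes$time[hit[1]]
  tibble::tibble(detected = TRUE, iteration = as.integer(t_hit),
                 years = t_hit * iteration_days / 365)
}
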