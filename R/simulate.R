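#' Simulate a tumor's subclonal evolution
#'
#' Runs the full stochastic clonal-expansion model from 1-3 founder
#' subclones: per-iteration Poisson births under the competition constraint,
#' deterministic apoptosis, passenger-mutation drift of DR/AR, mutation-rate
#' drift, rare driver events spawning new subclones, optional therapy
#' courses, and extinction of depleted subclones. The run is fully
#' reproducible from its seed.
#'
#' @param founders A founder tibble (see [founders()]).
#' @param iterations Number of iterations to simulate (each of real-time
#'   length `iteration_days`).
#' @param params Global parameters from [global_params()].
#' @param schedule Optional therapy schedule (rows from [therapy_course()]).
#' @param seed Integer seed; if `NULL` the current RNG stream is used
#'   (useful when the caller manages seeding).
#' @param stop_at_size Optional early-stopping threshold: the run ends at
#'   the first iteration where total size `N` reaches this value (used by
#'   tumorigenesis/detection studies).
#' @param strict_schedule Enforce the 10-iteration spacing between therapy
#'   courses; the experiment harness disables this for short-interval
#'   studies.
#' @return A `tumor_trajectory`: a long-format tibble with one row per
#'   subclone per iteration — columns `time`, `subpop_id`, `parent_id`,
#'   `origin_time`, `size`, `DR`, `AR`, `MR`, `TMB`, `drivers` (list-column
#'   of integer driver-event ids) and `alive` (a subclone's final, extinct
#'   record has `size` 0 and `alive = FALSE`). Attributes carry the
#'   parameters, founders, schedule, seed and the driver-event registry
#'   (`events(x)`).
#' @examples
#' traj <- simulate_tumor(founders(size = 30), iterations = 50, seed = 1)
#' dplyr::count(traj, time) # one record per living subclone per iteration
#' @seealso [ith_metrics()], [fold_change()], [autoplot.tumor_trajectory()]
#' @export
simulate_tumor <- function(founders = clonedyn::founders(),
                           iterations = 200,
                           params = global_params(),
                           schedule = NULL,
                           seed = NULL,
                           stop_at_size = NULL,
                           strict_schedule = TRUE) {
  stopifnot(iterations >= 1)
  bad <- validate_schedule(schedule, iterations, strict = strict_schedule)
  if (length(bad) > 0) {
    rlang::abort(c("Invalid therapy schedule:", stats::setNames(bad, rep("x", length(bad)))))
  }
  if (!is.null(seed)) set.seed(seed)
  state <- make_initial_state(founders, params)
  runtime <- make_therapy_runtime(schedule)
  chunks <- vector("list", iterations + 1L)
  chunks[[1L]] <- list(
    time = rep(0L, length(state$size)),
    subpop_id = state$id, parent_id = state$parent,
    origin_time = state$origin, size = state$size,
    DR = state$DR, AR = state$AR, MR = state$MR, TMB = state$TMB,
    drivers = state$drivers, alive = rep(TRUE, length(state$size))
  )
  completed <- 0L
  for (t in seq_len(iterations)) {
    step <- step_state(state, params, runtime)
    state <- step$state
    chunks[[t + 1L]] <- step$record
    completed <- t
    if (!is.null(stop_at_size) && sum(state$size) >= stop_at_size) break
  }
  # restore DR of any targeted course that finished exactly at the horizon
  if (!is.null(runtime)) {
    for (course in runtime$courses) {
      if (course$kind == "targeted" && course$started && !course$restored &&
          state$time >= course$end) {
        state <- restore_targeted(state, course)
      }
    }
  }
  chunks <- chunks[seq_len(completed + 1L)]
  traj <- tibble::tibble(
    time = unlist(lapply(chunks, `[[`, "time")),
    subpop_id = unlist(lapply(chunks, `[[`, "subpop_id")),
    parent_id = unlist(lapply(chunks, `[[`, "parent_id")),
    origin_time = unlist(lapply(chunks, `[[`, "origin_time")),
    size = unlist(lapply(chunks, `[[`, "size")),
    DR = unlist(lapply(chunks, `[[`, "DR")),
    AR = unlist(lapply(chunks, `[[`, "AR")),
    MR = unlist(lapply(chunks, `[[`, "MR")),
    TMB = unlist(lapply(chunks, `[[`, "TMB")),
    drivers = unlist(lapply(chunks, `[[`, "drivers"), recursive = FALSE),
    alive = unlist(lapply(chunks, `[[`, "alive"))
  )
  n_events <- state$next_event - 1L
  events <- tibble::tibble(
    event_id = seq_len(n_events),
    category = hallmark_categories()[state$event_cat[seq_len(n_events)]],
    origin_time = state$event_origin[seq_len(n_events)]
  )
  structure(
    traj,
    class = c("tumor_trajectory", class(traj)),
    params = params,
    founders = tibble::as_tibble(founders),
    schedule = schedule,
    seed = seed,
    events = events,
    iterations = completed,
    stopped_early = completed < iterations
  )
}

#' Driver-event registry of a trajectory
#'
#' @param traj A `tumor_trajectory`.
#' @return Tibble with columns `event_id`, `category`, `origin_time` — one
#'   row per driver event that arose during the run (founding events have
#'   `origin_time` 0).
#' @export
events <- function(traj) {
  attr(traj, "events")
}

#' Total tumor size over time
#'
#' @param traj A `tumor_trajectory`.
#' @return Tibble with columns `time` and `N` (sum of living subclone
#'   sizes), one row per recorded time point.
#' @export
tumor_size <- function(traj) {
  out <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(traj), time),
                          N = sum(size), .groups = "drop")
  # times after total extinction have no subclone records; N there is 0
  horizon <- attr(traj, "iterations") %||% max(out$time)
  all_times <- tibble::tibble(time = 0:horizon)
  out <- dplyr::left_join(all_times, out, by = "time")
  out$N[is.na(out$N)] <- 0
  out
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  n_sub <- length(unique(x$subpop_id))
  it <- attr(x, "iterations")
  final_N <- sum(x$size[x$time == max(x$time)])
  cat(sprintf(
    "<tumor_trajectory> %d iteration(s), %d subclone(s) ever, final N = %s\n",
    it, n_sub, format(final_N, big.mark = ",")))
  NextMethod()
}
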