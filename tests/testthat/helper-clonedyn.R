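# Shared fixtures, all built in code.

# A bare tumor state with explicit per-subclone attributes, for metric and
# therapy unit tests. `drivers` is a list of integer event-id vectors;
# event categories default to cycling through the three hallmark groups.
toy_state <- function(size, drivers = as.list(seq_along(size)),
                      DR = 0.2, AR = 0.05, MR = 100, TMB = 1,
                      event_cat = NULL, time = 0L) {
  n <- length(size)
  n_events <- max(unlist(drivers), 0)
  if (is.null(event_cat)) {
    event_cat <- rep_len(1:3, max(n_events, 1))
  }
  structure(list(
    time = as.integer(time),
    id = seq_len(n),
    parent = rep(NA_integer_, n),
    origin = rep(0L, n),
    size = as.numeric(size),
    DR = rep_len(DR, n), AR = rep_len(AR, n), MR = rep_len(MR, n),
    TMB = rep_len(as.numeric(TMB), n),
    drivers = drivers,
    event_cat = as.integer(event_cat),
    event_origin = rep(0L, max(n_events, 1)),
    next_event = n_events + 1L,
    next_id = n + 1L
  ), class = "clonedyn_state")
}

# A state slice shaped like one time point of a trajectory tibble.
toy_slice <- function(size, drivers = as.list(seq_along(size))) {
  tibble::tibble(subpop_id = seq_along(size), size = size, drivers = drivers)
}

# Short default-parameter run used by several tests.
short_run <- function(iterations = 60, seed = 42, ...) {
  simulate_tumor(founders(size = 30), iterations = iterations, seed = seed, ...)
}
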