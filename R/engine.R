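#' Competition constraint factor
#'
#' The Gompertz-like growth constraint applied to the birth intensity of
#' every subclone: `exp(-N * DR * AR / c)`. It equals 1 for an empty tumor
#' and decreases monotonically in the total size `N`, so that constrained
#' births eventually balance deaths at a carrying capacity proportional to
#' `c` (for a homogeneous tumor the expectation fixed point is
#' `N* = c * log(DR / AR) / (DR * AR)`).
#'
#' @param N Current total tumor size (all living subclones).
#' @param DR,AR Division and apoptosis rate of the subclone being updated.
#' @param c Competition constant (see [global_params()]).
#' @return A factor in `(0, 1]`; vectorized over its arguments.
#' @examples
#' constraint_factor(0, 0.2, 0.05)      # 1
#' constraint_factor(1e6, 0.2, 0.05)    # exp(-1)
#' @export
constraint_factor <- function(N, DR, AR, c = 10000) {
  stopifnot(all(N >= 0))
  exp(-N * DR * AR / c)
}

#' One stochastic growth/death update of subclone sizes
#'
#' Births are drawn as a single Poisson variate with mean
#' `size * DR * constraint_factor(N, DR, AR, c)` (equivalent, by Poisson
#' superposition, to summing one `Poisson(DR * factor)` draw per cell);
#' deaths are the deterministic `floor(size * AR)`. The new size is clamped
#' at 0.
#'
#' @param size Integer cell counts (vectorized over subclones).
#' @param DR,AR Per-subclone rates.
#' @param N Total tumor size at the start of the iteration, shared by all
#'   subclones updated in that iteration.
#' @param params Global parameters; only `c` is used.
#' @return Updated sizes, same length as `size`.
#' @export
growth_step <- function(size, DR, AR, N, params = global_params()) {
  lam <- size * DR * constraint_factor(N, DR, AR, params$c)
  births <- stats::rpois(length(size), lam)
  deaths <- floor(size * AR)
  pmax(0, size + births - deaths)
}

#' Passenger-mutation drift of DR and AR
#'
#' Each subclone acquires `k = floor(MR * U(0, z))` passenger mutations this
#' iteration (or `k ~ Poisson(MR / 100)` under `passenger_model =
#' "poisson"`). Each passenger perturbs the division rate additively by
#' `U(x1, y1)` and the apoptosis rate relatively by `U(x2, y2) * AR`.
#' Defaults make the expected DR change slightly negative, so passengers
#' carry a mild deleterious load. DR is clamped positive and AR to
#' `[0, 1)`.
#'
#' @param DR,AR,MR Per-subclone rates (vectorized).
#' @param params Global parameters.
#' @return A list with elements `DR`, `AR` (updated rates) and `k` (the
#'   passenger counts, to be accumulated into TMB).
#' @export
passenger_step <- function(DR, AR, MR, params = global_params()) {
  n <- length(DR)
  k <- if (params$passenger_model == "poisson") {
    stats::rpois(n, MR / 100)
  } else {
    floor(MR * stats::runif(n, 0, params$z))
  }
  dDR <- numeric(n)
  dARrel <- numeric(n)
  tot <- sum(k)
  if (tot > 0) {
    idx <- rep.int(seq_len(n), k)
    s1 <- rowsum(stats::runif(tot, params$x1, params$y1), idx)
    s2 <- rowsum(stats::runif(tot, params$x2, params$y2), idx)
    at <- as.integer(rownames(s1))
    dDR[at] <- s1[, 1]
    dARrel[at] <- s2[, 1]
  }
  list(
    DR = pmax(DR + dDR, 1e-6),
    AR = pmin(pmax(AR + AR * dARrel, 0), 1 - 1e-9),
    k = as.integer(k)
  )
}

#' Random drift of the mutation rate
#'
#' With probability `mr_drift_prob` the MR change is size-dependent:
#' `mr_drift_scale * (log10(size) - log10(small_size_threshold))`, so large
#' subclones tend to gain mutability while small ones (below the threshold)
#' lose it. Otherwise the change is symmetric zero-mean noise
#' `U(-mr_drift_scale, mr_drift_scale)`. MR is clamped at 0.
#'
#' @param MR,size Per-subclone mutation rates and sizes (vectorized).
#' @param params Global parameters.
#' @return Updated MR vector.
#' @export
mr_drift <- function(MR, size, params = global_params()) {
  n <- length(MR)
  use_size <- stats::runif(n) < params$mr_drift_prob
  noise <- stats::runif(n, -params$mr_drift_scale, params$mr_drift_scale)
  sized <- params$mr_drift_scale *
    (log10(pmax(size, 1)) - log10(params$small_size_threshold))
  pmax(0, MR + ifelse(use_size, sized, noise))
}

# Category-specific driver boost applied to a child subclone's attributes.
# proliferation_survival: strong DR gain; invasion_microenv: strong AR drop;
# genomic_mutability: strong MR gain. Returns list(DR, AR, MR).
driver_boost <- function(DR, AR, MR, category) {
  if (category == 1L) {                      # proliferation & survival
    DR <- DR + stats::runif(1, 0.10, 0.25)
    AR <- AR * 0.95
    MR <- MR + stats::runif(1, 10, 20)
  } else if (category == 2L) {               # invasion & microenvironment
    DR <- DR + stats::runif(1, 0.05, 0.15)
    AR <- AR * 0.60
    MR <- MR + stats::runif(1, 10, 20)
  } else {                                   # genomic mutability
    DR <- DR + stats::runif(1, 0.05, 0.15)
    AR <- AR * 0.95
    MR <- MR + stats::runif(1, 50, 100)
  }
  list(DR = DR, AR = pmin(pmax(AR, 0), 1 - 1e-9), MR = MR)
}

#' Driver-event trials for every living subclone
#'
#' Each living subclone of size at least 1 spawns a new subpopulation with
#' probability `min(1, MR / driver_divisor)` per iteration (per
#' subpopulation, not per cell). A spawned child inherits its parent's
#' attributes and driver set, then gains one new driver event of a uniformly
#' drawn hallmark category with the category-specific fitness boost (DR
#' strictly increases, AR decreases, MR increases), starts at size 1 debited
#' from the parent, and increments its TMB by 1. Trials are suppressed while
#' the number of living subclones has reached `max_subpops`.
#'
#' @param state A `clonedyn_state` as built by [make_initial_state()].
#' @param params Global parameters.
#' @return The updated state (possibly with new subclones appended).
#' @export
driver_trial <- function(state, params = global_params()) {
  n <- length(state$size)
  if (n == 0) return(state)
  occurs <- stats::runif(n) < pmin(1, state$MR / params$driver_divisor)
  for (i in seq_len(n)) {
    if (!occurs[i] || state$size[i] < 1) next
    if (length(state$size) >= params$max_subpops) break
    category <- sample.int(3L, 1L)
    boosted <- driver_boost(state$DR[i], state$AR[i], state$MR[i], category)
    ev <- state$next_event
    state$event_cat[ev] <- category
    state$event_origin[ev] <- state$time
    state$next_event <- ev + 1L
    j <- length(state$size) + 1L
    state$id[j] <- state$next_id
    state$next_id <- state$next_id + 1L
    state$parent[j] <- state$id[i]
    state$origin[j] <- state$time
    state$size[j] <- 1
    state$size[i] <- state$size[i] - 1
    state$DR[j] <- boosted$DR
    state$AR[j] <- boosted$AR
    state$MR[j] <- boosted$MR
    state$TMB[j] <- state$TMB[i] + 1
    state$drivers[[j]] <- c(state$drivers[[i]], ev)
  }
  state
}

#' Construct the initial tumor state
#'
#' Builds the simulation state from 1-3 founder subclones. Each founder is
#' tagged with one unique founding driver event (hallmark category drawn
#' uniformly at random) so that targeted therapy and the off-target metric
#' are well-defined from time 0; the founding event contributes 1 to the
#' founder's initial TMB.
#'
#' @param founders A data frame of founder specs (see [founders()]).
#' @param params Global parameters.
#' @return A list of class `"clonedyn_state"` holding per-subclone vectors
#'   (`id`, `parent`, `origin`, `size`, `DR`, `AR`, `MR`, `TMB`), the
#'   per-subclone driver sets, the event registry (`event_cat`,
#'   `event_origin`), the clock `time` and id counters.
#' @examples
#' set.seed(1)
#' st <- make_initial_state(founders(size = 30))
#' sum(st$size)   # 30
#' @export
make_initial_state <- function(founders, params = global_params()) {
  bad <- validate_founders(founders, params)
  if (length(bad) > 0) {
    rlang::abort(c("Invalid founders:", stats::setNames(bad, rep("x", length(bad)))))
  }
  n <- nrow(founders)
  state <- list(
    time = 0L,
    id = seq_len(n),
    parent = rep(NA_integer_, n),
    origin = rep(0L, n),
    size = as.numeric(founders$size),
    DR = as.numeric(founders$DR),
    AR = as.numeric(founders$AR),
    MR = as.numeric(founders$MR),
    TMB = rep(1, n),
    drivers = as.list(seq_len(n)),
    event_cat = sample.int(3L, n, replace = TRUE),
    event_origin = rep(0L, n),
    next_event = n + 1L,
    next_id = n + 1L
  )
  class(state) <- "clonedyn_state"
  state
}

#' @export
print.clonedyn_state <- function(x, ...) {
  cat(sprintf("<clonedyn_state> t = %d, %d living subclone(s), N = %s\n",
              x$time, length(x$size), format(sum(x$size), big.mark = ",")))
  invisible(x)
}

# Drop extinct subclones (size <= 0) from the state vectors.
cull_extinct <- function(state) {
  keep <- state$size > 0
  if (all(keep)) return(state)
  state$id <- state$id[keep]
  state$parent <- state$parent[keep]
  state$origin <- state$origin[keep]
  state$size <- state$size[keep]
  state$DR <- state$DR[keep]
  state$AR <- state$AR[keep]
  state$MR <- state$MR[keep]
  state$TMB <- state$TMB[keep]
  state$drivers <- state$drivers[keep]
  state
}

# Full per-iteration update with the fixed sub-step order:
# growth -> therapy -> passenger drift -> MR drift -> driver trials ->
# extinction cull -> clock advance. `runtime` is the therapy runtime built
# by simulate_tumor() (NULL when no schedule). Returns list(state, record)
# where record captures all subclones processed this iteration (extinct
# ones with size 0, alive = FALSE).
step_state <- function(state, params, runtime = NULL) {
  N0 <- sum(state$size)
  state$size <- growth_step(state$size, state$DR, state$AR, N0, params)
  if (!is.null(runtime)) {
    state <- apply_therapies(state, runtime, params)
  }
  ps <- passenger_step(state$DR, state$AR, state$MR, params)
  state$DR <- ps$DR
  state$AR <- ps$AR
  state$TMB <- state$TMB + ps$k
  state$MR <- mr_drift(state$MR, state$size, params)
  # advance the clock before the trials so a child's origin_time equals the
  # time of its first trajectory record
  state$time <- state$time + 1L
  state <- driver_trial(state, params)
  record <- list(
    time = rep(state$time, length(state$size)),
    subpop_id = state$id,
    parent_id = state$parent,
    origin_time = state$origin,
    size = state$size,
    DR = state$DR, AR = state$AR, MR = state$MR, TMB = state$TMB,
    drivers = state$drivers,
    alive = state$size > 0
  )
  state <- cull_extinct(state)
  list(state = state, record = record)
}

#' Advance the tumor state by one iteration
#'
#' Applies the fixed sub-step order of one time interval: stochastic
#' births/deaths under the competition constraint (using the total size `N`
#' from the iteration start for every subclone), passenger-mutation drift of
#' DR/AR, mutation-rate drift, driver-event trials, removal of extinct
#' subclones and clock advance. Therapies are applied between growth and
#' passenger drift by [simulate_tumor()]; `iterate()` itself runs a
#' therapy-free step.
#'
#' @param state A `clonedyn_state`.
#' @param params Global parameters.
#' @return The updated state.
#' @export
iterate <- function(state, params = global_params()) {
  step_state(state, params, runtime = NULL)$state
}
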