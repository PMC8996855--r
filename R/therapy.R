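#' Define a therapy course
#'
#' Builds one row of a therapy schedule. Four cytotoxic operators are
#' available:
#' \describe{
#'   \item{targeted}{Selects one driver event carried by the most prevalent
#'     subclone at course start and, each iteration, kills 25-60% of every
#'     subclone carrying that event while temporarily lowering its DR.}
#'   \item{general}{Non-specific: every subclone loses 5-15% of its cells
#'     plus a random loss below 100 per iteration, and its MR increases
#'     slightly as a mutagenic side-effect.}
#'   \item{surgery}{Instantaneous removal of the tumor mass; only subclones
#'     of size > 100 with the genomic-mutability hallmark may leave
#'     metastatic survivors (at most 40%).}
#'   \item{immunotherapy}{Kills a TMB-dependent fraction
#'     `min(0.45, 1 - exp(-0.02 * TMB))` of each subclone per iteration.}
#' }
#'
#' @param kind One of `"targeted"`, `"general"`, `"surgery"`,
#'   `"immunotherapy"`.
#' @param start Iteration at which the course begins (the tumor size
#'   recorded at `start` is still pre-therapy).
#' @param duration Length in iterations; at most 10 for general therapy and
#'   15 for targeted therapy and immunotherapy. Ignored for surgery, which
#'   acts at a single iteration.
#' @return A one-row tibble with columns `kind`, `start`, `duration`.
#'   Combine courses with [dplyr::bind_rows()].
#' @examples
#' dplyr::bind_rows(
#'   therapy_course("targeted", start = 100, duration = 10),
#'   therapy_course("general", start = 120, duration = 10)
#' )
#' @export
therapy_course <- function(kind = c("targeted", "general", "surgery",
                                    "immunotherapy"),
                           start, duration = 1L) {
  kind <- match.arg(kind)
  tibble::tibble(kind = kind, start = as.integer(start),
                 duration = as.integer(duration))
}

# End of a course for spacing/overlap purposes (surgery is instantaneous).
course_end <- function(kind, start, duration) {
  ifelse(kind == "surgery", start + 1L, start + duration)
}

#' Validate a therapy schedule
#'
#' Checks duration caps (10 iterations for general therapy, 15 for targeted
#' therapy and immunotherapy), that courses start within the simulated time
#' span, that courses never overlap, and — in strict mode — that consecutive
#' courses are separated by at least 10 iterations between the earlier
#' course's end and the later one's start. The experiment harness relaxes
#' the spacing rule (`strict = FALSE`) because the therapy-interval studies
#' use gaps as short as 5 iterations.
#'
#' @param schedule A data frame with columns `kind`, `start`, `duration`
#'   (see [therapy_course()]), or `NULL` for no therapy.
#' @param iterations Length of the simulation the schedule is applied to.
#' @param strict Enforce the 10-iteration minimum spacing between courses.
#' @return Character vector of violations; `character(0)` if valid.
#' @examples
#' validate_schedule(therapy_course("general", 100, 11), 200)  # too long
#' @export
validate_schedule <- function(schedule, iterations = Inf, strict = TRUE) {
  if (is.null(schedule) || nrow(schedule) == 0) return(character(0))
  bad <- character(0)
  need <- c("kind", "start", "duration")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule))) {
    return("schedule must be a data frame with columns kind, start, duration")
  }
  kinds <- c("targeted", "general", "surgery", "immunotherapy")
  if (!all(schedule$kind %in% kinds)) {
    bad <- c(bad, sprintf("unknown therapy kind(s): %s",
                          paste(setdiff(schedule$kind, kinds), collapse = ", ")))
  }
  if (any(schedule$start < 0) || any(schedule$start != floor(schedule$start))) {
    bad <- c(bad, "start must be a non-negative integer")
  }
  if (any(schedule$start >= iterations)) {
    bad <- c(bad, "start must be earlier than the number of iterations")
  }
  dur <- schedule$duration
  notsurg <- schedule$kind != "surgery"
  if (any(notsurg & (is.na(dur) | dur < 1 | dur != floor(dur)))) {
    bad <- c(bad, "duration must be an integer >= 1")
  }
  over <- schedule$kind == "general" & !is.na(dur) & dur > 10
  if (any(over)) bad <- c(bad, "general therapy duration must be <= 10 iterations")
  over <- schedule$kind %in% c("targeted", "immunotherapy") & !is.na(dur) & dur > 15
  if (any(over)) {
    bad <- c(bad, "targeted therapy and immunotherapy duration must be <= 15 iterations")
  }
  if (nrow(schedule) > 1) {
    ord <- order(schedule$start)
    s <- schedule[ord, ]
    ends <- course_end(s$kind, s$start, ifelse(is.na(s$duration), 1L, s$duration))
    gap <- s$start[-1] - ends[-nrow(s)]
    if (strict && any(gap < 10)) {
      bad <- c(bad, "courses must be separated by at least 10 iterations")
    }
  }
  bad
}

#' Select the target driver event for a targeted course
#'
#' Draws one driver event uniformly from the driver set of the largest
#' living subclone (ties broken by lowest subclone id). The choice is made
#' once at course start and fixed for the course; every subclone carrying
#' the chosen event — descendants included — is harmed.
#'
#' @param state A `clonedyn_state` with at least one living subclone.
#' @return The integer event id of the chosen driver.
#' @export
select_target <- function(state) {
  alive <- which(state$size > 0)
  if (length(alive) == 0) rlang::abort("no living subclone to target")
  top <- alive[which.max(state$size[alive])]   # which.max -> first max, ids ascend
  d <- state$drivers[[top]]
  if (length(d) == 0) rlang::abort("dominant subclone carries no driver event")
  d[sample.int(length(d), 1L)]
}

#' Targeted-therapy kill step
#'
#' Subclones carrying the targeted driver event lose a uniform 25-60% of
#' their cells (independently drawn per subclone per iteration); subclones
#' lacking the event are untouched. The accompanying temporary DR reduction
#' is managed by the simulation loop.
#'
#' @param size Integer subclone sizes.
#' @param carrier Logical vector: does the subclone carry the target event?
#' @return Updated sizes.
#' @export
targeted_effect <- function(size, carrier) {
  n <- sum(carrier)
  if (n > 0) {
    kill <- stats::runif(n, 0.25, 0.60)
    size[carrier] <- floor(size[carrier] * (1 - kill))
  }
  size
}

#' General (non-specific) therapy step
#'
#' Every subclone loses a uniform 5-15% of its cells plus an additional
#' integer loss drawn uniformly from 0-99, clamped at zero; as a mutagenic
#' side-effect its MR increases by `U(0, general_mr_boost_max)`.
#'
#' @param size Integer subclone sizes.
#' @param MR Subclone mutation rates.
#' @param params Global parameters.
#' @return A list with updated `size` and `MR`.
#' @export
general_effect <- function(size, MR, params = global_params()) {
  n <- length(size)
  frac <- stats::runif(n, 0.05, 0.15)
  loss <- sample.int(100L, n, replace = TRUE) - 1L
  list(
    size = pmax(0, floor(size * (1 - frac)) - loss),
    MR = MR + stats::runif(n, 0, params$general_mr_boost_max)
  )
}

#' Surgery: instant removal with metastatic escape
#'
#' Removes the tumor mass at a single iteration. A subclone may leave
#' survivors only if it has activated the metastasis-permitting hallmark
#' (by default genomic mutability) and exceeds size 100; its surviving
#' (metastasized) fraction is the saturating proportion
#' `min(0.40, 1 - exp(-size * 1e-9))`, so large subclones escape with up to
#' 40% of their cells. All other subclones are removed entirely.
#'
#' @param size Integer subclone sizes.
#' @param has_hallmark Logical: does the subclone carry at least one driver
#'   of the metastasis-permitting hallmark category?
#' @return Survivor sizes.
#' @export
surgery_effect <- function(size, has_hallmark) {
  frac <- pmin(0.40, 1 - exp(-size * 1e-9))
  ifelse(has_hallmark & size > 100, round(size * frac), 0)
}

#' Immunotherapy kill step
#'
#' The kill fraction grows with the subclone's tumor mutation burden:
#' `f = min(0.45, 1 - exp(-0.02 * TMB))`, saturating at a 45% decrease per
#' iteration for highly mutated subclones.
#'
#' @param size Integer subclone sizes.
#' @param TMB Subclone tumor mutation burdens.
#' @return Updated sizes `floor(size * (1 - f))`.
#' @export
immunotherapy_effect <- function(size, TMB) {
  f <- pmin(0.45, 1 - exp(-0.02 * TMB))
  floor(size * (1 - f))
}

# Build the mutable runtime used by simulate_tumor(): one entry per course
# with activation state, the chosen target and the saved pre-course DRs.
make_therapy_runtime <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) return(NULL)
  env <- new.env(parent = emptyenv())
  env$courses <- lapply(seq_len(nrow(schedule)), function(i) {
    kind <- schedule$kind[i]
    start <- as.integer(schedule$start[i])
    duration <- if (kind == "surgery") 1L else as.integer(schedule$duration[i])
    list(kind = kind, start = start, duration = duration,
         end = start + duration,
         started = FALSE, restored = FALSE,
         target = NA_integer_, saved_id = integer(0), saved_DR = numeric(0))
  })
  env
}

# Restore pre-course DR of subclones affected by a finished targeted course.
restore_targeted <- function(state, course) {
  hit <- match(course$saved_id, state$id)
  ok <- !is.na(hit)
  state$DR[hit[ok]] <- course$saved_DR[ok]
  state
}

# Apply every scheduled therapy active at the state's current (pre-advance)
# time t. Surgery fires once at its start; targeted courses choose their
# target and lower carriers' DR on activation, and restore DR after the
# course ends.
apply_therapies <- function(state, runtime, params) {
  t <- state$time
  for (ci in seq_along(runtime$courses)) {
    course <- runtime$courses[[ci]]
    if (course$kind == "targeted" && course$started && !course$restored &&
        t >= course$end) {
      state <- restore_targeted(state, course)
      course$restored <- TRUE
      runtime$courses[[ci]] <- course
    }
    if (t < course$start || t >= course$end) next
    switch(course$kind,
      surgery = {
        cat3 <- match(params$surgery_hallmark, hallmark_categories())
        hall <- vapply(state$drivers,
                       function(d) any(state$event_cat[d] == cat3),
                       logical(1))
        state$size <- surgery_effect(state$size, hall)
      },
      targeted = {
        if (!course$started) {
          course$started <- TRUE
          course$target <- select_target(state)
          carrier <- vapply(state$drivers, function(d) course$target %in% d,
                            logical(1))
          course$saved_id <- state$id[carrier]
          course$saved_DR <- state$DR[carrier]
          state$DR[carrier] <- state$DR[carrier] * params$targeted_dr_factor
          runtime$courses[[ci]] <- course
        }
        carrier <- vapply(state$drivers, function(d) course$target %in% d,
                          logical(1))
        state$size <- targeted_effect(state$size, carrier)
      },
      general = {
        upd <- general_effect(state$size, state$MR, params)
        state$size <- upd$size
        state$MR <- upd$MR
      },
      immunotherapy = {
        state$size <- immunotherapy_effect(state$size, state$TMB)
      }
    )
  }
  state
}
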