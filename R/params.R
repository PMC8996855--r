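#' Global model constants
#'
#' Builds the list of global constants that govern every simulation: the
#' competition constraint, the passenger-mutation perturbation bounds, the
#' driver-event chance, the subclone cap, and the bookkeeping constants used
#' by the tumorigenesis studies (detectable size, real-time length of one
#' iteration).
#'
#' @param c Competition constant of the growth constraint
#'   `exp(-N * DR * AR / c)`. Larger values allow a larger quasi-stationary
#'   tumor size; the default 10000 keeps replicated simulation fast while
#'   preserving Gompertz-like saturation.
#' @param z Passenger-count scale: each iteration a subclone acquires
#'   `floor(MR * U(0, z))` passenger mutations.
#' @param x1,y1 Bounds of the uniform additive perturbation of the division
#'   rate DR per passenger mutation. Defaults `-0.001` and `0.0008` give a
#'   slight expected fitness loss per passenger.
#' @param x2,y2 Bounds of the uniform *relative* perturbation of the
#'   apoptosis rate AR per passenger mutation (each draw is scaled by the
#'   current AR).
#' @param driver_divisor Denominator of the per-iteration driver-event
#'   chance `MR / driver_divisor` (per subpopulation, not per cell).
#' @param max_subpops Maximum number of co-existing subclones; driver trials
#'   are suppressed while the cap is reached.
#' @param mr_drift_prob Probability that the per-iteration mutation-rate
#'   change is size-dependent (logarithmic in subclone size) rather than
#'   symmetric noise.
#' @param small_size_threshold Subclone size below which the size-dependent
#'   MR drift is negative.
#' @param mr_drift_scale Magnitude constant for MR drift: the size-dependent
#'   change is `mr_drift_scale * (log10(size) - log10(small_size_threshold))`
#'   and the symmetric noise is `U(-mr_drift_scale, mr_drift_scale)`.
#' @param detect_size Detectable tumor size used by tumorigenesis studies.
#' @param iteration_days Real-time length of one iteration, in days.
#' @param passenger_model Either `"uniform"` (the default; passenger count
#'   `floor(MR * U(0, z))`) or `"poisson"` (count `Poisson(MR / 100)`, an
#'   alternative reading of the model's prose description).
#' @param targeted_dr_factor Multiplier applied to DR of subclones carrying
#'   the targeted driver event for the duration of a targeted course; the
#'   original DR is restored when the course ends.
#' @param general_mr_boost_max Upper bound of the per-iteration uniform MR
#'   increase caused by general (non-specific) therapy.
#' @param surgery_hallmark Hallmark category whose presence (in subclones of
#'   size > 100) permits metastatic escape from surgery: either
#'   `"genomic_mutability"` (default) or `"invasion_microenv"`.
#' @param max_founder_size Cap on each founder subclone's initial size;
#'   override via `allow_large_founders`.
#' @param allow_large_founders If `TRUE`, founder sizes above
#'   `max_founder_size` are accepted (some therapy experiments initialize at
#'   the cap or above).
#'
#' @return A named list with class `"clonedyn_params"`.
#' @seealso [validate_params()], [simulate_tumor()]
#' @examples
#' p <- global_params()
#' p$c
#' @export
global_params <- function(c = 10000,
                          z = 0.1,
                          x1 = -0.001, y1 = 0.0008,
                          x2 = -0.002, y2 = 0.002,
                          driver_divisor = 6000,
                          max_subpops = 10,
                          mr_drift_prob = 0.1,
                          small_size_threshold = 10,
                          mr_drift_scale = 10,
                          detect_size = 10000,
                          iteration_days = 10,
                          passenger_model = c("uniform", "poisson"),
                          targeted_dr_factor = 0.5,
                          general_mr_boost_max = 10,
                          surgery_hallmark = c("genomic_mutability",
                                               "invasion_microenv"),
                          max_founder_size = 100,
                          allow_large_founders = FALSE) {
  params <- list(
    c = c, z = z,
    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
    driver_divisor = driver_divisor,
    max_subpops = max_subpops,
    mr_drift_prob = mr_drift_prob,
    small_size_threshold = small_size_threshold,
    mr_drift_scale = mr_drift_scale,
    detect_size = detect_size,
    iteration_days = iteration_days,
    passenger_model = match.arg(passenger_model),
    targeted_dr_factor = targeted_dr_factor,
    general_mr_boost_max = general_mr_boost_max,
    surgery_hallmark = match.arg(surgery_hallmark),
    max_founder_size = max_founder_size,
    allow_large_founders = allow_large_founders
  )
  class(params) <- "clonedyn_params"
  report <- validate_params(params)
  if (length(report) > 0) {
    rlang::abort(c("Invalid global parameters:", stats::setNames(report, rep("x", length(report)))))
  }
  params
}

#' Validate global model constants
#'
#' Checks every invariant of the global parameter list and returns a
#' character vector of violations (empty when valid). Never mutates or
#' repairs its input.
#'
#' @param params A list as built by [global_params()].
#' @return Character vector of violation messages; `character(0)` if valid.
#' @examples
#' validate_params(global_params())                 # character(0)
#' p <- global_params(); p$c <- 0
#' validate_params(p)                               # "c must be > 0"
#' @export
validate_params <- function(params) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(params$c) && params$c > 0, "c must be > 0")
  chk(num1(params$z) && params$z > 0 && params$z <= 1, "z must satisfy 0 < z <= 1")
  chk(num1(params$x1) && num1(params$y1) && params$x1 <= params$y1,
      "DR perturbation bounds must satisfy x1 <= y1")
  chk(num1(params$x2) && num1(params$y2) && params$x2 <= params$y2,
      "AR perturbation bounds must satisfy x2 <= y2")
  chk(num1(params$driver_divisor) && params$driver_divisor > 0,
      "driver_divisor must be > 0")
  chk(num1(params$max_subpops) && params$max_subpops >= 1,
      "max_subpops must be >= 1")
  chk(num1(params$mr_drift_prob) && params$mr_drift_prob >= 0 &&
        params$mr_drift_prob <= 1,
      "mr_drift_prob must satisfy 0 <= p <= 1")
  chk(num1(params$small_size_threshold) && params$small_size_threshold > 0,
      "small_size_threshold must be > 0")
  chk(num1(params$mr_drift_scale) && params$mr_drift_scale >= 0,
      "mr_drift_scale must be >= 0")
  chk(num1(params$detect_size) && params$detect_size > 0,
      "detect_size must be > 0")
  chk(num1(params$iteration_days) && params$iteration_days > 0,
      "iteration_days must be > 0")
  chk(num1(params$targeted_dr_factor) && params$targeted_dr_factor > 0 &&
        params$targeted_dr_factor <= 1,
      "targeted_dr_factor must satisfy 0 < f <= 1")
  chk(num1(params$general_mr_boost_max) && params$general_mr_boost_max >= 0,
      "general_mr_boost_max must be >= 0")
  bad
}

#' Hallmark categories of driver events
#'
#' The three groups of cancer hallmarks a driver mutation can activate:
#' proliferation/survival (strong DR boost), invasion/microenvironment
#' regulation (strong AR reduction) and genomic mutability (strong MR
#' boost).
#'
#' @return Character vector of the three category names, in their canonical
#'   order.
#' @export
hallmark_categories <- function() {
  c("proliferation_survival", "invasion_microenv", "genomic_mutability")
}

#' Specify founder subpopulations
#'
#' Builds the validated tibble of founder (initial) subclones that seeds a
#' simulation. One to three founders are allowed; each has an initial size
#' `n` and its three rate attributes: division rate `DR` (division
#' probability per cell per iteration), apoptosis rate `AR` (fraction of
#' cells dying per iteration) and mutation rate `MR` (expected mutation
#' count per iteration).
#'
#' Defaults follow the model's canonical tumor-cell setting: `DR = 0.2`
#' (0.15 to 0.2 for cancer cells, 0.1 for precancerous cells), `AR = 0.05`,
#' `MR = 100`, size 30. Arguments are recycled to the longest length.
#'
#' @param size Initial cell counts, one per founder (1 to 100 unless
#'   `allow_large_founders` is set in the global parameters).
#' @param DR,AR,MR Rate attributes, recycled across founders.
#' @return A tibble with columns `size`, `DR`, `AR`, `MR` and class
#'   `"clonedyn_founders"`.
#' @examples
#' founders()                       # one canonical founder, size 30
#' founders(size = c(10, 10, 10))   # three founders
#' @export
founders <- function(size = 30, DR = 0.2, AR = 0.05, MR = 100) {
  df <- tibble::tibble(size = size, DR = DR, AR = AR, MR = MR)
  class(df) <- c("clonedyn_founders", class(df))
  df
}

# Founder invariants; returns violations, empty when valid.
validate_founders <- function(founders, params = global_params()) {
  bad <- character(0)
  need <- c("size", "DR", "AR", "MR")
  if (!is.data.frame(founders) || !all(need %in% names(founders))) {
    return("founders must be a data frame with columns size, DR, AR, MR")
  }
  n <- nrow(founders)
  if (n < 1 || n > 3) bad <- c(bad, "between 1 and 3 founders are required")
  if (any(!is.finite(founders$size)) || any(founders$size < 1) ||
      any(founders$size != floor(founders$size))) {
    bad <- c(bad, "founder sizes must be positive integers")
  }
  if (!params$allow_large_founders &&
      any(founders$size > params$max_founder_size, na.rm = TRUE)) {
    bad <- c(bad, sprintf("founder sizes must be <= %d (set allow_large_founders to override)",
                          as.integer(params$max_founder_size)))
  }
  if (any(!is.finite(founders$DR)) || any(founders$DR <= 0)) {
    bad <- c(bad, "DR must be > 0")
  }
  if (any(!is.finite(founders$AR)) || any(founders$AR < 0) || any(founders$AR >= 1)) {
    bad <- c(bad, "AR must lie in [0, 1)")
  }
  if (any(!is.finite(founders$MR)) || any(founders$MR < 0)) {
    bad <- c(bad, "MR must be >= 0")
  }
  bad
}
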