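#' Derive per-replicate seeds from a base seed
#'
#' Seeds the RNG with the base seed and draws distinct child seeds, so
#' replicate k is reproducible in isolation from `(base_seed, k)`.
#'
#' @param base_seed Integer base seed.
#' @param reps Number of replicates.
#' @return Integer vector of `reps` distinct seeds.
#' @export
replicate_seeds <- function(base_seed, reps) {
  set.seed(base_seed)
  sample.int(2147483646L, reps)
}

#' Random multi-founder recipe
#'
#' Factory for the founder draw used by multi-founder scenarios: `n`
#' founder subclones splitting `total_size` cells equally (remainder to the
#' first), each with its division rate drawn independently and uniformly
#' from the cancer-cell range 0.15-0.2, `AR = 0.05` and `MR = 100`.
#'
#' @param n Number of founders (1-3).
#' @param total_size Total initial tumor size to split across founders.
#' @return A zero-argument function that draws a founder tibble from the
#'   current RNG stream (pass it as `founders` to [run_replicates()]).
#' @export
draw_founders <- function(n = 3, total_size = 100) {
  stopifnot(n >= 1, n <= 3, total_size >= n)
  base <- total_size %/% n
  sizes <- rep(base, n)
  sizes[1] <- sizes[1] + total_size - sum(sizes)
  function() {
    founders(size = sizes, DR = stats::runif(n, 0.15, 0.2),
             AR = 0.05, MR = 100)
  }
}

#' Run replicated seeded simulations
#'
#' The generic replication harness behind every scenario: runs `reps`
#' independent simulations with per-replicate seeds derived from
#' `base_seed`, and collects one row per replicate. The whole table is
#' reproducible from `base_seed`, and any single replicate can be re-run in
#' isolation from its recorded seed.
#'
#' @param founders Either a founder tibble used for every replicate, or a
#'   zero-argument function drawing one (called after the replicate's seed
#'   is set, so the draw is reproducible; see [draw_founders()]).
#' @param iterations,params,schedule,stop_at_size,strict_schedule Passed to
#'   [simulate_tumor()].
#' @param reps Number of replicates (the canonical study size is 200).
#' @param base_seed Base seed from which per-replicate seeds are derived.
#' @param outcome Optional function mapping a trajectory to a one-row data
#'   frame of outcome columns, bound onto each replicate's row.
#' @return A tibble with columns `replicate`, `seed`, `final_time`,
#'   `final_N`, plus any outcome columns.
#' @examples
#' run_replicates(founders(), iterations = 20, reps = 3, base_seed = 1)
#' @export
run_replicates <- function(founders = clonedyn::founders(),
                           iterations = 200,
                           params = global_params(),
                           schedule = NULL,
                           reps = 200,
                           base_seed = 1,
                           outcome = NULL,
                           stop_at_size = NULL,
                           strict_schedule = TRUE) {
  seeds <- replicate_seeds(base_seed, reps)
  rows <- lapply(seq_len(reps), function(k) {
    set.seed(seeds[k])
    f <- if (is.function(founders)) founders() else founders
    traj <- simulate_tumor(f, iterations = iterations, params = params,
                           schedule = schedule, seed = NULL,
                           stop_at_size = stop_at_size,
                           strict_schedule = strict_schedule)
    last <- max(traj$time)
    row <- tibble::tibble(
      replicate = k, seed = seeds[k],
      final_time = last,
      final_N = sum(traj$size[traj$time == last])
    )
    if (!is.null(outcome)) row <- dplyr::bind_cols(row, outcome(traj))
    row
  })
  dplyr::bind_rows(rows)
}

# ITH metrics of the trajectory slice at one time point.
metrics_at <- function(traj, t) {
  slice <- traj[traj$time == t, , drop = FALSE]
  tibble::tibble(
    dominant_clone_proportion = dominant_clone_proportion(slice),
    off_target_probability = off_target_probability(slice)
  )
}

# Significance stars as printed in the model's figures.
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 0.05 ~ "*",
    .default = "ns"
  )
}

#' One-at-a-time parameter sweep of untreated growth
#'
#' Reproduces the untreated simulation study: starting from the baseline
#' (one founder, size 30, DR = 0.2, AR = 0.05, MR = 100), one parameter is
#' varied at a time — the founder division rate, the mutation rate, or the
#' number of founder subpopulations (total size 30 split equally, each
#' founder's DR drawn from 0.15-0.2) — and the final tumor size after
#' `iterations` iterations is recorded per replicate. High mutation rates
#' depress late tumor size (mutational load), and extra founders do not
#' increase it (competition).
#'
#' @param DRs,MRs,founder_counts Grids for the three one-at-a-time sweeps.
#' @param reps Replicates per grid point.
#' @param base_seed Base seed (shared across grid points, so points are
#'   coupled through common replicate seeds).
#' @param iterations Simulation length.
#' @return A tibble: `parameter`, `value`, `replicate`, `seed`, `final_N`.
#' @export
sweep_parameters <- function(DRs = c(0.15, 0.2),
                             MRs = c(100, 500, 1000),
                             founder_counts = 1:3,
                             reps = 200, base_seed = 1, iterations = 200) {
  grid <- dplyr::bind_rows(
    tibble::tibble(parameter = "DR", value = DRs),
    tibble::tibble(parameter = "MR", value = MRs),
    tibble::tibble(parameter = "founders", value = as.numeric(founder_counts))
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    par <- grid$parameter[i]
    val <- grid$value[i]
    f <- switch(par,
      DR = founders(size = 30, DR = val),
      MR = founders(size = 30, MR = val),
      founders = draw_founders(n = as.integer(val), total_size = 30)
    )
    res <- run_replicates(f, iterations = iterations, reps = reps,
                          base_seed = base_seed)
    dplyr::bind_cols(tibble::tibble(parameter = par, value = val), res)
  })
  dplyr::bind_rows(out)
}

#' Therapy-interval study
#'
#' Reproduces the treatment-timing experiment: two founder subpopulations
#' (total initial size 100), a targeted therapy of 10 iterations starting
#' at time 100, then an adjuvant general therapy of 10 iterations starting
#' `interval` iterations after the targeted course *starts* (so at time
#' `100 + interval`; for intervals below 10 the two courses overlap and the
#' tumor is hit by both at once). The outcome is the log10 fold change of
#' tumor size between times 100 and 170. Short intervals give the best
#' outcomes; the treatment effect worsens as the adjuvant course is
#' delayed.
#'
#' @param intervals Gaps (iterations) between the starts of the targeted
#'   course and of the adjuvant general course.
#' @param reps Replicates per interval.
#' @param base_seed Base seed; replicate seeds are shared across intervals,
#'   so pre-therapy histories are paired.
#' @return An object of class `clonedyn_intervals`; `tidy()` gives the
#'   per-replicate table, `glance()` the per-interval medians.
#' @export
sweep_therapy_intervals <- function(intervals = c(5, 10, 15, 20),
                                    reps = 200, base_seed = 1) {
  out <- lapply(intervals, function(gap) {
    sched <- dplyr::bind_rows(
      therapy_course("targeted", start = 100, duration = 10),
      therapy_course("general", start = 100 + gap, duration = 10)
    )
    res <- run_replicates(
      draw_founders(n = 2, total_size = 100),
      iterations = 170, schedule = sched, reps = reps,
      base_seed = base_seed, strict_schedule = FALSE,
      outcome = function(traj) fold_change(traj, 100, 170)[, c("N0", "N1", "fold_change", "log10_fold_change")]
    )
    dplyr::bind_cols(tibble::tibble(interval = gap), res)
  })
  structure(list(results = dplyr::bind_rows(out),
                 intervals = intervals, reps = reps, base_seed = base_seed),
            class = "clonedyn_intervals")
}

#' Adjuvant versus neoadjuvant general therapy around surgery
#'
#' Reproduces the therapy-ordering experiment: two founder subpopulations
#' (total size 100); in the *adjuvant* arm surgery is performed at time 100
#' followed by a 10-iteration general therapy at time 120, in the
#' *neoadjuvant* arm the general therapy starts at time 100 and surgery
#' follows at time 120. The outcome is the log10 fold change of tumor size
#' between times 100 and 170; arms are compared with a rank-based
#' two-sample (Wilcoxon) test, whose p-value is reported, not asserted.
#'
#' @param reps Replicates per arm.
#' @param base_seed Base seed; seeds are shared across arms (paired
#'   pre-therapy histories).
#' @return An object of class `clonedyn_adjuvant`; `tidy()` gives
#'   per-replicate rows with an `arm` column, `glance()` the arm medians,
#'   the Wilcoxon p-value and its significance stars.
#' @export
compare_adjuvant_neoadjuvant <- function(reps = 200, base_seed = 1) {
  arms <- list(
    adjuvant = dplyr::bind_rows(
      therapy_course("surgery", start = 100),
      therapy_course("general", start = 120, duration = 10)
    ),
    neoadjuvant = dplyr::bind_rows(
      therapy_course("general", start = 100, duration = 10),
      therapy_course("surgery", start = 120)
    )
  )
  out <- lapply(names(arms), function(arm) {
    res <- run_replicates(
      draw_founders(n = 2, total_size = 100),
      iterations = 170, schedule = arms[[arm]], reps = reps,
      base_seed = base_seed, strict_schedule = FALSE,
      outcome = function(traj) fold_change(traj, 100, 170)[, c("N0", "N1", "fold_change", "log10_fold_change")]
    )
    dplyr::bind_cols(tibble::tibble(arm = arm), res)
  })
  results <- dplyr::bind_rows(out)
  test <- stats::wilcox.test(log10_fold_change ~ arm, data = results,
                             exact = FALSE)
  structure(list(results = results, test = test, reps = reps,
                 base_seed = base_seed),
            class = "clonedyn_adjuvant")
}

#' Heterogeneity metrics versus targeted-therapy outcome
#'
#' Reproduces the metric-outcome correlation study: `n_founders` founder
#' subpopulations (total size 100), a single 10-iteration targeted therapy
#' at time 100, outcome measured as the log10 fold change of tumor size 50
#' iterations after the course ends (time 160 versus 100). Both
#' heterogeneity metrics are recorded at therapy start, and their Spearman
#' rank correlations with the outcome are reported. With three founders the
#' dominant-clone proportion correlates negatively and the off-target
#' probability positively with the outcome; with a single founder the
#' off-target correlation attenuates because every descendant shares the
#' founding driver.
#'
#' @param n_founders Number of founder subpopulations (3 in the canonical
#'   study).
#' @param reps Replicates.
#' @param base_seed Base seed.
#' @return An object of class `clonedyn_ith_cor`; `tidy()` gives the
#'   per-replicate table, `glance()` the two correlations with p-values.
#' @export
ith_outcome_correlation <- function(n_founders = 3, reps = 200,
                                    base_seed = 1) {
  sched <- therapy_course("targeted", start = 100, duration = 10)
  res <- run_replicates(
    draw_founders(n = n_founders, total_size = 100),
    iterations = 160, schedule = sched, reps = reps, base_seed = base_seed,
    outcome = function(traj) {
      dplyr::bind_cols(
        metrics_at(traj, 100),
        fold_change(traj, 100, 160)[, c("N0", "N1", "log10_fold_change")]
      )
    }
  )
  ok <- stats::complete.cases(
    res[, c("dominant_clone_proportion", "off_target_probability",
            "log10_fold_change")])
  use <- res[ok, ]
  cor_dom <- suppressWarnings(stats::cor.test(
    use$dominant_clone_proportion, use$log10_fold_change,
    method = "spearman"))
  cor_off <- suppressWarnings(stats::cor.test(
    use$off_target_probability, use$log10_fold_change,
    method = "spearman"))
  structure(list(results = res, cor_dominant = cor_dom,
                 cor_off_target = cor_off, n_founders = n_founders,
                 reps = reps, base_seed = base_seed),
            class = "clonedyn_ith_cor")
}

#' Heterogeneity-metric trajectories over tumor development
#'
#' Runs replicated untreated simulations (three founder subpopulations,
#' total size 100) and summarizes both heterogeneity metrics at every time
#' point by their median and quartiles across replicates. Both metrics
#' typically follow a parabolic course — heterogeneity rises while new
#' subclones emerge and falls again as a dominant subclone sweeps.
#'
#' @param n_founders Number of founder subpopulations.
#' @param reps Replicates.
#' @param base_seed Base seed.
#' @param iterations Simulation length.
#' @return An object of class `clonedyn_metric_summary` whose `tidy()`
#'   method returns one row per time point and metric (`median`, `q25`,
#'   `q75`).
#' @export
metric_trajectory_summary <- function(n_founders = 3, reps = 200,
                                      base_seed = 1, iterations = 200) {
  seeds <- replicate_seeds(base_seed, reps)
  series <- lapply(seq_len(reps), function(k) {
    set.seed(seeds[k])
    f <- draw_founders(n = n_founders, total_size = 100)()
    traj <- simulate_tumor(f, iterations = iterations, seed = NULL)
    m <- ith_metrics(traj)
    dplyr::bind_cols(tibble::tibble(replicate = k), tibble::as_tibble(m))
  })
  long <- tidyr::pivot_longer(
    dplyr::bind_rows(series),
    cols = c("dominant_clone_proportion", "off_target_probability"),
    names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(long, time, metric),
    median = stats::median(value, na.rm = TRUE),
    q25 = stats::quantile(value, 0.25, na.rm = TRUE, names = FALSE),
    q75 = stats::quantile(value, 0.75, na.rm = TRUE, names = FALSE),
    n = sum(!is.na(value)),
    .groups = "drop")
  structure(list(summary = summary, reps = reps, base_seed = base_seed,
                 iterations = iterations),
            class = "clonedyn_metric_summary")
}

#' Tumorigenesis detection-time study
#'
#' Starts simulations at a near-normal cell state (low DR and AR) and
#' measures the real time needed to reach a detectable tumor size. From the
#' base point `DR = AR = 0.02`, `MR = 100` — a founder with *no initial
#' fitness advantage* — one parameter is varied at a time across the given
#' grids. Each replicate runs until detection (`detect_size`, default
#' 10000) or the iteration cap, and crossing times are converted to years
#' with `iteration_days = 10`. Censored runs are reported, not dropped.
#'
#' @param MR_grid,DR_grid One-at-a-time grids around the base point
#'   (`DR = 0.02`, `MR = 100`).
#' @param AR Apoptosis rate of the founder (0.02 for near-normal cells).
#' @param size Founder size.
#' @param reps Replicates per grid point.
#' @param base_seed Base seed.
#' @param max_iterations Iteration cap after which a run is censored
#'   (default 2000, about 55 years).
#' @param params Global parameters (detection threshold and iteration
#'   length are taken from here).
#' @return An object of class `clonedyn_tumorigenesis`; `tidy()` gives one
#'   row per replicate (`DR`, `MR`, `detected`, `iteration`, `years`),
#'   `glance()` the per-point median and range of detection times plus the
#'   censored fraction.
#' @export
tumorigenesis_study <- function(MR_grid = c(50, 100, 500),
                                DR_grid = c(0.02, 0.03, 0.04),
                                AR = 0.02, size = 30,
                                reps = 200, base_seed = 1,
                                max_iterations = 2000,
                                params = global_params()) {
  grid <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(DR = 0.02, MR = MR_grid),
    tibble::tibble(DR = DR_grid, MR = 100)
  ))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    f <- founders(size = size, DR = grid$DR[i], AR = AR, MR = grid$MR[i])
    res <- run_replicates(
      f, iterations = max_iterations, params = params, reps = reps,
      base_seed = base_seed, stop_at_size = params$detect_size,
      outcome = function(traj) {
        detection_time(traj, threshold = params$detect_size,
                       iteration_days = params$iteration_days)
      }
    )
    dplyr::bind_cols(tibble::tibble(DR = grid$DR[i], MR = grid$MR[i]), res)
  })
  structure(list(results = dplyr::bind_rows(out), grid = grid, reps = reps,
                 base_seed = base_seed, max_iterations = max_iterations),
            class = "clonedyn_tumorigenesis")
}
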