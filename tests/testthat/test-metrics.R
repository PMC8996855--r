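test_that("dominant clone proportion matches hand-computed values", {
  expect_equal(dominant_clone_proportion(toy_slice(c(60, 30, 10))), 0.6)
  expect_equal(dominant_clone_proportion(toy_slice(100)), 1)
  expect_true(is.na(dominant_clone_proportion(toy_slice(c(0, 0)))))
  # dead subclones are excluded
  expect_equal(dominant_clone_proportion(toy_slice(c(50, 50, 0))), 0.5)
})

test_that("off-target probability matches set arithmetic", {
  # dominant carries {1}; minors add events 2 and 3 -> 2 of 3 off-target
  sl <- toy_slice(c(100, 10, 10),
                  drivers = list(1L, c(1L, 2L), c(1L, 3L)))
  expect_equal(off_target_probability(sl), 2 / 3)
  expect_equal(off_target_probability(toy_slice(40, drivers = list(1L))), 0)
  # zero iff the dominant clone carries the whole extant driver union
  all_in <- toy_slice(c(100, 10), drivers = list(c(1L, 2L), 2L))
  expect_equal(off_target_probability(all_in), 0)
  # drivers private to dead subclones are excluded from the union
  dead <- toy_slice(c(100, 0), drivers = list(1L, c(1L, 2L)))
  expect_equal(off_target_probability(dead), 0)
  # ties broken by lowest subclone id
  tie <- toy_slice(c(10, 10), drivers = list(1L, c(1L, 2L)))
  expect_equal(off_target_probability(tie), 1 / 2)
})

test_that("both metrics agree with a brute-force recomputation", {
  set.seed(33)
  for (i in 1:50) {
    k <- sample(1:10, 1)
    n_events <- sample(1:20, 1)
    sizes <- sample(0:1000, k, replace = TRUE)
    if (all(sizes == 0)) sizes[1] <- 1
    drv <- lapply(seq_len(k), function(j) {
      sort(sample.int(n_events, sample(1:min(5, n_events), 1)))
    })
    sl <- toy_slice(sizes, drivers = drv)
    # independent oracle: explicit loops over living subclones and events
    live <- which(sizes > 0)
    dom <- live[order(-sizes[live], live)][1]
    union_ev <- sort(unique(unlist(drv[live])))
    off <- sum(vapply(union_ev, function(e) !(e %in% drv[[dom]]), TRUE))
    expect_equal(dominant_clone_proportion(sl), max(sizes[live]) / sum(sizes))
    expect_equal(off_target_probability(sl), off / length(union_ev))
  }
})

test_that("both metrics are invariant to rescaling all subclone sizes", {
  sl <- toy_slice(c(500, 300, 200), drivers = list(1L, c(1L, 2L), 3L))
  sl10 <- sl
  sl10$size <- sl10$size * 10
  expect_equal(dominant_clone_proportion(sl), dominant_clone_proportion(sl10))
  expect_equal(off_target_probability(sl), off_target_probability(sl10))
})

test_that("the metric series covers every time point within bounds", {
  traj <- short_run(iterations = 80)
  m <- ith_metrics(traj)
  expect_equal(m$time, 0:80)            # one row per time point
  expect_equal(m$dominant_clone_proportion[1], 1)   # single founder
  expect_equal(m$off_target_probability[1], 0)
  ok <- m$N > 0
  expect_true(all(m$dominant_clone_proportion[ok] > 0 &
                    m$dominant_clone_proportion[ok] <= 1))
  expect_true(all(m$off_target_probability[ok] >= 0 &
                    m$off_target_probability[ok] <= 1))
  expect_equal(m$N, tumor_size(traj)$N)
})

test_that("fold change and its log are computed from the size series", {
  traj <- tibble::tibble(time = c(0L, 1L, 2L), size = c(100, 50, 10))
  fc <- fold_change(traj, 0, 2)
  expect_equal(fc$fold_change, 0.1)
  expect_equal(fc$log10_fold_change, -1)
  flat <- tibble::tibble(time = 0:3, size = rep(70, 4))
  expect_equal(fold_change(flat, 0, 3)$log10_fold_change, 0)
  empty0 <- tibble::tibble(time = 0:1, size = c(0, 5))
  expect_error(fold_change(empty0, 0, 1), "zero")
  expect_error(fold_change(traj, 0, 9), "recorded")
})

test_that("detection time converts iterations to years and censors", {
  # deterministic toy trajectory crossing the threshold at iteration 350
  traj <- tibble::tibble(time = c(0L, 350L), size = c(30, 20000))
  dt <- detection_time(traj, threshold = 10000, iteration_days = 10)
  expect_true(dt$detected)
  expect_equal(dt$iteration, 350L)
  expect_equal(dt$years, 350 * 10 / 365)
  never <- tibble::tibble(time = 0:5, size = rep(100, 6))
  expect_false(detection_time(never, 10000)$detected)
  expect_true(is.na(detection_time(never, 10000)$years))
  at_birth <- tibble::tibble(time = 0L, size = 20000)
  expect_equal(detection_time(at_birth, 10000)$years, 0)
})

test_that("tumor size reports zero after total extinction", {
  # find a founder whose single driver is not the mutability hallmark, so
  # surgery eradicates the tumor outright
  seed <- 1
  repeat {
    traj <- simulate_tumor(founders(size = 50),
                           iterations = 10,
                           schedule = therapy_course("surgery", start = 5),
                           seed = seed)
    ev <- events(traj)
    if (ev$category[1] != "genomic_mutability") break
    seed <- seed + 1
  }
  sizes <- tumor_size(traj)
  expect_equal(sizes$time, 0:10)
  expect_true(all(sizes$N[sizes$time > 5] == 0))
  m <- ith_metrics(traj)
  expect_equal(m$time, 0:10)
  expect_true(all(is.na(m$dominant_clone_proportion[m$time > 5])))
})
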