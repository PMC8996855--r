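test_that("the competition factor is 1 at N = 0 and decreases with N", {
  expect_equal(constraint_factor(0, 0.2, 0.05), 1)
  expect_equal(constraint_factor(1e6, 0.2, 0.05, c = 1e4), exp(-1))
  N <- seq(0, 2e6, length.out = 50)
  f <- constraint_factor(N, 0.2, 0.05)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
})

test_that("growth step matches its closed-form expectation", {
  # mean change = size*DR*exp(-N*DR*AR/c) - floor(size*AR)
  set.seed(101)
  n <- 1e5
  new_sizes <- growth_step(rep(1000, n), DR = 0.2, AR = 0.05, N = 1000)
  delta <- new_sizes - 1000
  expected <- 1000 * 0.2 * exp(-1000 * 0.2 * 0.05 / 1e4) - floor(1000 * 0.05)
  se <- stats::sd(delta) / sqrt(n)
  expect_lt(abs(mean(delta) - expected), 3 * se)
  # empty subclones stay empty; deaths use floor arithmetic
  expect_equal(growth_step(0, 0.2, 0.05, N = 0), 0)
  set.seed(1)
  deaths_only <- growth_step(30, DR = 1e-12, AR = 0.05, N = 30)
  expect_equal(deaths_only, 30 - 1)     # floor(30 * 0.05) = 1 death
})

test_that("passenger drift matches the floored-uniform count oracle", {
  # k = floor(MR * U(0, z)) with MR = 100, z = 0.1 is uniform on {0..9},
  # mean 4.5; E[dDR] = 4.5 * (x1 + y1) / 2 = -4.5e-4
  set.seed(202)
  n <- 1e5
  upd <- passenger_step(rep(0.2, n), rep(0.05, n), rep(100, n))
  expect_equal(sort(unique(upd$k)), 0:9)
  se_k <- stats::sd(upd$k) / sqrt(n)
  expect_lt(abs(mean(upd$k) - 4.5), 3 * se_k)
  dDR <- upd$DR - 0.2
  se <- stats::sd(dDR) / sqrt(n)
  expect_lt(abs(mean(dDR) - (-4.5e-4)), 3 * se)
  expect_lt(mean(dDR), 0)               # net deleterious passenger load
  # MR = 0 means no passengers and no change
  none <- passenger_step(0.2, 0.05, 0)
  expect_equal(none$k, 0L)
  expect_equal(none$DR, 0.2)
  expect_equal(none$AR, 0.05)
})

test_that("AR passenger perturbations are relative and clamped", {
  set.seed(11)
  n <- 2e4
  upd <- passenger_step(rep(0.2, n), rep(0.5, n), rep(100, n))
  # relative bounds: per passenger at most |x2| = 0.002 of current AR
  expect_true(all(upd$AR >= 0.5 * (1 - 9 * 0.002)))
  expect_true(all(upd$AR <= 0.5 * (1 + 9 * 0.002)))
  expect_true(all(upd$AR >= 0 & upd$AR < 1))
})

test_that("MR drift is zero at the size threshold and ordered in size", {
  p <- global_params(mr_drift_prob = 1)   # force the size-dependent branch
  set.seed(3)
  expect_equal(mr_drift(100, 10, p), 100) # log10(10) - log10(10) = 0
  set.seed(3)
  expect_lt(mr_drift(100, 5, p), 100)     # small subclones lose mutability
  set.seed(3)
  d_small <- mr_drift(100, 1e3, p) - 100
  set.seed(3)
  d_large <- mr_drift(100, 1e6, p) - 100
  expect_gt(d_large, d_small)
  # clamped at zero
  set.seed(3)
  expect_gte(mr_drift(0.01, 1, p), 0)
})

test_that("driver events occur at rate MR / 6000 per subclone", {
  set.seed(404)
  n <- 3e4
  p <- global_params(max_subpops = 1e9)
  st <- toy_state(size = rep(10, n), drivers = as.list(rep(1L, n)),
                  MR = 100)
  out <- driver_trial(st, p)
  spawned <- length(out$size) - n
  phat <- spawned / n
  se <- sqrt((1 / 60) * (59 / 60) / n)
  expect_lt(abs(phat - 1 / 60), 3 * se)
})

test_that("spawned subclones are strictly fitter and conserve cells", {
  set.seed(7)
  p <- global_params()
  for (rep in 1:200) {
    st <- toy_state(size = 50, drivers = list(1L), MR = 6001)  # certain spawn
    out <- driver_trial(st, p)
    expect_length(out$size, 2)
    expect_gt(out$DR[2], out$DR[1])     # higher fitness assured
    expect_lte(out$AR[2], out$AR[1])
    expect_gt(out$MR[2], out$MR[1])
    expect_equal(out$size[1] + out$size[2], 50)  # child debited from parent
    expect_equal(out$size[2], 1)
    expect_equal(out$TMB[2], out$TMB[1] + 1)
    expect_true(all(out$drivers[[1]] %in% out$drivers[[2]]))
    expect_length(out$drivers[[2]], length(out$drivers[[1]]) + 1)
  }
})

test_that("the subclone cap suppresses further driver trials", {
  set.seed(8)
  p <- global_params(max_subpops = 3)
  st <- toy_state(size = rep(50, 3), drivers = as.list(1:3), MR = 6001)
  out <- driver_trial(st, p)
  expect_length(out$size, 3)
})

test_that("whole-tumor iteration conserves counts and advances time", {
  traj <- short_run(iterations = 150)
  # one record per living subclone per time; N equals the sum of sizes
  by_time <- split(traj, traj$time)
  expect_equal(sort(unique(traj$time)), 0:150)
  for (slice in by_time) {
    expect_lte(sum(slice$size > 0), 10)  # subclone cap, always
    expect_true(all(slice$size >= 0))
    expect_equal(sum(duplicated(slice$subpop_id)), 0)
  }
  # TMB non-decreasing within each subclone's lifetime
  for (sid in unique(traj$subpop_id)) {
    tmb <- traj$TMB[traj$subpop_id == sid]
    expect_true(all(diff(tmb) >= 0))
  }
  # children record strictly higher DR than their parent at spawn
  kids <- traj[!is.na(traj$parent_id) & traj$time == traj$origin_time, ]
  for (i in seq_len(nrow(kids))) {
    parent_dr <- traj$DR[traj$subpop_id == kids$parent_id[i] &
                           traj$time == kids$time[i]]
    expect_gt(kids$DR[i], parent_dr)
  }
  expect_gt(nrow(kids), 0)              # the run did branch
})

test_that("simulation is deterministic in the seed and stochastic across seeds", {
  a <- short_run(iterations = 40, seed = 5)
  b <- short_run(iterations = 40, seed = 5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- short_run(iterations = 40, seed = 6)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
})

test_that("a fit founder population expands by orders of magnitude", {
  # DR = 0.2 >> AR = 0.05: supercritical growth from size 30
  finals <- vapply(1:10, function(s) {
    traj <- simulate_tumor(founders(size = 30), iterations = 150, seed = s)
    sum(traj$size[traj$time == 150])
  }, numeric(1))
  expect_true(all(finals > 3000))
})

test_that("early stopping halts the run once N reaches the threshold", {
  traj <- simulate_tumor(founders(size = 30), iterations = 2000, seed = 3,
                         stop_at_size = 5000)
  sizes <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(traj), time),
                            N = sum(size), .groups = "drop")
  expect_gte(max(sizes$N), 5000)
  expect_true(all(sizes$N[sizes$time < max(sizes$time)] < 5000))
  expect_lt(max(sizes$time), 2000)
  expect_true(attr(traj, "stopped_early"))
})
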