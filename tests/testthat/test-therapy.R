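test_that("schedule validation enforces duration caps and spacing", {
  ok <- dplyr::bind_rows(
    therapy_course("targeted", start = 100, duration = 15),
    therapy_course("general", start = 125, duration = 10)
  )
  expect_length(validate_schedule(ok, 200), 0)
  expect_match(validate_schedule(therapy_course("general", 100, 11), 200),
               "<= 10", all = FALSE)
  expect_length(validate_schedule(therapy_course("targeted", 100, 15), 200), 0)
  expect_match(validate_schedule(therapy_course("immunotherapy", 100, 16), 200),
               "<= 15", all = FALSE)
  close_pair <- dplyr::bind_rows(
    therapy_course("targeted", start = 100, duration = 10),
    therapy_course("general", start = 115, duration = 5)
  )
  expect_match(validate_schedule(close_pair, 200), "at least 10", all = FALSE)
  # the experiment harness may relax spacing (even into overlap)
  expect_length(validate_schedule(close_pair, 200, strict = FALSE), 0)
  expect_match(validate_schedule(therapy_course("general", 300, 5), 200),
               "earlier than", all = FALSE)
  # surgery is instantaneous: a course 10 iterations later is legal
  surg <- dplyr::bind_rows(
    therapy_course("surgery", start = 100),
    therapy_course("general", start = 111, duration = 10)
  )
  expect_length(validate_schedule(surg, 200), 0)
})

test_that("target selection is uniform over the dominant clone's drivers", {
  st <- toy_state(size = c(100, 10), drivers = list(c(1L, 2L), 3L))
  set.seed(1)
  draws <- replicate(1e4, select_target(st))
  expect_true(all(draws %in% c(1L, 2L)))
  phat <- mean(draws == 1L)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 1e4))
  # ties broken by lowest subclone id
  tie <- toy_state(size = c(10, 10), drivers = list(1L, 2L))
  expect_equal(select_target(tie), 1L)
  expect_error(select_target(toy_state(size = 0, drivers = list(1L))),
               "no living subclone")
})

test_that("targeted therapy spares non-carriers and kills 25-60% of carriers", {
  set.seed(2)
  size <- rep(1000L, 1e4)
  hit <- targeted_effect(size, carrier = rep(TRUE, 1e4))
  expect_true(all(hit >= floor(1000 * 0.40) & hit <= floor(1000 * 0.75)))
  expect_lt(abs(mean(hit) - 1000 * 0.575), 3 * stats::sd(hit) / sqrt(1e4))
  expect_equal(targeted_effect(c(50, 70), carrier = c(FALSE, FALSE)),
               c(50, 70))
  # a full 10-iteration course leaves about 0.575^10 of a carrier
  set.seed(3)
  n <- 1e4
  frac <- rep(1, n)
  for (i in 1:10) {
    killed <- targeted_effect(rep(1e9, n), rep(TRUE, n)) / 1e9
    frac <- frac * killed
  }
  expect_lt(abs(mean(frac) - 0.575^10), 3 * stats::sd(frac) / sqrt(n))
})

test_that("general therapy matches its expectation and raises MR", {
  set.seed(4)
  n <- 1e5
  upd <- general_effect(rep(1000, n), rep(100, n))
  # E[floor(1000*(1-U))] = 900 - 1/2 exactly (the fractional part of
  # 1000*(1-U) is uniform); minus the mean integer loss 49.5
  expected <- 1000 * 0.90 - 0.5 - 49.5
  expect_lt(abs(mean(upd$size) - expected), 3 * stats::sd(upd$size) / sqrt(n))
  expect_true(all(upd$MR >= 100))       # mutagenic side-effect
  expect_equal(general_effect(0, 50)$size, 0)
  expect_true(all(general_effect(rep(1L, 1e3), rep(1, 1e3))$size < 1))
})

test_that("surgery spares only large subclones with the mutability hallmark", {
  set.seed(5)
  expect_equal(surgery_effect(c(1e6, 1e6), c(FALSE, FALSE)), c(0, 0))
  surv <- surgery_effect(1e6, TRUE)
  expect_equal(surv, round(1e6 * min(0.40, 1 - exp(-1e6 * 1e-9))))
  expect_lt(surv, 1100)                 # ~1e-3 survivor fraction at 1e6
  expect_equal(surgery_effect(100, TRUE), 0)   # at the size gate, removed
  sizes <- 10^(3:10)
  expect_true(all(surgery_effect(sizes, TRUE) <= 0.40 * sizes))
})

test_that("immunotherapy kill saturates at 45% and grows with TMB", {
  expect_equal(immunotherapy_effect(1000, 0), 1000)
  expect_equal(immunotherapy_effect(1000, 10),
               floor(1000 * exp(-0.02 * 10)))
  expect_equal(immunotherapy_effect(1e6, 30), floor(1e6 * 0.55))  # capped
  expect_equal(immunotherapy_effect(1e6, 1000), floor(1e6 * 0.55))
  kills <- 1e6 - immunotherapy_effect(rep(1e6, 5), c(1, 5, 10, 20, 22))
  expect_true(all(diff(kills) > 0))
})

test_that("every therapy strictly shrinks a positive targeted subclone", {
  set.seed(6)
  sizes <- c(1L, 2L, 5L, 10L, 100L, 12345L)
  for (i in 1:20) {
    expect_true(all(targeted_effect(sizes, rep(TRUE, 6)) < sizes))
    expect_true(all(general_effect(sizes, rep(1, 6))$size < sizes))
    expect_true(all(immunotherapy_effect(sizes, rep(5, 6)) < sizes))
    expect_true(all(surgery_effect(sizes, rep(TRUE, 6)) < sizes))
  }
})

test_that("targeted therapy halves DR for the course and restores it exactly", {
  # MR pinned at 0 (no drift): no passengers, so DR is flat outside the
  # course and the restoration is exact in the recorded series
  f <- founders(size = 50, DR = 0.2, AR = 0.05, MR = 0)
  quiet <- global_params(mr_drift_scale = 0)
  sched <- therapy_course("targeted", start = 10, duration = 5)
  traj <- simulate_tumor(f, iterations = 25, params = quiet,
                         schedule = sched, seed = 9)
  df <- traj[order(traj$time), ]        # single subclone, one row per time
  expect_equal(df$DR[df$time <= 10], rep(0.2, 11))
  expect_equal(df$DR[df$time >= 11 & df$time <= 15], rep(0.1, 5))
  expect_equal(df$DR[df$time >= 16], rep(0.2, 10))
  # and the course shrank the (only, carrying) subclone overall
  expect_lt(df$size[df$time == 15], df$size[df$time == 10])
})

test_that("therapy effects never enlarge a subclone at their sub-step", {
  set.seed(10)
  for (i in 1:50) {
    sz <- sample.int(1e6, 8)
    expect_true(all(targeted_effect(sz, rep(TRUE, 8)) <= sz))
    expect_true(all(general_effect(sz, rep(100, 8))$size <= sz))
    expect_true(all(immunotherapy_effect(sz, rexp(8, 1 / 20)) <= sz))
    expect_true(all(surgery_effect(sz, sample(c(TRUE, FALSE), 8, TRUE)) <= sz))
  }
})
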