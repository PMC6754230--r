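test_that("no entry pathway gives a quiescent, empty trajectory", {
  kin <- MotorKinetics(0, 0, 0.5, 2, 1, c_total = 1)
  tr <- simulateGillespie(kin, LatticeSpec(5), ReservoirSpec(closed = FALSE),
                          duration = 100, seed = 1)
  expect_true(tr@quiescent)
  expect_equal(nrow(trajectoryEvents(tr)), 0)
  expect_equal(tr@final_state, rep(0L, 5))
})

test_that("identical seeds reproduce identical event sequences", {
  kin <- kin_small()
  tr1 <- simulateGillespie(kin, LatticeSpec(4), ReservoirSpec(closed = FALSE),
                           duration = 50, seed = 99)
  tr2 <- simulateGillespie(kin, LatticeSpec(4), ReservoirSpec(closed = FALSE),
                           duration = 50, seed = 99)
  expect_identical(trajectoryEvents(tr1), trajectoryEvents(tr2))
  tr3 <- simulateGillespie(kin, LatticeSpec(4), ReservoirSpec(closed = FALSE),
                           duration = 50, seed = 100)
  expect_false(identical(trajectoryEvents(tr1), trajectoryEvents(tr3)))
})

test_that("trajectory states respect single-site exclusion", {
  kin <- kin_small()
  tr <- simulateGillespie(kin, LatticeSpec(4), ReservoirSpec(closed = FALSE),
                          duration = 200, seed = 3)
  states <- trajectoryStates(tr)
  expect_true(all(vapply(states, function(s) all(s %in% 0:1), logical(1))))
  expect_identical(states[[length(states)]], as.integer(tr@final_state))
  expect_true(all(diff(trajectoryEvents(tr)$time_s) >= 0))
})

test_that("time-averaged occupancy matches hand-computable replays", {
  # constant state: a trajectory with one landing event at t=0+ then
  # nothing; occupancy of that site ~ fraction of window occupied
  kin <- MotorKinetics(0, 0, 0, 0, 0, c_total = 1)  # frozen dynamics
  tr <- new("LatticeTrajectory",
            events = data.frame(
              time_s = c(2, 6),
              event_type = factor(c("land", "detach"),
                                  levels = kip2traffic:::.EVENT_LABELS),
              site_index = c(2L, 2L), n_sites = c(3L, 3L)),
            n_init = 3L, duration = 10, final_state = c(0L, 0L, 0L),
            rng_seed = 1L, quiescent = FALSE, reservoir = list())
  occ <- occupancy(timeAveragedOccupancy(tr, burn_in = 0))
  expect_equal(occ, c(0, 0.4, 0))          # occupied from t=2 to t=6
  occ2 <- occupancy(timeAveragedOccupancy(tr, burn_in = 4))
  expect_equal(occ2, c(0, 2 / 6, 0))       # occupied from t=4 to t=6
  expect_error(timeAveragedOccupancy(tr, burn_in = 10), "burn_in")
})

test_that("Gillespie time averages match exact master-equation marginals", {
  kin <- kin_small()
  for (n in c(2L, 4L, 6L)) {
    tr <- simulateGillespie(kin, LatticeSpec(n),
                            ReservoirSpec(closed = FALSE),
                            duration = 30000, seed = 40 + n)
    ta <- occupancy(timeAveragedOccupancy(tr, burn_in = 500))
    exact <- occupancy(solveMasterEquation(kin, LatticeSpec(n), 1))
    # Monte-Carlo standard error per site from 30 batch means
    ev <- trajectoryEvents(tr)
    win <- seq(500, 30000, length.out = 31)
    per_batch <- sapply(seq_len(30), function(b) {
      idx <- ev$time_s > win[b] & ev$time_s <= win[b + 1]
      # occupancy within batch from the replay helper
      kip2traffic:::.time_average_cpp(
        ev$time_s, as.integer(ev$event_type), ev$site_index, n,
        win[b + 1], win[b])
    })
    se <- apply(per_batch, 1, sd) / sqrt(30)
    expect_true(all(abs(ta - exact) <= 3 * pmax(se, 1e-3)),
                info = paste("n =", n))
  }
})

test_that("closed reservoir conserves integer motor copies", {
  kin <- MotorKinetics(0.5, 0.05, 0.1, 2, 1, c_total = 10)
  res <- ReservoirSpec(volume = 2, n_filaments = 1, closed = TRUE)
  tr <- simulateGillespie(kin, LatticeSpec(6), res, duration = 500,
                          seed = 8)
  total <- tr@reservoir$total_copies
  expect_equal(total, round(10 * 2 * 0.602214076))
  expect_equal(tr@reservoir$free_copies + sum(tr@final_state), total)
  # replay: conservation holds after every event
  states <- trajectoryStates(tr)
  ev <- trajectoryEvents(tr)
  bound <- vapply(states, sum, numeric(1))
  delta <- diff(c(0, bound))
  gain <- ev$event_type %in% c("entry", "land")
  loss <- ev$event_type %in% c("detach", "exit")
  expect_true(all(delta[gain] == 1))
  expect_true(all(delta[loss] == -1))
})

test_that("the stochastic simulator refuses multi-filament reservoirs", {
  kin <- kin_small()
  expect_error(
    simulateGillespie(kin, LatticeSpec(4), ReservoirSpec(n_filaments = 2),
                      duration = 10, seed = 1),
    "n_filaments")
})

test_that("growth_rate = 0 reduces the growing lattice to the static one", {
  kin <- kin_small()
  a <- simulateGillespie(kin, LatticeSpec(5), ReservoirSpec(closed = FALSE),
                         duration = 100, seed = 12)
  b <- simulateGrowingLattice(kin, growth_rate = 0, initial_n = 5,
                              duration = 100, seed = 12,
                              reservoir = ReservoirSpec(closed = FALSE))
  expect_identical(trajectoryEvents(a), trajectoryEvents(b))
})

test_that("pure growth is a Poisson count of appended empty sites", {
  kin <- MotorKinetics(0, 0, 0, 1, 1, c_total = 1)  # no motors
  # 2.92 sites/s is the 1.4 um/min growth speed at 8 nm per site
  lens <- vapply(1:20, function(s) {
    tr <- simulateGrowingLattice(kin, growth_rate = 2.92, initial_n = 10,
                                 duration = 100, seed = 300 + s)
    length(tr@final_state)
  }, numeric(1))
  expect_true(all(lens >= 10))
  # mean of 20 Poisson(292) counts: SE = sqrt(292/20) ~ 3.8
  expect_lt(abs(mean(lens - 10) - 292), 4 * sqrt(292 / 20))
  tr <- simulateGrowingLattice(kin, growth_rate = 2.92, initial_n = 10,
                               duration = 100, seed = 1)
  expect_true(all(trajectoryEvents(tr)$event_type == "grow"))
  expect_equal(sum(tr@final_state), 0)
})

test_that("growing wt-like lattices keep a flat shaft", {
  # ensemble mean over seeds: interior shaft slope consistent with zero
  kin <- MotorKinetics(0.04, 0, 0, 13.125, 2.8, c_total = 35)
  occ_sum <- NULL
  n_rep <- 8
  for (s in seq_len(n_rep)) {
    tr <- simulateGrowingLattice(kin, growth_rate = 1, initial_n = 60,
                                 duration = 400, seed = 500 + s,
                                 reservoir = ReservoirSpec(closed = FALSE))
    occ <- occupancy(timeAveragedOccupancy(tr, burn_in = 100))[1:60]
    occ_sum <- if (is.null(occ_sum)) occ else occ_sum + occ
  }
  shaft <- (occ_sum / n_rep)[5:50]
  fit <- lm(shaft ~ seq_along(shaft))
  slope_t <- summary(fit)$coefficients[2, 3]
  expect_lt(abs(slope_t), 3)  # slope not significantly different from 0
})

test_that("event tables round-trip through CSV", {
  kin <- kin_small()
  tr <- simulateGillespie(kin, LatticeSpec(4), ReservoirSpec(closed = FALSE),
                          duration = 20, seed = 5)
  path <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(tr, path)
  back <- read.csv(path)
  ev <- trajectoryEvents(tr)
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$event_type, as.character(ev$event_type))
  expect_equal(back$site_index, ev$site_index)
})
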