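.EVENT_LABELS <- c("entry", "land", "detach", "step", "exit", "grow")

.make_trajectory <- function(raw, n_init, duration, seed, reservoir) {
  events <- data.frame(
    time_s = raw$time,
    event_type = factor(.EVENT_LABELS[raw$type], levels = .EVENT_LABELS),
    site_index = raw$site,
    n_sites = raw$n_sites)
  new("LatticeTrajectory", events = events, n_init = as.integer(n_init),
      duration = as.numeric(duration),
      final_state = as.integer(raw$final_state),
      rng_seed = as.integer(seed), quiescent = isTRUE(raw$quiescent),
      reservoir = list(free_copies = raw$free_copies,
                       total_copies = raw$total_copies,
                       closed = reservoir@closed))
}

#' Exact stochastic simulation (Gillespie) of the lattice traffic model
#'
#' Simulates the continuous-time Markov chain of the minus-end-loading
#' exclusion process. With a closed reservoir the motor pool holds an
#' integer number of copies (`round(c_total * volume * N_A)`); every
#' binding decrements and every unbinding increments the free pool, so
#' `bound + free` copies are conserved exactly. Identical seed and inputs
#' reproduce the identical event sequence.
#'
#' @param kinetics a [MotorKinetics].
#' @param lattice a [LatticeSpec].
#' @param reservoir a [ReservoirSpec]; the stochastic simulator supports
#'   `n_filaments = 1` only (the mean-field solver handles shared pools).
#' @param duration simulated time (s), > 0.
#' @param seed integer seed.
#' @param max_events guard on the event count.
#' @return A [LatticeTrajectory]. If the total propensity reaches zero with
#'   no bound motors (no entry pathway), the trajectory returns early with
#'   the `quiescent` flag set.
#' @export
simulateGillespie <- function(kinetics, lattice,
                              reservoir = ReservoirSpec(), duration,
                              seed, max_events = 2e7) {
  simulateGrowingLattice(kinetics, growth_rate = 0,
                         initial_n = lattice@n_sites, duration = duration,
                         seed = seed, reservoir = reservoir,
                         site_length = lattice@site_length,
                         max_events = max_events)
}

#' Stochastic simulation on a growing lattice
#'
#' As [simulateGillespie()], but new empty plus-end sites are appended as a
#' Poisson process at `growth_rate`, interleaved exactly with the motor
#' events (growth is one more reaction channel of the same Markov chain).
#' The site that was the plus end becomes an interior site when the lattice
#' grows. `growth_rate = 0` reduces event-for-event to the static
#' simulation.
#'
#' @param kinetics a [MotorKinetics].
#' @param growth_rate plus-end site addition rate (sites/s), >= 0.
#'   2.92 sites/s corresponds to a 1.4 um/min growth speed at 8 nm/site.
#' @param initial_n initial number of sites.
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param reservoir a [ReservoirSpec] (`n_filaments = 1`).
#' @param site_length nm per site.
#' @param max_events guard on the event count.
#' @return A [LatticeTrajectory]; the `n_sites` column of its event table
#'   records the lattice length after each event.
#' @export
simulateGrowingLattice <- function(kinetics, growth_rate, initial_n,
                                   duration, seed,
                                   reservoir = ReservoirSpec(),
                                   site_length = 8, max_events = 2e7) {
  stopifnot(is(kinetics, "MotorKinetics"), is(reservoir, "ReservoirSpec"))
  if (duration <= 0) stop("duration must be > 0")
  if (growth_rate < 0) stop("growth_rate must be >= 0")
  if (reservoir@n_filaments != 1L)
    stop("the stochastic simulator supports n_filaments = 1 only")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  raw <- .gillespie_cpp(as.integer(initial_n), kinetics@k_in,
                        kinetics@k_on, kinetics@k_off, kinetics@k_step,
                        kinetics@k_out, kinetics@c_total,
                        reservoir@volume * COPIES_PER_NM_FL,
                        reservoir@closed, growth_rate, duration, max_events)
  .make_trajectory(raw, initial_n, duration, seed, reservoir)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Time-averaged site occupancy of a trajectory
#'
#' Computes, for each site, the time-weighted mean of its occupancy
#' indicator between `burn_in` and the trajectory end. For growing
#' lattices, sites are indexed from the minus end and a site's indicator is
#' zero before the site exists.
#'
#' @param trajectory a [LatticeTrajectory].
#' @param burn_in time (s) discarded from the start; must be smaller than
#'   the trajectory duration.
#' @param site_length nm per site (for the returned site positions).
#' @return An [OccupancyProfile]; its `flux` slot holds the empirical
#'   plus-end exit rate (exit events per second after burn-in).
#' @export
timeAveragedOccupancy <- function(trajectory, burn_in = 0, site_length = 8) {
  stopifnot(is(trajectory, "LatticeTrajectory"))
  if (burn_in >= trajectory@duration)
    stop("burn_in must be smaller than the trajectory duration")
  ev <- trajectory@events
  occ <- .time_average_cpp(ev$time_s, as.integer(ev$event_type),
                           ev$site_index, trajectory@n_init,
                           trajectory@duration, burn_in)
  n_exit <- sum(ev$event_type == "exit" & ev$time_s > burn_in)
  OccupancyProfile(occ, (seq_along(occ) - 0.5) * site_length,
                   flux = n_exit / (trajectory@duration - burn_in))
}

#' Reconstruct per-event occupancy states
#'
#' Replays the event list and returns the occupancy bit-vector after each
#' event (a list of integer vectors). Intended for small trajectories;
#' memory grows as events x sites.
#'
#' @param trajectory a [LatticeTrajectory].
#' @return list of 0/1 integer vectors, one per event.
#' @export
trajectoryStates <- function(trajectory) {
  ev <- trajectory@events
  n <- trajectory@n_init
  n_final <- n + sum(ev$event_type == "grow")
  occ <- integer(n_final)
  out <- vector("list", nrow(ev))
  for (e in seq_len(nrow(ev))) {
    s <- ev$site_index[e]
    switch(as.character(ev$event_type[e]),
           entry = { occ[1L] <- 1L },
           land = { occ[s] <- 1L },
           detach = { occ[s] <- 0L },
           step = { occ[s] <- 0L; occ[s + 1L] <- 1L },
           exit = { occ[s] <- 0L },
           grow = { n <- n + 1L })
    out[[e]] <- occ[seq_len(n)]
  }
  out
}

#' Write a trajectory as a tidy event table
#'
#' @param trajectory a [LatticeTrajectory].
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
writeTrajectoryCSV <- function(trajectory, path) {
  ev <- trajectory@events
  out <- data.frame(time_s = ev$time_s,
                    event_type = as.character(ev$event_type),
                    site_index = ev$site_index, n_sites = ev$n_sites)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
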