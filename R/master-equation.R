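#' Exact stationary occupancy from the lattice master equation
#'
#' Enumerates the full `2^N` configuration space of the lattice model at a
#' fixed free motor concentration, builds the continuous-time Markov chain
#' generator, solves for the stationary distribution, and returns the exact
#' marginal occupancy of each site. This is the small-system oracle against
#' which the mean-field solver and the Gillespie simulator are validated.
#'
#' @param kinetics a [MotorKinetics] (the `c_total` slot is ignored here;
#'   the chain runs at the clamped `free_concentration`).
#' @param lattice a [LatticeSpec] with `n_sites <= 12`.
#' @param free_concentration free motor concentration in nM.
#' @return An [OccupancyProfile] of exact marginals, with flux
#'   `k_out * rho_N`.
#' @examples
#' kin <- MotorKinetics(1, 0, 0, 1, 1, c_total = 1)
#' occupancy(solveMasterEquation(kin, LatticeSpec(2), 1))  # c(0.6, 0.4)
#' @export
solveMasterEquation <- function(kinetics, lattice, free_concentration) {
  stopifnot(is(kinetics, "MotorKinetics"), is(lattice, "LatticeSpec"))
  n <- lattice@n_sites
  if (n > 12L)
    stop("solveMasterEquation enumerates 2^N states and refuses n_sites > 12")
  if (free_concentration < 0) stop("free_concentration must be >= 0")
  r_in <- kinetics@k_in * free_concentration
  a <- kinetics@k_on * free_concentration
  k_off <- kinetics@k_off; k_step <- kinetics@k_step; k_out <- kinetics@k_out
  pos <- (seq_len(n) - 0.5) * lattice@site_length

  if (r_in == 0 && a == 0) {
    # no entry pathway: the empty configuration is absorbing; its point mass
    # is the defined stationary result
    return(OccupancyProfile(rep(0, n), pos, flux = 0,
                            c_free = free_concentration))
  }

  n_states <- 2L^n
  occ_bit <- function(state, i) bitwAnd(bitwShiftR(state, i - 1L), 1L) == 1L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    ii[[length(ii) + 1L]] <<- from; jj[[length(jj) + 1L]] <<- to
    xx[[length(xx) + 1L]] <<- rate
  }
  for (s in 0:(n_states - 1L)) {
    occ <- vapply(seq_len(n), function(i) occ_bit(s, i), logical(1))
    # entry at the minus end (loading + lattice landing share site 1)
    if (!occ[1] && (r_in + a) > 0) add(s, bitwOr(s, 1L), r_in + a)
    if (n >= 2) {
      for (i in 2:n) if (!occ[i] && a > 0)
        add(s, bitwOr(s, bitwShiftL(1L, i - 1L)), a)
      for (i in 1:(n - 1)) if (occ[i] && k_off > 0)
        add(s, bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))), k_off)
      for (i in 1:(n - 1)) if (occ[i] && !occ[i + 1] && k_step > 0)
        add(s, bitwOr(bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))),
                      bitwShiftL(1L, i)), k_step)
    }
    if (occ[n] && k_out > 0)
      add(s, bitwAnd(s, bitwNot(bitwShiftL(1L, n - 1L))), k_out)
  }
  Q <- Matrix::sparseMatrix(i = unlist(ii) + 1L, j = unlist(jj) + 1L,
                            x = unlist(xx), dims = c(n_states, n_states))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # stationary distribution: pi^T Q = 0, sum(pi) = 1
  A <- Matrix::t(Q)
  A[n_states, ] <- 1
  b <- c(rep(0, n_states - 1L), 1)
  pi_vec <- as.numeric(Matrix::solve(A, b))
  pi_vec <- pmax(pi_vec, 0)
  pi_vec <- pi_vec / sum(pi_vec)
  if (abs(sum(pi_vec) - 1) > 1e-12)
    stop("stationary distribution failed to normalize")
  states <- 0:(n_states - 1L)
  rho <- vapply(seq_len(n), function(i) {
    sum(pi_vec[bitwAnd(bitwShiftR(states, i - 1L), 1L) == 1L])
  }, numeric(1))
  OccupancyProfile(rho, pos, flux = k_out * rho[n],
                   c_free = free_concentration)
}
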