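# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths: plain R fixed-point iteration for the
# mean-field equations, dense linear algebra for small master equations.

# mean-field balance residuals, written out directly from the model rules
mf_residual_R <- function(rho, r_in, a, k_off, k_step, k_out) {
  n <- length(rho)
  if (n == 1) return((r_in + a) * (1 - rho) - k_out * rho)
  F <- numeric(n)
  F[1] <- (r_in + a) * (1 - rho[1]) - k_off * rho[1] -
    k_step * rho[1] * (1 - rho[2])
  if (n > 2) {
    i <- 2:(n - 1)
    F[i] <- a * (1 - rho[i]) + k_step * rho[i - 1] * (1 - rho[i]) -
      k_off * rho[i] - k_step * rho[i] * (1 - rho[i + 1])
  }
  F[n] <- a * (1 - rho[n]) + k_step * rho[n - 1] * (1 - rho[n]) -
    k_out * rho[n]
  F
}

# slow but independent: damped explicit fixed-point iteration
mf_fixed_point_R <- function(n, r_in, a, k_off, k_step, k_out,
                             tol = 1e-12, max_iter = 5e6) {
  rho <- rep(0.05, n)
  dt <- 0.4 / (r_in + a + k_off + k_step + k_out)
  for (it in seq_len(max_iter)) {
    F <- mf_residual_R(rho, r_in, a, k_off, k_step, k_out)
    rho <- pmin(1, pmax(0, rho + dt * F))
    if (it %% 200 == 0 && max(abs(F)) < tol) break
  }
  rho
}

# dense-matrix stationary distribution of the small-lattice master equation
master_dense_R <- function(n, r_in, a, k_off, k_step, k_out) {
  n_states <- 2^n
  occ <- function(s, i) bitwAnd(bitwShiftR(s, i - 1L), 1L) == 1L
  Q <- matrix(0, n_states, n_states)
  for (s in 0:(n_states - 1)) {
    o <- vapply(1:n, function(i) occ(s, i), logical(1))
    if (!o[1]) Q[s + 1, bitwOr(s, 1L) + 1] <-
      Q[s + 1, bitwOr(s, 1L) + 1] + r_in + a
    if (n >= 2) {
      for (i in 2:n) if (!o[i])
        Q[s + 1, bitwOr(s, bitwShiftL(1L, i - 1L)) + 1] <-
          Q[s + 1, bitwOr(s, bitwShiftL(1L, i - 1L)) + 1] + a
      for (i in 1:(n - 1)) {
        if (o[i]) Q[s + 1, bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))) + 1] <-
          Q[s + 1, bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))) + 1] + k_off
        if (o[i] && !o[i + 1]) {
          to <- bitwOr(bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L))),
                       bitwShiftL(1L, i))
          Q[s + 1, to + 1] <- Q[s + 1, to + 1] + k_step
        }
      }
    }
    if (o[n]) Q[s + 1, bitwAnd(s, bitwNot(bitwShiftL(1L, n - 1L))) + 1] <-
      Q[s + 1, bitwAnd(s, bitwNot(bitwShiftL(1L, n - 1L))) + 1] + k_out
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- t(Q); A[n_states, ] <- 1
  p <- solve(A, c(rep(0, n_states - 1), 1))
  vapply(1:n, function(i) {
    sum(p[vapply(0:(n_states - 1), function(s) occ(s, i), logical(1))])
  }, numeric(1))
}

# standard kinetics used in small-system tests
kin_small <- function() MotorKinetics(k_in = 0.5, k_on = 0.2, k_off = 0.1,
                                      k_step = 2, k_out = 1, c_total = 1)

# a quick low-noise profile dataset for fitting tests
quick_truth <- function(preset = "wt", cells = 50L, seed = 7L) {
  tr <- truthConfig(preset, seed = seed)
  tr$cells_per_bin <- as.integer(cells)
  tr
}
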