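#' Classify a parameter point against the flat-profile theorem
#'
#' The steady-state shaft occupancy of the minus-end-loading traffic model
#' is flat only in special regimes: when there is no entry pathway at all
#' (`no-lattice-motors`), when the motors cannot step
#' (`zero-speed`: Langmuir equilibrium everywhere), or when all motors are
#' recruited exclusively at the minus-end and never detach on the lattice
#' (`minus-end-only`: `k_on = 0`, `k_off = 0`, with `k_in > 0` and
#' `k_step > 0`). Every other parameter point is `non-flat` (a nonzero
#' `k_on` makes occupancy increase towards the plus end; a nonzero `k_off`
#' makes it decay away from the minus end).
#'
#' @param kinetics a [MotorKinetics].
#' @param c_free free concentration used for the predicted bulk density
#'   (defaults to `c_total`).
#' @return A [FlatnessVerdict]. When flat, `bulk_density` is the predicted
#'   uniform interior occupancy: `k_in * c_free / k_step` clipped to the
#'   low-density branch (at most 1/2) for `minus-end-only`, the Langmuir
#'   ratio for `zero-speed`, and 0 for `no-lattice-motors`.
#' @export
classifyFlatProfile <- function(kinetics, c_free = kinetics@c_total) {
  stopifnot(is(kinetics, "MotorKinetics"))
  k <- kineticRates(kinetics)
  no_entry <- (k[["k_in"]] == 0 && k[["k_on"]] == 0) || c_free == 0
  if (no_entry) {
    return(new("FlatnessVerdict", is_flat = TRUE,
               regime_label = "no-lattice-motors", bulk_density = 0))
  }
  if (k[["k_step"]] == 0 && k[["k_on"]] > 0) {
    a <- k[["k_on"]] * c_free
    return(new("FlatnessVerdict", is_flat = TRUE,
               regime_label = "zero-speed",
               bulk_density = a / (a + k[["k_off"]])))
  }
  if (k[["k_on"]] == 0 && k[["k_off"]] == 0 && k[["k_in"]] > 0 &&
      k[["k_step"]] > 0) {
    rho <- min(k[["k_in"]] * c_free / k[["k_step"]], 0.5)
    return(new("FlatnessVerdict", is_flat = TRUE,
               regime_label = "minus-end-only", bulk_density = rho))
  }
  new("FlatnessVerdict", is_flat = FALSE, regime_label = "non-flat",
      bulk_density = NA_real_)
}
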