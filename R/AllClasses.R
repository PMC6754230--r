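#' @import methods
#' @importFrom stats approx coef density dnorm lm mad median optim optimize pnorm
#'   quantile rbinom rlnorm rnorm runif sd setNames rexp rpois var
#' @importFrom utils read.csv write.csv head
#' @useDynLib kip2traffic, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Avogadro-derived conversion: copies of a species at 1 nM in 1 fL.
# 1e-9 mol/L * 1e-15 L * 6.02214076e23 /mol = 0.602214076 copies.
COPIES_PER_NM_FL <- 0.602214076

#' Kinetic rate constants of the minus-end-loading motor traffic model
#'
#' Bundles the five rate constants of the exclusion-process transport model
#' together with the total motor concentration. A free motor loads onto the
#' minus-end site at rate `k_in * c_free` (nM^-1 s^-1 times free
#' concentration), lands on any free lattice site at `k_on * c_free` per
#' site, detaches from the lattice at `k_off` (s^-1), advances towards the
#' plus end at `k_step` (s^-1) when the next site is free, and detaches from
#' the plus-end site at the dedicated rate `k_out` (s^-1).
#'
#' @slot k_in numeric(1), minus-end loading rate constant (nM^-1 s^-1).
#' @slot k_on numeric(1), per-site lattice landing rate constant (nM^-1 s^-1).
#' @slot k_off numeric(1), lattice detachment rate (s^-1); does not act on
#'   the plus-end site, which uses `k_out` instead.
#' @slot k_step numeric(1), stepping rate (s^-1).
#' @slot k_out numeric(1), plus-end detachment rate (s^-1).
#' @slot c_total numeric(1), total motor concentration (nM).
#' @exportClass MotorKinetics
setClass("MotorKinetics",
  representation(k_in = "numeric", k_on = "numeric", k_off = "numeric",
                 k_step = "numeric", k_out = "numeric", c_total = "numeric"),
  validity = function(object) {
    v <- c(k_in = object@k_in, k_on = object@k_on, k_off = object@k_off,
           k_step = object@k_step, k_out = object@k_out,
           c_total = object@c_total)
    if (any(lengths(list(object@k_in, object@k_on, object@k_off,
                         object@k_step, object@k_out, object@c_total)) != 1))
      return("all rate slots must be length 1")
    if (any(!is.finite(v))) return("all rates must be finite")
    if (any(v < 0)) return("all rates must be >= 0")
    if ((object@k_in > 0 || object@k_on > 0) && object@c_total <= 0)
      return("c_total must be > 0 when a binding rate constant is > 0")
    TRUE
  })

#' @param k_in,k_on,k_off,k_step,k_out,c_total see slot descriptions.
#' @return A `MotorKinetics` object.
#' @rdname MotorKinetics-class
#' @export
MotorKinetics <- function(k_in, k_on, k_off, k_step, k_out, c_total) {
  new("MotorKinetics", k_in = as.numeric(k_in), k_on = as.numeric(k_on),
      k_off = as.numeric(k_off), k_step = as.numeric(k_step),
      k_out = as.numeric(k_out), c_total = as.numeric(c_total))
}

#' Discretization of a microtubule into lattice sites
#'
#' @slot n_sites integer(1), number of sites (>= 1), minus end first.
#' @slot site_length numeric(1), physical length per site in nm
#'   (default 8 nm, one tubulin dimer per site).
#' @exportClass LatticeSpec
setClass("LatticeSpec",
  representation(n_sites = "integer", site_length = "numeric"),
  validity = function(object) {
    if (length(object@n_sites) != 1 || object@n_sites < 1L)
      return("n_sites must be a single integer >= 1")
    if (length(object@site_length) != 1 || !is.finite(object@site_length) ||
        object@site_length <= 0)
      return("site_length must be a single positive number")
    TRUE
  })

#' @param n_sites,site_length see slot descriptions.
#' @rdname LatticeSpec-class
#' @export
LatticeSpec <- function(n_sites, site_length = 8) {
  new("LatticeSpec", n_sites = as.integer(n_sites),
      site_length = as.numeric(site_length))
}

#' Cytoplasmic motor reservoir shared by the lattices
#'
#' In closed mode the free concentration is depleted by lattice-bound
#' copies: `c_free = c_total - n_filaments * bound / (volume * N_A)`.
#' In clamped mode `c_free` equals `c_total` regardless of binding.
#'
#' @slot volume numeric(1), cytoplasmic volume in fL.
#' @slot n_filaments integer(1), number of lattices sharing the pool.
#' @slot closed logical(1), finite pool (TRUE) vs clamped concentration.
#' @exportClass ReservoirSpec
setClass("ReservoirSpec",
  representation(volume = "numeric", n_filaments = "integer",
                 closed = "logical"),
  validity = function(object) {
    if (!is.finite(object@volume) || object@volume <= 0)
      return("volume must be > 0")
    if (object@n_filaments < 1L) return("n_filaments must be >= 1")
    TRUE
  })

#' @param volume,n_filaments,closed see slot descriptions.
#' @rdname ReservoirSpec-class
#' @export
ReservoirSpec <- function(volume = 40, n_filaments = 1, closed = TRUE) {
  new("ReservoirSpec", volume = as.numeric(volume),
      n_filaments = as.integer(n_filaments), closed = as.logical(closed))
}

#' Per-site expected motor occupancy on a lattice
#'
#' @slot occupancy numeric, expected occupancy per site in `[0, 1]`,
#'   minus end first.
#' @slot site_positions numeric, site-center distance from the minus end (nm).
#' @slot flux numeric(1), steady-state motor current onto the plus end (s^-1).
#' @slot c_free numeric(1), self-consistent free motor concentration (nM).
#' @exportClass OccupancyProfile
setClass("OccupancyProfile",
  representation(occupancy = "numeric", site_positions = "numeric",
                 flux = "numeric", c_free = "numeric"),
  validity = function(object) {
    if (length(object@occupancy) != length(object@site_positions))
      return("occupancy and site_positions must have equal length")
    if (any(object@occupancy < -1e-12 | object@occupancy > 1 + 1e-12))
      return("occupancy values must lie in [0, 1]")
    if (length(object@flux) == 1 && is.finite(object@flux) &&
        object@flux < 0)
      return("flux must be >= 0")
    TRUE
  })

OccupancyProfile <- function(occupancy, site_positions, flux,
                             c_free = NA_real_) {
  new("OccupancyProfile", occupancy = pmin(1, pmax(0, occupancy)),
      site_positions = site_positions, flux = flux,
      c_free = as.numeric(c_free))
}

#' Event record of a stochastic lattice trajectory
#'
#' Stores the seeded Gillespie event sequence (times, event types, sites,
#' lattice length after each event) plus the initial and final occupancy
#' state. Full per-event occupancy states are reconstructed on demand by
#' [trajectoryStates()]; time averages by [timeAveragedOccupancy()].
#'
#' Event types: `entry` (minus-end loading), `land` (lattice landing),
#' `detach` (lattice detachment), `step`, `exit` (plus-end detachment),
#' `grow` (a new empty plus-end site).
#'
#' @slot events data.frame with columns `time_s`, `event_type`,
#'   `site_index`, `n_sites`.
#' @slot n_init integer(1), initial lattice length.
#' @slot duration numeric(1), simulated time span (s).
#' @slot final_state integer vector of site occupancies at `duration`.
#' @slot rng_seed integer(1), seed the trajectory was generated with.
#' @slot quiescent logical(1), TRUE when simulation ended early because the
#'   total propensity dropped to zero.
#' @slot reservoir list with `free_copies`, `total_copies`, `closed`.
#' @exportClass LatticeTrajectory
setClass("LatticeTrajectory",
  representation(events = "data.frame", n_init = "integer",
                 duration = "numeric", final_state = "integer",
                 rng_seed = "integer", quiescent = "logical",
                 reservoir = "list"),
  validity = function(object) {
    tm <- object@events$time_s
    if (length(tm) > 1 && any(diff(tm) < 0))
      return("event times must be non-decreasing")
    if (any(object@final_state < 0 | object@final_state > 1))
      return("final state must be a 0/1 occupancy vector")
    TRUE
  })

#' Classification of a parameter point against the flat-profile theorem
#'
#' @slot is_flat logical(1), whether the predicted steady-state shaft
#'   occupancy is uniform.
#' @slot regime_label one of `"no-lattice-motors"`, `"zero-speed"`,
#'   `"minus-end-only"`, `"non-flat"`.
#' @slot bulk_density numeric(1), predicted uniform interior occupancy when
#'   flat, `NA` otherwise.
#' @exportClass FlatnessVerdict
setClass("FlatnessVerdict",
  representation(is_flat = "logical", regime_label = "character",
                 bulk_density = "numeric"),
  validity = function(object) {
    if (!object@regime_label %in%
        c("no-lattice-motors", "zero-speed", "minus-end-only", "non-flat"))
      return("unknown regime label")
    if (object@is_flat) {
      if (!is.finite(object@bulk_density) || object@bulk_density < 0 ||
          object@bulk_density > 1)
        return("bulk_density must be in [0, 1] when is_flat")
    } else if (!is.na(object@bulk_density)) {
      return("bulk_density is defined only when is_flat")
    }
    TRUE
  })

#' Optical model mapping bound motors to fluorescence
#'
#' @slot psf_sigma numeric(1), Gaussian blur standard deviation (nm).
#' @slot pixel_size numeric(1), nm per pixel (default 133.35, half the
#'   266.7 nm two-pixel bin).
#' @slot scale numeric(1), fluorescence per bound motor (a.u.).
#' @slot background numeric(1), additive offset (a.u.).
#' @exportClass OpticalModel
setClass("OpticalModel",
  representation(psf_sigma = "numeric", pixel_size = "numeric",
                 scale = "numeric", background = "numeric"),
  validity = function(object) {
    if (object@psf_sigma < 0) return("psf_sigma must be >= 0")
    if (object@pixel_size <= 0) return("pixel_size must be > 0")
    if (object@scale < 0) return("scale must be >= 0")
    TRUE
  })

#' @param psf_sigma,pixel_size,scale,background see slot descriptions.
#' @rdname OpticalModel-class
#' @export
OpticalModel <- function(psf_sigma = 135, pixel_size = 133.35, scale = 1,
                         background = 0) {
  new("OpticalModel", psf_sigma = as.numeric(psf_sigma),
      pixel_size = as.numeric(pixel_size), scale = as.numeric(scale),
      background = as.numeric(background))
}

#' Likelihood samples over kinetic and optical parameters
#'
#' @slot draws matrix, one row per retained draw, one column per parameter.
#' @slot log_likelihoods numeric, log-likelihood of each draw.
#' @slot sampler_seed integer(1).
#' @slot ranges matrix with columns `lower`, `upper` (sampled box, natural
#'   scale; sampling itself runs in log10 space).
#' @slot rhat numeric, split-chain convergence statistic per parameter.
#' @slot converged logical(1), TRUE when `max(rhat) <= 1.05`.
#' @exportClass ParameterSamples
setClass("ParameterSamples",
  representation(draws = "matrix", log_likelihoods = "numeric",
                 sampler_seed = "integer", ranges = "matrix",
                 rhat = "numeric", converged = "logical"),
  validity = function(object) {
    if (nrow(object@draws) != length(object@log_likelihoods))
      return("one log-likelihood per draw required")
    if (is.null(colnames(object@draws)))
      return("draws must have parameter names")
    TRUE
  })

#' @rdname ParameterSamples-class
#' @param object,x a `ParameterSamples`.
#' @export
setGeneric("nDraws", function(object) standardGeneric("nDraws"))
#' @rdname ParameterSamples-class
#' @export
setMethod("nDraws", "ParameterSamples", function(object) nrow(object@draws))

#' @rdname ParameterSamples-class
#' @export
setGeneric("parameterDraws", function(object) standardGeneric("parameterDraws"))
#' @rdname ParameterSamples-class
#' @export
setMethod("parameterDraws", "ParameterSamples", function(object) object@draws)

#' @rdname MotorKinetics-class
#' @param object,x the object.
#' @export
setGeneric("kineticRates", function(object) standardGeneric("kineticRates"))
#' @rdname MotorKinetics-class
#' @export
setMethod("kineticRates", "MotorKinetics", function(object) {
  c(k_in = object@k_in, k_on = object@k_on, k_off = object@k_off,
    k_step = object@k_step, k_out = object@k_out, c_total = object@c_total)
})

#' @rdname OccupancyProfile-class
#' @param object,x an `OccupancyProfile`.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname OccupancyProfile-class
#' @export
setMethod("occupancy", "OccupancyProfile", function(object) object@occupancy)

#' @rdname OccupancyProfile-class
#' @export
setGeneric("sitePositions", function(object) standardGeneric("sitePositions"))
#' @rdname OccupancyProfile-class
#' @export
setMethod("sitePositions", "OccupancyProfile",
          function(object) object@site_positions)

#' @rdname OccupancyProfile-class
#' @export
setGeneric("plusEndFlux", function(object) standardGeneric("plusEndFlux"))
#' @rdname OccupancyProfile-class
#' @export
setMethod("plusEndFlux", "OccupancyProfile", function(object) object@flux)

#' @rdname LatticeTrajectory-class
#' @param object,x a `LatticeTrajectory`.
#' @export
setGeneric("trajectoryEvents",
           function(object) standardGeneric("trajectoryEvents"))
#' @rdname LatticeTrajectory-class
#' @export
setMethod("trajectoryEvents", "LatticeTrajectory",
          function(object) object@events)

setMethod("show", "MotorKinetics", function(object) {
  r <- kineticRates(object)
  cat("MotorKinetics: k_in =", r["k_in"], "/nM/s, k_on =", r["k_on"],
      "/nM/s,\n  k_off =", r["k_off"], "/s, k_step =", r["k_step"],
      "/s, k_out =", r["k_out"], "/s, c_total =", r["c_total"], "nM\n")
})

setMethod("show", "OccupancyProfile", function(object) {
  n <- length(object@occupancy)
  cat("OccupancyProfile over", n, "sites; interior mean",
      signif(mean(object@occupancy), 4), "; plus-end",
      signif(object@occupancy[n], 4), "; flux", signif(object@flux, 4),
      "/s\n")
})

setMethod("show", "LatticeTrajectory", function(object) {
  cat("LatticeTrajectory:", nrow(object@events), "events over",
      object@duration, "s;", object@n_init, "->",
      length(object@final_state), "sites",
      if (object@quiescent) "(quiescent)" else "", "\n")
})

setMethod("show", "FlatnessVerdict", function(object) {
  cat("FlatnessVerdict:", object@regime_label,
      if (object@is_flat) sprintf("(flat, bulk density %.4g)",
                                  object@bulk_density) else "(not flat)",
      "\n")
})

setMethod("show", "ParameterSamples", function(object) {
  cat("ParameterSamples:", nrow(object@draws), "draws over",
      ncol(object@draws), "parameters (",
      paste(colnames(object@draws), collapse = ", "), ")\n  max split-Rhat",
      signif(max(object@rhat), 4),
      if (object@converged) "[converged]" else "[NOT converged]", "\n")
})
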