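#' Render an occupancy profile as a predicted fluorescence line scan
#'
#' Each bound motor contributes a unit-mass Gaussian of standard deviation
#' `psf_sigma`, integrated over each pixel; intensities are
#' `background + scale * sum_i rho_i * G(pixel | site_i)`. Summed over a
#' window that covers the whole blurred lattice, the
#' background-subtracted intensity equals `scale * sum(rho)` (mass
#' conservation). `psf_sigma = 0` puts each site's mass entirely into the
#' pixel containing it.
#'
#' @param occupancy an [OccupancyProfile] (site positions in nm from the
#'   spindle-pole-aligned origin).
#' @param optical an [OpticalModel].
#' @param window numeric(2), nm range to render; must cover the lattice
#'   (silent truncation is refused).
#' @return data.frame of class `PredictedProfile` with columns
#'   `position_nm` (pixel centers, uniform spacing = `pixel_size`) and
#'   `intensity_au`; attribute `mt_length` holds the lattice length in nm.
#' @export
renderProfile <- function(occupancy, optical, window) {
  stopifnot(is(occupancy, "OccupancyProfile"), is(optical, "OpticalModel"))
  pos <- sitePositions(occupancy)
  half_site <- if (length(pos) > 1) diff(pos[1:2]) / 2 else pos[1]
  lat_lo <- min(pos) - half_site
  lat_hi <- max(pos) + half_site
  if (window[1] > lat_lo + 1e-9 || window[2] < lat_hi - 1e-9)
    stop("render window must cover the whole lattice [",
         signif(lat_lo, 6), ", ", signif(lat_hi, 6), "] nm")
  centers <- .pixel_centers(window, optical@pixel_size)
  intensity <- .render_at(occupancy(occupancy), pos, optical, centers)
  out <- data.frame(position_nm = centers, intensity_au = intensity)
  attr(out, "mt_length") <- lat_hi - lat_lo
  class(out) <- c("PredictedProfile", "data.frame")
  out
}

.pixel_centers <- function(window, pixel_size) {
  n_pix <- ceiling((window[2] - window[1]) / pixel_size - 1e-9)
  window[1] + (seq_len(n_pix) - 0.5) * pixel_size
}

# pixel-integrated Gaussian mass at given pixel centers
.render_at <- function(rho, site_pos, optical, centers) {
  half <- optical@pixel_size / 2
  sig <- optical@psf_sigma
  if (length(rho) == 0) return(rep(optical@background, length(centers)))
  if (sig <= 0) {
    mass <- vapply(centers, function(x) {
      sum(rho[site_pos > x - half & site_pos <= x + half])
    }, numeric(1))
  } else {
    lo <- outer(centers - half, site_pos, "-") / sig
    hi <- outer(centers + half, site_pos, "-") / sig
    mass <- as.numeric((pnorm(hi) - pnorm(lo)) %*% rho)
  }
  optical@background + optical@scale * mass
}

#' Predict binned fluorescence profiles from kinetics
#'
#' One predicted profile per microtubule-length bin, each computed at the
#' bin's midpoint length rounded to whole sites and rendered through the
#' optical model. Deterministic.
#'
#' @param kinetics a [MotorKinetics].
#' @param optical an [OpticalModel].
#' @param length_bins list (or 2-column matrix) of non-overlapping,
#'   increasing `(lo, hi)` nm ranges.
#' @param lattice_defaults a [LatticeSpec]; only `site_length` is used
#'   (the per-bin site count comes from the bin midpoint).
#' @param reservoir a [ReservoirSpec].
#' @param window_margin nm rendered beyond the lattice on each side
#'   (default 4 pixels, covering the blur tails).
#' @param positions optional list of pixel-center vectors, one per bin, at
#'   which to evaluate instead of the default window (used when matching a
#'   measured grid).
#' @return list of `PredictedProfile` data.frames, one per bin, each with
#'   attributes `bin_lo_nm`, `bin_hi_nm`, `n_sites`.
#' @export
predictBinnedProfiles <- function(kinetics, optical, length_bins,
                                  lattice_defaults = LatticeSpec(1),
                                  reservoir = ReservoirSpec(),
                                  window_margin = 4 * optical@pixel_size,
                                  positions = NULL) {
  bins <- .as_bin_list(length_bins)
  site_len <- lattice_defaults@site_length
  out <- vector("list", length(bins))
  for (b in seq_along(bins)) {
    lo <- bins[[b]][1]; hi <- bins[[b]][2]
    mid <- (lo + hi) / 2
    n <- round(mid / site_len)
    if (n < 1) stop("bin midpoint ", mid, " nm is shorter than one site")
    prof <- solveMeanfieldSteadyState(
      kinetics, LatticeSpec(n, site_len), reservoir)
    if (is.null(positions)) {
      pp <- renderProfile(prof, optical,
                          window = c(-window_margin,
                                     n * site_len + window_margin))
    } else {
      centers <- positions[[b]]
      ints <- .render_at(occupancy(prof), sitePositions(prof), optical,
                         centers)
      pp <- data.frame(position_nm = centers, intensity_au = ints)
      class(pp) <- c("PredictedProfile", "data.frame")
    }
    attr(pp, "bin_lo_nm") <- lo
    attr(pp, "bin_hi_nm") <- hi
    attr(pp, "n_sites") <- n
    out[[b]] <- pp
  }
  out
}

.as_bin_list <- function(length_bins) {
  if (is.matrix(length_bins))
    length_bins <- lapply(seq_len(nrow(length_bins)),
                          function(i) length_bins[i, ])
  los <- vapply(length_bins, `[`, numeric(1), 1)
  his <- vapply(length_bins, `[`, numeric(1), 2)
  if (any(his <= los)) stop("each bin must have hi > lo")
  if (length(los) > 1 && any(los[-1] < his[-length(his)] - 1e-9))
    stop("length bins must be non-overlapping and increasing")
  length_bins
}

#' Write predicted profiles as a tidy table
#'
#' @param profiles list returned by [predictBinnedProfiles()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writePredictedProfilesCSV <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(bin_lo_nm = attr(p, "bin_lo_nm"),
               bin_hi_nm = attr(p, "bin_hi_nm"),
               position_nm = p$position_nm, intensity_au = p$intensity_au)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
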