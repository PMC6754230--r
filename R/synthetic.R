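#' Ground-truth configuration for the synthetic-data generators
#'
#' Bundles the kinetic truth, the optical model, the binning layout and
#' the noise/asymmetry/dynamics settings every generator draws from. The
#' named presets encode the strain differences as the reported
#' fold-changes on an otherwise identical wild-type parameter set:
#'
#' * `"wt"`: minus-end loading dominates; `k_in / k_on = 500`.
#' * `"bfa1bub2"`: the GAP-complex deletion strain; `k_in` reduced
#'   12-fold, everything else as wild type.
#' * `"S63A"`: the hypo-phosphorylated landing mutant; `k_on` raised
#'   6-fold and `k_in` scaled so that `k_in / k_on = 40` inside the
#'   mutant (the in-rate shift, 0.48x, stays well inside the wild-type
#'   uncertainty and is reported as not significant).
#'
#' Absolute rate scales are model choices (the reference analysis prints
#' ratios, not absolute values): `k_step = 13.125` /s from the measured
#' 6.3 um/min speckle speed over 8 nm sites, `k_off = 0` (the flat-profile
#' regime), `c_total = 35` nM, `k_out` of the same magnitude as the
#' minus-end loading rate.
#'
#' @param preset one of `"wt"`, `"bfa1bub2"`, `"S63A"`.
#' @param seed integer seed recorded in the config.
#' @return list of class `TruthConfig`.
#' @export
truthConfig <- function(preset = c("wt", "bfa1bub2", "S63A"), seed = 1L) {
  preset <- match.arg(preset)
  k_in_wt <- 0.009                     # /nM/s
  k_on_wt <- k_in_wt / 500             # wt in/on ratio 500
  k_in <- switch(preset, wt = k_in_wt, bfa1bub2 = k_in_wt / 12,
                 S63A = k_in_wt * 0.48)
  k_on <- switch(preset, wt = k_on_wt, bfa1bub2 = k_on_wt,
                 S63A = k_on_wt * 6)
  cst <- kip2Constants()
  structure(list(
    preset = preset,
    kinetics = MotorKinetics(k_in = k_in, k_on = k_on, k_off = 0,
                             k_step = 6.3 * 1000 / 60 / cst$site_length_nm,
                             k_out = 0.6, c_total = 35),
    optical = OpticalModel(psf_sigma = 135,
                           pixel_size = cst$pixel_size_nm,
                           scale = 800, background = 200),
    length_bin_edges = cst$bin_nm * (3:9),   # 800.1 .. 2400.3 nm, 6 bins
    cells_per_bin = 100L,
    noise_sd_au = 100,
    noise_frac = 0.12,
    orientation_p_correct = 0.94,
    spb_ratio_median = 17 / 3,               # asymmetry index 0.7
    spb_ratio_log_sd = 0.5,
    spb_noise_log_sd = 0.2,
    inverted_ratio_median = 2 / 3,           # asymmetry index -0.2
    speckle_speed_mean = 6.3, speckle_speed_sd = 2.1,   # um/min
    growth_speed_mean = 1.4, growth_speed_sd = 1.1,     # um/min
    shrink_speed_mean = 3.0, shrink_speed_sd = 1.5,     # um/min, magnitude
    reservoir = ReservoirSpec(volume = 40, n_filaments = 1, closed = TRUE),
    site_length_nm = cst$site_length_nm,
    seed = as.integer(seed)), class = "TruthConfig")
}

# parameters (mu, sigma) of a zero-truncated normal whose realized mean
# and standard deviation equal the printed cohort statistics: the printed
# values are moments of the measured (positive) speeds, so drawing from
# N(mean, sd) truncated at zero would bias the realized mean upward
.trunc_norm_params <- function(target_mean, target_sd) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    z <- -mu / sig
    lam <- dnorm(z) / (1 - pnorm(z))
    m <- mu + sig * lam
    v <- sig^2 * (1 + z * lam - lam^2)
    (m - target_mean)^2 + (sqrt(max(v, 0)) - target_sd)^2
  }
  par <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14))$par
  c(mu = par[1], sigma = exp(par[2]))
}

# zero-truncated normal draws by rejection
.rtrunc_norm <- function(n, target_mean, target_sd) {
  if (target_sd == 0) return(rep(target_mean, n))
  pp <- .trunc_norm_params(target_mean, target_sd)
  x <- rnorm(n, pp[["mu"]], pp[["sigma"]])
  while (any(x <= 0))
    x[x <= 0] <- rnorm(sum(x <= 0), pp[["mu"]], pp[["sigma"]])
  x
}

.substream <- function(seed, label) {
  # deterministic per-module substream below 2^31
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h * 31) %% 2147483647)
}

#' Generate binned fluorescence profiles (plus raw line scans)
#'
#' Per length bin, renders the mean-field forward profile at the bin
#' midpoint length, simulates `cells_per_bin` cells by adding independent
#' Gaussian pixel noise (an additive floor `noise_sd_au` plus an
#' intensity-proportional component `noise_frac`, emulating photon
#' statistics), and aggregates to mean +/- SEM. Also emits the
#' raw per-cell two-channel scans (mCherry SPB peak at the origin, GFP
#' channel from the model) so the alignment/binning path can be exercised
#' end-to-end; the raw scans draw each cell's true length uniformly within
#' its bin. Pure function of (config, seed).
#'
#' @param truth a [truthConfig()].
#' @param seed overrides `truth$seed` when given.
#' @return list with `bins` (a `ProfileBins` data.frame on the bin
#'   midpoint grid — the fitting target), `scans` (list of raw line-scan
#'   data.frames), and `truth_sidecar` (list of the generating
#'   parameters).
#' @export
generateProfileDataset <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "TruthConfig"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, "profiles"))
  edges <- truth$length_bin_edges
  bins <- lapply(seq_len(length(edges) - 1),
                 function(i) c(edges[i], edges[i + 1]))
  preds <- predictBinnedProfiles(truth$kinetics, truth$optical, bins,
                                 LatticeSpec(1, truth$site_length_nm),
                                 truth$reservoir)
  nf <- truth$noise_frac %||% 0
  out_rows <- list(); scans <- list()
  for (b in seq_along(preds)) {
    p <- preds[[b]]
    n_cells <- truth$cells_per_bin
    # additive read noise plus an intensity-proportional (photon-like)
    # component, per pixel per cell
    pix_sd <- sqrt(truth$noise_sd_au^2 + (nf * p$intensity_au)^2)
    noise <- matrix(rnorm(length(p$intensity_au) * n_cells, 0, pix_sd),
                    nrow = length(p$intensity_au))
    cells <- p$intensity_au + noise
    m <- rowMeans(cells)
    sem <- apply(cells, 1, sd) / sqrt(n_cells)
    if (truth$noise_sd_au == 0 && nf == 0)
      sem <- rep(1, length(m))  # noise-free: SEMs degenerate, kept usable
    out_rows[[b]] <- data.frame(
      bin_lo_nm = bins[[b]][1], bin_hi_nm = bins[[b]][2],
      position_nm = p$position_nm, mean_au = m, sem_au = sem,
      n = n_cells, n_at_position = n_cells)
    # raw scans: per-cell true length uniform within the bin
    for (cell in seq_len(n_cells)) {
      len <- runif(1, bins[[b]][1], bins[[b]][2])
      n_sites <- max(1L, round(len / truth$site_length_nm))
      prof <- solveMeanfieldSteadyState(
        truth$kinetics, LatticeSpec(n_sites, truth$site_length_nm),
        truth$reservoir)
      margin <- 4 * truth$optical@pixel_size
      centers <- .pixel_centers(c(-margin,
                                  n_sites * truth$site_length_nm + margin),
                                truth$optical@pixel_size)
      gfp_clean <- .render_at(occupancy(prof), sitePositions(prof),
                              truth$optical, centers)
      gfp <- gfp_clean + rnorm(length(centers), 0,
                               sqrt(truth$noise_sd_au^2 +
                                      (nf * gfp_clean)^2))
      mch <- 200 + 3000 * exp(-centers^2 / (2 * truth$optical@psf_sigma^2)) +
        rnorm(length(centers), 0, truth$noise_sd_au)
      scans[[length(scans) + 1]] <- data.frame(
        position_nm = centers, gfp_au = gfp, mcherry_au = mch,
        cell_id = sprintf("bin%d_cell%03d", b, cell),
        date = "synthetic", true_length_nm = len)
    }
  }
  bins_df <- do.call(rbind, out_rows)
  class(bins_df) <- c("ProfileBins", "data.frame")
  list(bins = bins_df, scans = scans,
       truth_sidecar = list(preset = truth$preset,
                            kinetics = as.list(kineticRates(truth$kinetics)),
                            scale = truth$optical@scale,
                            background = truth$optical@background,
                            psf_sigma = truth$optical@psf_sigma,
                            noise_sd_au = truth$noise_sd_au,
                            seed = seed))
}

#' Generate per-cell SPB fluorescence pairs with orientation labels
#'
#' Each cell's orientation is Bernoulli(`orientation_p_correct`); its true
#' bud:mother intensity ratio is lognormal with the configured median
#' (`spb_ratio_median` for correctly oriented cells,
#' `inverted_ratio_median` for inverted ones) and log-sd; both sides then
#' receive independent multiplicative lognormal measurement noise.
#'
#' @param truth a [truthConfig()].
#' @param n_cells number of cells.
#' @param seed overrides `truth$seed`.
#' @param p_correct overrides the orientation probability (e.g. 1 to
#'   generate a purely correctly-oriented cohort).
#' @return data.frame (`CellRecord` rows): `fi_b`, `fi_m`, `orientation`,
#'   `genotype`, `true_ratio`.
#' @export
generateSpbDataset <- function(truth, n_cells, seed = truth$seed,
                               p_correct = truth$orientation_p_correct) {
  stopifnot(inherits(truth, "TruthConfig"), n_cells >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, "spb"))
  correct <- runif(n_cells) < p_correct
  med <- ifelse(correct, truth$spb_ratio_median,
                truth$inverted_ratio_median)
  ratio <- rlnorm(n_cells, log(med), truth$spb_ratio_log_sd)
  base <- rlnorm(n_cells, log(1000), 0.3)
  noise_b <- rlnorm(n_cells, 0, truth$spb_noise_log_sd)
  noise_m <- rlnorm(n_cells, 0, truth$spb_noise_log_sd)
  data.frame(fi_b = base * ratio * noise_b, fi_m = base * noise_m,
             orientation = ifelse(correct, "correct", "inverted"),
             genotype = truth$preset, true_ratio = ratio)
}

#' Generate kymograph speckle tracks
#'
#' Per-track speed drawn from a normal truncated at zero (mean/sd from the
#' config, um/min), converted to an integer pixel displacement over an
#' integer frame span at the standard frame interval and pixel size; the
#' resulting quantization error is below one pixel per track.
#'
#' @param truth a [truthConfig()].
#' @param n_tracks number of tracks.
#' @param seed overrides `truth$seed`.
#' @return data.frame (`KymographTrack` rows): `start_frame`, `start_px`,
#'   `end_frame`, `end_px`, `true_speed_um_min`.
#' @export
generateSpeckleTracks <- function(truth, n_tracks, seed = truth$seed) {
  stopifnot(inherits(truth, "TruthConfig"), n_tracks >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, "speckles"))
  cst <- kip2Constants()
  speed <- .rtrunc_norm(n_tracks, truth$speckle_speed_mean,
                        truth$speckle_speed_sd)
  span <- sample(8:40, n_tracks, replace = TRUE)
  start_frame <- sample(1:20, n_tracks, replace = TRUE)
  dpx <- round(speed * 1000 / 60 * span * cst$frame_interval_s /
                 cst$pixel_size_nm)
  start_px <- sample(1:10, n_tracks, replace = TRUE)
  data.frame(start_frame = start_frame, start_px = start_px,
             end_frame = start_frame + span, end_px = start_px + dpx,
             true_speed_um_min = speed)
}

#' Generate 3D microtubule length series with annotated phases
#'
#' Alternating growth and shrinkage phases over the 80-frame (85.6 s)
#' recording window; per-phase speeds are drawn from the configured
#' normals (growth truncated positive). Lengths are laid out in 3D along a
#' random per-microtubule direction from an SPB at the origin; spindle
#' lengths are drawn so that a configurable fraction of series violates
#' the 2 um spindle filter.
#'
#' @param truth a [truthConfig()].
#' @param n_microtubules number of series.
#' @param seed overrides `truth$seed`.
#' @param frac_long_spindle fraction of series with spindle > 2 um.
#' @return list of per-microtubule lists, each with `series` (coordinate
#'   data.frame ready for [microtubuleLength3d()]), `phases` (annotation
#'   data.frame) and `truth` (the drawn phase speeds, um/min).
#' @export
generateDynamicsDataset <- function(truth, n_microtubules,
                                    seed = truth$seed,
                                    frac_long_spindle = 0.1) {
  stopifnot(inherits(truth, "TruthConfig"), n_microtubules >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, "dynamics"))
  cst <- kip2Constants()
  n_frames <- cst$n_frames
  out <- vector("list", n_microtubules)
  for (m in seq_len(n_microtubules)) {
    frames <- seq_len(n_frames)
    # phase layout: alternating growth/shrinkage, 10-40 frames each
    phase_rows <- list(); speeds <- numeric(0)
    f <- 1L; growing <- TRUE
    len <- numeric(n_frames); len[1] <- runif(1, 0.8, 1.5)
    while (f < n_frames) {
      f_end <- min(n_frames, f + sample(10:40, 1))
      sp <- if (growing) {
        .rtrunc_norm(1, truth$growth_speed_mean, truth$growth_speed_sd)
      } else {
        -.rtrunc_norm(1, truth$shrink_speed_mean, truth$shrink_speed_sd)
      }
      for (ff in (f + 1):f_end)
        len[ff] <- max(0.05, len[ff - 1] +
                         sp / 60 * cst$frame_interval_s)
      phase_rows[[length(phase_rows) + 1]] <- data.frame(
        start_frame = f, end_frame = f_end,
        phase = if (growing) "growth" else "shrinkage")
      speeds <- c(speeds, sp)
      f <- f_end; growing <- !growing
    }
    dir_vec <- rnorm(3); dir_vec <- dir_vec / sqrt(sum(dir_vec^2))
    spindle <- if (runif(1) < frac_long_spindle) runif(1, 2.05, 3)
               else runif(1, 1.0, 1.9)
    series <- data.frame(
      frame = frames,
      plus_x_um = len * dir_vec[1], plus_y_um = len * dir_vec[2],
      plus_z_um = len * dir_vec[3],
      spb_x_um = 0, spb_y_um = 0, spb_z_um = 0,
      spindle_um = spindle)
    out[[m]] <- list(series = series,
                     phases = do.call(rbind, phase_rows),
                     truth = list(phase_speeds_um_min = speeds,
                                  spindle_um = spindle))
  }
  out
}

#' Apply an inter-day intensity scaling (inverse of the normalization)
#'
#' Transforms values by `(x - beta) / alpha`, the inverse of the affine
#' day-correction model, so that [qqNormalize()] against the untransformed
#' set recovers `(alpha, beta)`.
#'
#' @param values intensities (a.u.).
#' @param alpha multiplicative day effect (> 0).
#' @param beta additive day effect (a.u.).
#' @return transformed values.
#' @export
applyDayEffect <- function(values, alpha, beta) {
  if (alpha <= 0) stop("alpha must be > 0")
  (values - beta) / alpha
}
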