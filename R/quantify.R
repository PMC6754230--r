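#' Align a two-channel line scan to the spindle pole body
#'
#' Peak detection uses the global maximum of each channel after a 3-pixel
#' moving-average smoothing, with ties broken towards the scan start (the
#' SPB-proximal end). The profile origin is placed at the mCherry (SPB
#' marker) peak; the plus end is the GFP peak; the profile length is their
#' peak-to-peak distance. Positions are flipped if needed so that they
#' increase from the SPB towards the plus end.
#'
#' A channel whose smoothed maximum does not rise above its noise floor
#' (the lower-quartile baseline plus 3 robust spreads, so a constant or
#' featureless channel fails) is rejected.
#'
#' @param scan data.frame with columns `position_nm`, `gfp_au`,
#'   `mcherry_au` and optionally `cell_id`, `date`; positions uniform.
#' @return data.frame of class `AlignedProfile` with columns `position_nm`
#'   (relative to the SPB peak) and `gfp_au`, plus attributes
#'   `plus_end_position`, `profile_length`, `cell_id`, `date`, and
#'   `degenerate` (TRUE when both peaks coincide). On rejection, a
#'   zero-row record of class `RejectedScan` carrying the `reason`
#'   attribute is returned; [isRejectedScan()] tests for it.
#' @export
alignLineScan <- function(scan) {
  stopifnot(all(c("position_nm", "gfp_au", "mcherry_au") %in% names(scan)))
  pk_m <- .find_peak(scan$mcherry_au)
  if (is.na(pk_m)) return(.rejected("flat_mcherry_channel"))
  pk_g <- .find_peak(scan$gfp_au)
  if (is.na(pk_g)) return(.rejected("flat_gfp_channel"))
  pos_m <- scan$position_nm[pk_m]
  pos_g <- scan$position_nm[pk_g]
  len <- abs(pos_g - pos_m)
  flip <- if (pos_g < pos_m) -1 else 1
  rel <- (scan$position_nm - pos_m) * flip
  ord <- order(rel)
  out <- data.frame(position_nm = rel[ord], gfp_au = scan$gfp_au[ord])
  attr(out, "plus_end_position") <- len
  attr(out, "profile_length") <- len
  attr(out, "degenerate") <- len == 0
  attr(out, "cell_id") <- if ("cell_id" %in% names(scan))
    scan$cell_id[1] else NA
  attr(out, "date") <- if ("date" %in% names(scan)) scan$date[1] else NA
  class(out) <- c("AlignedProfile", "data.frame")
  out
}

.rejected <- function(reason) {
  structure(list(), class = "RejectedScan", reason = reason)
}

#' Test whether a line-scan alignment was rejected
#'
#' @param x result of [alignLineScan()].
#' @return TRUE for a rejection record.
#' @export
isRejectedScan <- function(x) inherits(x, "RejectedScan")

# global maximum after 3-pixel moving average; ties -> first index;
# NA when the maximum does not rise above the noise floor: the decile
# baseline (the scan's dim background region) plus three noise scales,
# with the noise scale taken from first differences so it is insensitive
# to the scan's own structure (background / shaft / peak levels)
.find_peak <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_integer_)
  sm <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(x[1:2]); sm[n] <- mean(x[(n - 1):n])
  sm <- as.numeric(sm)
  noise <- mad(diff(x)) / sqrt(2)
  floor_lvl <- quantile(sm, 0.1, names = FALSE) + 3 * noise
  pk <- which.max(sm)
  if (sm[pk] - floor_lvl <= 1e-8 * (abs(sm[pk]) + 1)) return(NA_integer_)
  pk
}

#' Group aligned profiles into microtubule-length bins
#'
#' Half-open bins `[k * bin_size, (k + 1) * bin_size)` on the profile
#' length. Within each retained bin the per-position mean and SEM over
#' profiles are computed on the common pixel grid; each profile is
#' truncated at its own plus-end peak plus `truncate_px` pixels before
#' aggregation. Bins with fewer than `min_n` profiles are dropped (and
#' listed in the `dropped` attribute).
#'
#' @param profiles list of `AlignedProfile` objects (see
#'   [alignLineScan()]); rejected (`NULL`) entries are ignored.
#' @param bin_size bin width in nm (default 266.7).
#' @param min_n minimum profiles per retained bin.
#' @param truncate_px pixels kept beyond each profile's plus-end peak.
#' @return data.frame of class `ProfileBins` with columns `bin_lo_nm`,
#'   `bin_hi_nm`, `position_nm`, `mean_au`, `sem_au`, `n`. A bin with a
#'   single profile has `sem_au = 0` and is flagged in the `degenerate`
#'   attribute. Empty input gives an empty result.
#' @export
binProfiles <- function(profiles, bin_size = 266.7, min_n = 1L,
                        truncate_px = 3L) {
  profiles <- Filter(function(p) !is.null(p) && !isRejectedScan(p),
                     profiles)
  if (length(profiles) == 0) return(.empty_bins())
  lens <- vapply(profiles, attr, numeric(1), "profile_length")
  idx <- floor(lens / bin_size)
  pixel <- .grid_step(profiles[[1]])
  rows <- list(); dropped <- integer(0); degenerate <- numeric(0)
  for (k in sort(unique(idx))) {
    sel <- which(idx == k)
    if (length(sel) < min_n) { dropped <- c(dropped, k); next }
    lo <- k * bin_size; hi <- (k + 1) * bin_size
    trunc_profiles <- lapply(profiles[sel], function(p) {
      keep <- p$position_nm <= attr(p, "plus_end_position") +
        truncate_px * pixel + 1e-9
      p[keep, , drop = FALSE]
    })
    all_pos <- sort(unique(round(
      unlist(lapply(trunc_profiles, `[[`, "position_nm")) / pixel)))
    stats_tab <- t(vapply(all_pos, function(px) {
      vals <- unlist(lapply(trunc_profiles, function(p) {
        p$gfp_au[round(p$position_nm / pixel) == px]
      }))
      m <- mean(vals)
      s <- if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0
      c(m, s, length(vals))
    }, numeric(3)))
    if (length(sel) == 1) degenerate <- c(degenerate, k)
    rows[[length(rows) + 1]] <- data.frame(
      bin_lo_nm = lo, bin_hi_nm = hi, position_nm = all_pos * pixel,
      mean_au = stats_tab[, 1], sem_au = stats_tab[, 2],
      n = length(sel), n_at_position = stats_tab[, 3])
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_bins()
  attr(out, "dropped") <- dropped
  attr(out, "degenerate") <- degenerate
  attr(out, "bin_size") <- bin_size
  class(out) <- c("ProfileBins", "data.frame")
  out
}

.empty_bins <- function() {
  out <- data.frame(bin_lo_nm = numeric(0), bin_hi_nm = numeric(0),
                    position_nm = numeric(0), mean_au = numeric(0),
                    sem_au = numeric(0), n = integer(0),
                    n_at_position = integer(0))
  class(out) <- c("ProfileBins", "data.frame")
  out
}

.grid_step <- function(profile) {
  p <- sort(unique(profile$position_nm))
  if (length(p) > 1) min(diff(p)) else kip2Constants()$pixel_size_nm
}

#' Quantile-quantile normalization between acquisition days
#'
#' Computes intensities at quantiles 0.5% to 99.5% in 0.5% steps (199
#' quantiles, linear interpolation between order statistics) from both
#' datasets and fits the linear model
#' `reference(q) = alpha * other(q) + beta` by ordinary least squares.
#'
#' @param reference numeric vector of reference-day intensities.
#' @param other numeric vector of intensities to be mapped onto the
#'   reference scale.
#' @return list with `alpha`, `beta`, `r_squared`, `mapped`
#'   (`alpha * other + beta`), and `interpolated` (TRUE when either input
#'   had fewer than 199 values so quantiles were interpolated).
#' @export
qqNormalize <- function(reference, other) {
  q <- seq(0.005, 0.995, by = 0.005)
  qr <- quantile(reference, q, names = FALSE, type = 7)
  qo <- quantile(other, q, names = FALSE, type = 7)
  if (var(qo) == 0) stop("zero variance in the quantiles of `other`")
  fit <- lm(qr ~ qo)
  r2 <- summary(fit)$r.squared
  alpha <- unname(coef(fit)[2]); beta <- unname(coef(fit)[1])
  list(alpha = alpha, beta = beta, r_squared = r2,
       mapped = alpha * other + beta,
       interpolated = length(reference) < 199 || length(other) < 199)
}

#' Weighted regression of plus-end peak intensity on microtubule length
#'
#' For each bin the plus-end peak value is the maximum of the bin's mean
#' profile within +/- 2 pixels of the bin's plus-end position (bin
#' midpoint length). Weighted least squares of the peak values against the
#' bin midpoints uses weights `1 / SEM^2` at the peak position; if any
#' peak SEM is zero the regression falls back to unweighted with a
#' warning.
#'
#' @param bins a `ProfileBins` data.frame (see [binProfiles()] or
#'   [generateProfileDataset()]).
#' @param peak_window_px half-width of the peak search window, in pixels.
#' @return list with `slope` (a.u. per nm), `intercept`, and a data.frame
#'   `peaks` (`length_nm`, `peak_au`, `sem_au`).
#' @export
plusEndRegression <- function(bins, peak_window_px = 2) {
  pixel <- kip2Constants()$pixel_size_nm
  keys <- unique(bins[, c("bin_lo_nm", "bin_hi_nm")])
  if (nrow(keys) < 2)
    stop("need >= 2 bins with plus-end peaks for a regression")
  peaks <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- bins[bins$bin_lo_nm == keys$bin_lo_nm[i], ]
    mid <- (keys$bin_lo_nm[i] + keys$bin_hi_nm[i]) / 2
    win <- abs(sub$position_nm - mid) <= peak_window_px * pixel + 1e-9
    if (!any(win)) win <- rep(TRUE, nrow(sub))
    j <- which(win)[which.max(sub$mean_au[win])]
    data.frame(length_nm = mid, peak_au = sub$mean_au[j],
               sem_au = sub$sem_au[j])
  }))
  if (any(peaks$sem_au == 0)) {
    warning("zero SEM at a peak position; falling back to unweighted ",
            "regression")
    fit <- lm(peak_au ~ length_nm, data = peaks)
  } else {
    fit <- lm(peak_au ~ length_nm, data = peaks,
              weights = 1 / peaks$sem_au^2)
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       peaks = peaks)
}

#' Spindle-pole asymmetry index
#'
#' `(fi_b - fi_m) / (fi_b + fi_m)`: +1 when all fluorescence sits on the
#' bud-directed side, -1 when all sits on the mother-directed side.
#' Swapping the two sides negates the index exactly.
#'
#' @param fi_b,fi_m non-negative bud-side and mother-side fluorescence
#'   intensities (vectorized).
#' @return numeric vector in `[-1, 1]`; `NA` where both intensities are
#'   zero (undefined; such records are excluded with the `excluded`
#'   attribute listing their indices).
#' @export
asymmetryIndex <- function(fi_b, fi_m) {
  stopifnot(length(fi_b) == length(fi_m))
  if (any(fi_b < 0 | fi_m < 0, na.rm = TRUE))
    stop("fluorescence intensities must be >= 0")
  tot <- fi_b + fi_m
  out <- ifelse(tot > 0, (fi_b - fi_m) / tot, NA_real_)
  attr(out, "excluded") <- which(tot == 0)
  out
}

#' Relative fluorescence (%) against a reference group mean
#'
#' @param values numeric fluorescence intensities.
#' @param groups group label per value.
#' @param reference_group label of the normalizing group.
#' @return values divided by the reference-group mean, times 100.
#' @export
relativeFluorescence <- function(values, groups, reference_group) {
  ref <- values[groups == reference_group]
  if (length(ref) == 0) stop("reference group is empty")
  m <- mean(ref)
  if (m <= 0) stop("reference group mean must be > 0")
  100 * values / m
}

#' Speckle speed from kymograph endpoints
#'
#' `|delta pixel| * pixel_size / (delta frame * frame_interval)`,
#' converted to um/min. Vectorized over tracks.
#'
#' @param start_frame,start_px,end_frame,end_px track endpoints.
#' @param frame_interval_s seconds per frame (default 1.07).
#' @param pixel_size_nm nm per pixel (default 133.35).
#' @return speeds in um/min.
#' @export
speckleSpeed <- function(start_frame, start_px, end_frame, end_px,
                         frame_interval_s = kip2Constants()$frame_interval_s,
                         pixel_size_nm = kip2Constants()$pixel_size_nm) {
  dframe <- end_frame - start_frame
  if (any(dframe <= 0)) stop("each track needs end_frame > start_frame")
  dist_um <- abs(end_px - start_px) * pixel_size_nm / 1000
  dist_um / (dframe * frame_interval_s) * 60
}

#' 3D microtubule lengths with the standard filters
#'
#' Per-frame Euclidean distance between the plus-end and SPB coordinates.
#' Frames whose spindle is longer than 2 um are excluded; lengths at or
#' below the 5-pixel (666.7 nm) resolution limit are flagged
#' undetectable. Frames with missing plus-end coordinates (no visible
#' microtubule) get length 0 by convention.
#'
#' @param series data.frame with columns `frame`, `plus_x_um`,
#'   `plus_y_um`, `plus_z_um`, `spb_x_um`, `spb_y_um`, `spb_z_um`,
#'   `spindle_um`.
#' @return the input with added columns `length_um`, `detectable`,
#'   `excluded`.
#' @export
microtubuleLength3d <- function(series) {
  need <- c("frame", "plus_x_um", "plus_y_um", "plus_z_um",
            "spb_x_um", "spb_y_um", "spb_z_um", "spindle_um")
  stopifnot(all(need %in% names(series)))
  cst <- kip2Constants()
  dx <- series$plus_x_um - series$spb_x_um
  dy <- series$plus_y_um - series$spb_y_um
  dz <- series$plus_z_um - series$spb_z_um
  len <- sqrt(dx^2 + dy^2 + dz^2)
  len[is.na(len)] <- 0           # absent microtubule convention
  if (any(!is.finite(len))) stop("non-finite coordinates in series")
  series$length_um <- len
  series$detectable <- len > cst$detect_limit_nm / 1000
  series$excluded <- series$spindle_um > cst$spindle_max_um
  series
}

#' Maximum length, lifetime and per-phase speeds of a microtubule
#'
#' Operates on the output of [microtubuleLength3d()] plus manual phase
#' annotations. The maximum detectable length and the lifetime (total time
#' with detectable length) are computed over non-excluded frames within
#' the recording window; per-phase speeds are signed
#' `(length at phase end - length at phase start) / phase duration`, in
#' um/min (growth positive, shrinkage negative). Phases shorter than 2
#' frames are skipped with a warning.
#'
#' @param series data.frame as returned by [microtubuleLength3d()].
#' @param phases data.frame with columns `start_frame`, `end_frame`,
#'   `phase` (`"growth"` or `"shrinkage"`), non-overlapping.
#' @param frame_interval_s seconds per frame.
#' @return list with `max_length_um`, `lifetime_s`, and data.frame
#'   `phase_speeds` (`phase`, `speed_um_min`).
#' @export
summarizeDynamics <- function(series, phases,
                              frame_interval_s =
                                kip2Constants()$frame_interval_s) {
  stopifnot(all(c("length_um", "detectable", "excluded") %in%
                  names(series)))
  ok <- !series$excluded
  det <- ok & series$detectable
  max_len <- if (any(det)) max(series$length_um[det]) else NA_real_
  lifetime <- sum(det) * frame_interval_s
  rows <- list()
  for (i in seq_len(nrow(phases))) {
    f0 <- phases$start_frame[i]; f1 <- phases$end_frame[i]
    if (f1 - f0 < 2) {
      warning("phase ", i, " shorter than 2 frames; skipped")
      next
    }
    l0 <- series$length_um[match(f0, series$frame)]
    l1 <- series$length_um[match(f1, series$frame)]
    speed <- (l1 - l0) / ((f1 - f0) * frame_interval_s) * 60
    rows[[length(rows) + 1]] <- data.frame(phase = phases$phase[i],
                                           speed_um_min = speed)
  }
  list(max_length_um = max_len, lifetime_s = lifetime,
       phase_speeds = if (length(rows)) do.call(rbind, rows) else
                        data.frame(phase = character(0),
                                   speed_um_min = numeric(0)))
}
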