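px <- 133.35

make_scan <- function(mch_peak_idx, gfp_peak_idx, n = 30, noise = 0,
                      seed = 1) {
  set.seed(seed)
  pos <- (seq_len(n) - 1) * px
  gfp <- 100 + rnorm(n, 0, noise)
  gfp[gfp_peak_idx] <- gfp[gfp_peak_idx] + 900
  mch <- 100 + rnorm(n, 0, noise)
  mch[mch_peak_idx] <- mch[mch_peak_idx] + 900
  data.frame(position_nm = pos, gfp_au = gfp, mcherry_au = mch,
             cell_id = "c1", date = "d1")
}

test_that("line-scan alignment puts the origin at the SPB peak", {
  out <- alignLineScan(make_scan(4, 13))
  # peaks at indices 4 and 13: 9 pixels apart = 1200.15 nm
  expect_equal(attr(out, "profile_length"), 9 * px)
  expect_equal(attr(out, "plus_end_position"), 1200.15, tolerance = 1e-9)
  expect_false(attr(out, "degenerate"))
  expect_equal(min(abs(out$position_nm)), 0)
  # orientation flip: SPB peak beyond the GFP peak reverses positions
  out2 <- alignLineScan(make_scan(20, 5))
  expect_equal(attr(out2, "profile_length"), 15 * px)
  expect_gt(out2$gfp_au[which.max(out2$position_nm == 15 * px)], 0)
})

test_that("coincident peaks are flagged degenerate, flat channels rejected", {
  out <- alignLineScan(make_scan(7, 7))
  expect_equal(attr(out, "profile_length"), 0)
  expect_true(attr(out, "degenerate"))
  flat <- make_scan(4, 13)
  flat$mcherry_au <- 100
  rej <- alignLineScan(flat)
  expect_true(isRejectedScan(rej))
  expect_equal(attr(rej, "reason"), "flat_mcherry_channel")
})

test_that("alignment recovers rendered peak offsets within one pixel", {
  # constructed geometry: two sharp rendered peaks at known positions
  set.seed(44)
  opt <- OpticalModel(psf_sigma = 60, pixel_size = px, scale = 2000,
                      background = 100)
  for (rep in 1:5) {
    spb_nm <- runif(1, 100, 400)
    plus_nm <- spb_nm + runif(1, 900, 2200)
    centers <- kip2traffic:::.pixel_centers(c(-400, plus_nm + 500), px)
    gfp <- 100 + 2000 * exp(-(centers - plus_nm)^2 / (2 * 60^2)) +
      rnorm(length(centers), 0, 20)
    mch <- 100 + 2000 * exp(-(centers - spb_nm)^2 / (2 * 60^2)) +
      rnorm(length(centers), 0, 20)
    out <- alignLineScan(data.frame(position_nm = centers, gfp_au = gfp,
                                    mcherry_au = mch))
    expect_false(isRejectedScan(out))
    expect_lt(abs(attr(out, "profile_length") - (plus_nm - spb_nm)),
              1 * px + 1e-9)
  }
})

test_that("alignment finds generated plus-end peaks despite blur displacement", {
  # full forward-model scans: the blurred plus-end maximum sits up to a
  # few pixels inside the lattice end, so recovery is coarser than the
  # sharp-peak geometry above
  truth <- truthConfig("wt", seed = 42)
  truth$noise_sd_au <- 20          # low noise: geometry check, not power
  truth$cells_per_bin <- 3L
  ds <- generateProfileDataset(truth)
  for (scan in ds$scans[1:6]) {
    out <- alignLineScan(scan)
    expect_false(isRejectedScan(out))
    expect_lt(abs(attr(out, "profile_length") - scan$true_length_nm[1]),
              4 * px)
  }
})

test_that("binning partitions profiles and computes exact SEMs", {
  mk <- function(len_px, value, cell) {
    p <- data.frame(position_nm = (0:20) * px, gfp_au = value)
    attr(p, "plus_end_position") <- len_px * px
    attr(p, "profile_length") <- len_px * px
    class(p) <- c("AlignedProfile", "data.frame")
    p
  }
  # two identical profiles in one bin: SEM exactly zero
  bins <- binProfiles(list(mk(5, 10), mk(5, 10)), bin_size = 266.7)
  expect_true(all(bins$sem_au == 0))
  expect_true(all(bins$n == 2))
  # a single profile: degenerate flag, mean equals the profile
  bins1 <- binProfiles(list(mk(5, 7)), bin_size = 266.7)
  expect_true(all(bins1$mean_au == 7))
  expect_length(attr(bins1, "degenerate"), 1)
  # partition: each profile lands in exactly one bin, counts conserved
  profs <- list(mk(3, 1), mk(3, 2), mk(9, 3), mk(9, 4), mk(15, 5))
  bins3 <- binProfiles(profs, bin_size = 266.7)
  keys <- unique(bins3[, c("bin_lo_nm", "n")])
  expect_equal(sum(keys$n), 5)
  # empty input: empty result, not an error
  expect_equal(nrow(binProfiles(list())), 0)
  # min_n drops sparse bins
  bins4 <- binProfiles(profs, bin_size = 266.7, min_n = 2)
  expect_equal(sort(unique(bins4$n)), 2)
  expect_true(length(attr(bins4, "dropped")) >= 1)
})

test_that("binned SEM follows the sampling law on i.i.d. noise", {
  set.seed(11)
  n_prof <- 100
  profs <- lapply(seq_len(n_prof), function(i) {
    p <- data.frame(position_nm = (0:10) * px,
                    gfp_au = rnorm(11, 50, 5))
    attr(p, "plus_end_position") <- 8 * px
    attr(p, "profile_length") <- 8 * px
    class(p) <- c("AlignedProfile", "data.frame")
    p
  })
  bins <- binProfiles(profs, bin_size = 266.7)
  expect_equal(mean(bins$sem_au), 5 / sqrt(n_prof), tolerance = 0.2)
})

test_that("quantile normalization recovers affine relations exactly", {
  set.seed(2)
  x <- rlnorm(500, 5, 1)
  same <- qqNormalize(x, x)
  expect_equal(same$alpha, 1, tolerance = 1e-12)
  expect_equal(same$beta, 0, tolerance = 1e-9)
  expect_equal(same$r_squared, 1, tolerance = 1e-12)
  aff <- qqNormalize(2 * x + 5, x)
  expect_equal(aff$alpha, 2, tolerance = 1e-10)
  expect_equal(aff$beta, 5, tolerance = 1e-7)
  expect_equal(aff$r_squared, 1, tolerance = 1e-10)
  expect_equal(aff$mapped, 2 * x + 5, tolerance = 1e-7)
  expect_error(qqNormalize(x, rep(3, 500)), "variance")
})

test_that("quantile normalization is consistent under independent noise", {
  set.seed(3)
  ref <- rlnorm(1e4, 6, 0.8)
  other <- rlnorm(1e4, 6, 0.8)
  fit <- qqNormalize(ref, other)
  expect_lt(abs(fit$alpha - 1), 0.05)
})

test_that("plus-end regression matches the weighted normal equations", {
  mids <- 266.7 * (3:8) + 266.7 / 2
  mk_bin <- function(mid, peak, sem) {
    pos <- seq(0, mid + 2 * px, by = px)
    m <- rep(5, length(pos)); m[which.min(abs(pos - mid))] <- peak
    data.frame(bin_lo_nm = mid - 266.7 / 2, bin_hi_nm = mid + 266.7 / 2,
               position_nm = pos, mean_au = m, sem_au = sem, n = 10,
               n_at_position = 10)
  }
  # flat peaks: slope 0
  flat <- do.call(rbind, lapply(mids, mk_bin, peak = 50, sem = 1))
  expect_equal(plusEndRegression(flat)$slope, 0, tolerance = 1e-12)
  # proportional peaks: slope = constant, intercept 0
  prop <- do.call(rbind, lapply(mids, function(m)
    mk_bin(m, peak = 0.3 * m, sem = 1)))
  r <- plusEndRegression(prop)
  expect_equal(r$slope, 0.3, tolerance = 1e-9)
  expect_equal(r$intercept, 0, tolerance = 1e-6)
  # heteroscedastic: match an independent weighted normal-equations solve
  set.seed(9)
  sems <- runif(6, 0.5, 4)
  peaks <- 10 + 0.05 * mids + rnorm(6, 0, 2)
  het <- do.call(rbind, lapply(seq_along(mids), function(i)
    mk_bin(mids[i], peaks[i], sems[i])))
  r2 <- plusEndRegression(het)
  W <- diag(1 / sems^2)
  X <- cbind(1, mids)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% peaks)
  expect_equal(r2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  # zero SEM: warning + unweighted fallback
  zero <- do.call(rbind, lapply(mids, mk_bin, peak = 50, sem = 0))
  expect_warning(plusEndRegression(zero), "unweighted")
})

test_that("asymmetry index is bounded, antisymmetric and exact", {
  expect_equal(asymmetryIndex(10, 10), 0, ignore_attr = TRUE)
  expect_equal(asymmetryIndex(10, 0), 1, ignore_attr = TRUE)
  expect_equal(asymmetryIndex(85, 15), 0.7, ignore_attr = TRUE)
  set.seed(13)
  b <- runif(200, 0, 50); m <- runif(200, 0, 50)
  expect_equal(as.numeric(asymmetryIndex(b, m)),
               -as.numeric(asymmetryIndex(m, b)))
  expect_true(all(abs(asymmetryIndex(b, m)) <= 1, na.rm = TRUE))
  both0 <- asymmetryIndex(c(1, 0), c(1, 0))
  expect_true(is.na(both0[2]))
  expect_equal(attr(both0, "excluded"), 2L)
  expect_error(asymmetryIndex(-1, 2), ">= 0")
})

test_that("relative fluorescence normalizes to the reference-group mean", {
  vals <- c(10, 10, 10, 25)
  grp <- c("ref", "ref", "q", "q")
  out <- relativeFluorescence(vals, grp, "ref")
  expect_equal(out, c(100, 100, 100, 250))
  expect_error(relativeFluorescence(vals, grp, "missing"), "empty")
})

test_that("speckle speeds follow the pixel/frame arithmetic", {
  expect_equal(speckleSpeed(1, 5, 11, 5), 0)
  # 10 px over 10 frames: 1.3335 um / 10.7 s * 60 = 7.477 um/min
  expect_equal(speckleSpeed(1, 0, 11, 10), 1.3335 / 10.7 * 60,
               tolerance = 1e-12)
  # invariance under a common frame shift
  expect_equal(speckleSpeed(1, 0, 11, 10), speckleSpeed(21, 0, 31, 10))
  expect_error(speckleSpeed(5, 0, 5, 10), "end_frame")
})

test_that("3D lengths apply the detectability and spindle filters", {
  series <- data.frame(
    frame = 1:4,
    plus_x_um = c(0.3, 0.6, 1.0, NA), plus_y_um = c(0.4, 0.8, 0, NA),
    plus_z_um = c(0, 0, 0, NA),
    spb_x_um = 0, spb_y_um = 0, spb_z_um = 0,
    spindle_um = c(1.5, 1.5, 2.5, 1.5))
  out <- microtubuleLength3d(series)
  expect_equal(out$length_um, c(0.5, 1.0, 1.0, 0))
  expect_equal(out$detectable, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE, FALSE))
  # filters are idempotent predicates
  again <- microtubuleLength3d(out[, names(series)])
  expect_equal(again$detectable, out$detectable)
  expect_equal(again$excluded, out$excluded)
  # brute-force distance oracle on random coordinates
  set.seed(21)
  rnd <- data.frame(frame = 1:50,
                    plus_x_um = rnorm(50), plus_y_um = rnorm(50),
                    plus_z_um = rnorm(50), spb_x_um = rnorm(50),
                    spb_y_um = rnorm(50), spb_z_um = rnorm(50),
                    spindle_um = 1)
  got <- microtubuleLength3d(rnd)$length_um
  want <- vapply(1:50, function(i) {
    sqrt(sum((c(rnd$plus_x_um[i], rnd$plus_y_um[i], rnd$plus_z_um[i]) -
                c(rnd$spb_x_um[i], rnd$spb_y_um[i], rnd$spb_z_um[i]))^2))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("dynamics summaries compute phase speeds and lifetimes", {
  # monotone growth 0.7 -> 1.4 um over 30 frame intervals at 1.07 s
  lens <- seq(0.7, 1.4, length.out = 31)
  series <- data.frame(
    frame = 1:31,
    plus_x_um = lens, plus_y_um = 0, plus_z_um = 0,
    spb_x_um = 0, spb_y_um = 0, spb_z_um = 0, spindle_um = 1)
  out <- microtubuleLength3d(series)
  phases <- data.frame(start_frame = 1, end_frame = 31, phase = "growth")
  s <- summarizeDynamics(out, phases)
  expect_equal(s$phase_speeds$speed_um_min, 0.7 / (30 * 1.07) * 60,
               tolerance = 1e-12)
  expect_equal(s$max_length_um, 1.4)
  expect_equal(s$lifetime_s, 31 * 1.07)
  # constant series: zero speeds, full-window lifetime
  const <- series; const$plus_x_um <- 1
  cs <- summarizeDynamics(microtubuleLength3d(const), phases)
  expect_equal(cs$phase_speeds$speed_um_min, 0)
  expect_equal(cs$lifetime_s, 31 * 1.07)
  # too-short phase skipped with warning
  expect_warning(
    summarizeDynamics(out, data.frame(start_frame = 1, end_frame = 2,
                                      phase = "growth")),
    "skipped")
})
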