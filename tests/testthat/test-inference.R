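toy_bins <- function() {
  # two tiny bins with hand-set means/SEMs on the standard pixel grid
  mk <- function(lo, hi, means, sems) {
    data.frame(bin_lo_nm = lo, bin_hi_nm = hi,
               position_nm = (seq_along(means) - 0.5) * 133.35 - 266.7,
               mean_au = means, sem_au = sems, n = 10, n_at_position = 10)
  }
  rbind(mk(800.1, 1066.8, c(210, 260, 270, 275, 250, 205), rep(4, 6)),
        mk(1066.8, 1333.5, c(212, 262, 268, 273, 270, 248, 206), rep(5, 7)))
}

test_that("the negative log-likelihood is an SEM-weighted half chi-square", {
  bins <- toy_bins()
  pars <- c(k_in = 0.04, k_on = 8e-5, k_off = 0, k_step = 13.125,
            k_out = 2.8, c_total = 35, scale = 300, background = 200)
  got <- negLogLikelihood(pars, bins)
  # brute-force oracle: loop over rows, render via the public forward model
  nll <- 0
  for (key in unique(bins$bin_lo_nm)) {
    sub <- bins[bins$bin_lo_nm == key, ]
    mid <- (sub$bin_lo_nm[1] + sub$bin_hi_nm[1]) / 2
    prof <- solveMeanfieldSteadyState(
      MotorKinetics(0.04, 8e-5, 0, 13.125, 2.8, 35),
      LatticeSpec(round(mid / 8), 8))
    opt <- OpticalModel(psf_sigma = 135, scale = 300, background = 200)
    pred <- predictBinnedProfiles(
      MotorKinetics(0.04, 8e-5, 0, 13.125, 2.8, 35), opt,
      list(c(sub$bin_lo_nm[1], sub$bin_hi_nm[1])), LatticeSpec(1, 8),
      positions = list(sub$position_nm))[[1]]
    for (i in seq_len(nrow(sub)))
      nll <- nll + 0.5 * ((sub$mean_au[i] - pred$intensity_au[i]) /
                            sub$sem_au[i])^2
  }
  expect_equal(as.numeric(got), nll, tolerance = 1e-10)
})

test_that("negLL is zero at a perfect fit and 0.5 at one SEM residual", {
  # single bin, single position: set the datum to the prediction
  pars <- c(k_in = 0.04, k_on = 0, k_off = 0, k_step = 13.125,
            k_out = 2.8, c_total = 35, scale = 300, background = 200)
  bins <- data.frame(bin_lo_nm = 800.1, bin_hi_nm = 1066.8,
                     position_nm = 466.725, mean_au = 0, sem_au = 2,
                     n = 5, n_at_position = 5)
  pred <- negLogLikelihood(pars, transform(bins, mean_au = 0))
  # solve for the prediction by rearranging the residual at mean 0
  pred_val <- sqrt(2 * as.numeric(pred)) * 2
  bins$mean_au <- pred_val
  expect_equal(as.numeric(negLogLikelihood(pars, bins)), 0,
               tolerance = 1e-9)
  bins$mean_au <- pred_val + 2     # one SEM off
  expect_equal(as.numeric(negLogLikelihood(pars, bins)), 0.5,
               tolerance = 1e-9)
})

test_that("negLL is invariant under bin order and guards its inputs", {
  bins <- toy_bins()
  pars <- c(k_in = 0.04, k_on = 8e-5, k_off = 0, k_step = 13.125,
            k_out = 2.8, c_total = 35, scale = 300, background = 200)
  shuffled <- bins[rev(seq_len(nrow(bins))), ]
  expect_equal(as.numeric(negLogLikelihood(pars, bins)),
               as.numeric(negLogLikelihood(pars, shuffled)),
               tolerance = 1e-12)
  bad <- bins; bad$sem_au[3] <- 0
  expect_error(negLogLikelihood(pars, bad), "SEM > 0")
  # invalid parameter point is sampler-safe
  pars_bad <- pars; pars_bad["k_in"] <- -1
  expect_true(is.infinite(negLogLikelihood(pars_bad, bins)))
})

test_that("maximum likelihood is deterministic and respects bounds", {
  truth <- quick_truth("wt", cells = 60, seed = 5)
  bins <- generateProfileDataset(truth)$bins
  f1 <- fitMaximumLikelihood(bins, n_starts = 2, seed = 3)
  f2 <- fitMaximumLikelihood(bins, n_starts = 2, seed = 3)
  expect_identical(f1$par, f2$par)
  free <- setdiff(names(f1$par), names(defaultFixed()))
  expect_true(all(f1$par[free] >= defaultRanges()[free, 1] - 1e-12))
  expect_true(all(f1$par[free] <= defaultRanges()[free, 2] + 1e-12))
  # bounds excluding the truth: endpoint flagged on the boundary; the
  # constrained parameter must be one the scale degeneracy cannot absorb
  narrow <- defaultRanges()
  narrow["k_out", ] <- c(5, 100)         # truth 0.6 excluded
  f3 <- fitMaximumLikelihood(bins, ranges = narrow, n_starts = 2, seed = 3)
  expect_true("k_out" %in% f3$at_boundary)
})

test_that("ML recovers identifiable ratios from low-noise profiles", {
  truth <- quick_truth("wt", cells = 200, seed = 5)
  truth$noise_sd_au <- 30
  bins <- generateProfileDataset(truth)$bins
  fit <- fitMaximumLikelihood(bins, n_starts = 3, seed = 3)
  # ratios are identified even where absolute rates trade against the
  # concentration and the fluorescence scale
  expect_equal(fit$par[["k_in"]] / fit$par[["k_on"]], 500,
               tolerance = 0.2)
  expect_equal(fit$par[["k_out"]], 0.6, tolerance = 0.15)
})

test_that("the sampler reproduces a closed-form Gaussian target", {
  # 1-D quadratic negLL: N(3, 0.5^2); analytic median 3, IQR 1.349 sigma
  neg_ll <- function(theta) 0.5 * ((theta - 3) / 0.5)^2
  res <- kip2traffic:::.adaptive_mh(neg_ll, lower = -10, upper = 10,
                                    init = 2.5, n_draws = 20000,
                                    n_chains = 4, burn = 2000, seed = 4)
  x <- as.numeric(res$draws)
  expect_lt(abs(median(x) - 3), 2 * 0.5 / sqrt(length(x)) * 10)
  expect_equal(IQR(x), 1.349 * 0.5, tolerance = 0.05)
  expect_lt(max(res$rhat), 1.05)
})

test_that("a flat target yields approximately uniform draws", {
  neg_ll <- function(theta) 0
  res <- kip2traffic:::.adaptive_mh(neg_ll, lower = 0, upper = 1,
                                    init = 0.5, n_draws = 8000,
                                    n_chains = 4, burn = 1500, seed = 6)
  thinned <- as.numeric(res$draws)[seq(1, 8000, by = 40)]
  ks <- suppressWarnings(stats::ks.test(thinned, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("likelihood sampling is seed-deterministic", {
  truth <- quick_truth("wt", cells = 40, seed = 5)
  bins <- generateProfileDataset(truth)$bins
  s1 <- sampleLikelihood(bins, n_draws = 300, seed = 17, n_chains = 2,
                         burn = 300)
  s2 <- sampleLikelihood(bins, n_draws = 300, seed = 17, n_chains = 2,
                         burn = 300)
  expect_identical(parameterDraws(s1), parameterDraws(s2))
  expect_true(all(parameterDraws(s1)[, "k_in"] >=
                    defaultRanges()["k_in", 1]))
})

test_that("sample summaries follow the averaged order-statistic convention", {
  draws <- cbind(k_in = as.numeric(1:100), k_on = rep(2, 100))
  smp <- new("ParameterSamples", draws = draws,
             log_likelihoods = rep(0, 100), sampler_seed = 1L,
             ranges = cbind(lower = c(1, 2), upper = c(100, 2)),
             rhat = c(1, 1), converged = TRUE)
  s <- summarizeSamples(smp, derived = c(ratio = "k_in / k_on"))
  tab <- s$table
  expect_equal(tab$median[tab$parameter == "k_in"], 50.5)
  expect_equal(tab$iqr[tab$parameter == "k_in"], 50)
  expect_equal(tab$median[tab$parameter == "k_on"], 2)
  expect_equal(tab$iqr[tab$parameter == "k_on"], 0)
  expect_equal(tab$median[tab$parameter == "ratio"], 50.5 / 2)
  # KDE integrates to one
  kde <- s$kde$k_in
  expect_equal(sum(kde$y) * diff(kde$x[1:2]), 1, tolerance = 1e-3)
  # lognormal median against theory
  set.seed(8)
  ln <- cbind(k_in = rlnorm(20000, 1, 0.7))
  smp2 <- new("ParameterSamples", draws = ln,
              log_likelihoods = rep(0, 20000), sampler_seed = 1L,
              ranges = cbind(lower = 0, upper = Inf), rhat = 1,
              converged = TRUE)
  med <- summarizeSamples(smp2)$table$median
  se_med <- 1.2533 * sd(ln) / sqrt(20000)
  expect_lt(abs(med - exp(1)), 3 * se_med)
})

test_that("draw-counting comparisons report violation fractions", {
  set.seed(10)
  n <- 20000
  mk_samples <- function(k_in) {
    draws <- cbind(k_in = k_in, k_on = rlnorm(n, -8, 0.3),
                   c_total = rlnorm(n, log(50), 0.5))
    new("ParameterSamples", draws = draws, log_likelihoods = rep(0, n),
        sampler_seed = 1L,
        ranges = cbind(lower = apply(draws, 2, min),
                       upper = apply(draws, 2, max)),
        rhat = rep(1, 3), converged = TRUE)
  }
  # a predicate that always holds: p reported at the 1/n floor
  always <- mk_samples(rlnorm(n, 0, 0.2))
  cmp <- compareParameters(always, "k_in > k_on")
  expect_equal(cmp$p_value, 1 / n)
  expect_true(cmp$p_is_floor)
  # paired identical distributions: p about one half
  a <- mk_samples(rlnorm(n, -2, 0.4))
  b <- mk_samples(rlnorm(n, -2, 0.4))
  sym <- compareParameters(list(x = a, y = b), "k_in_x < k_in_y",
                           seed = 2)
  expect_equal(sym$p_value, 0.5, tolerance = 0.02)
  # constructed 12-fold separation with overlapping noise
  lo <- mk_samples(rlnorm(n, log(0.003), 0.45))
  hi <- mk_samples(rlnorm(n, log(0.036), 0.45))
  sep <- compareParameters(list(mut = lo, wt = hi), "k_in_mut < k_in_wt",
                           conditioning = "c_total >= 35",
                           fold = "k_in_wt / k_in_mut", seed = 3)
  expect_lt(sep$p_value, 0.01)
  expect_equal(sep$fold_difference, 12, tolerance = 0.25)
  # conditioning that strips almost everything errors out
  expect_error(
    compareParameters(list(mut = lo, wt = hi), "k_in_mut < k_in_wt",
                      conditioning = "c_total >= 1e6"),
    "100 draws")
})

test_that("joint fits validate their sharing map", {
  truth <- quick_truth("wt", cells = 40, seed = 5)
  bins <- generateProfileDataset(truth)$bins
  expect_error(
    jointFitStrains(list(a = bins, b = bins),
                    sharing = list(shared = c("k_step", "bogus"),
                                   per_strain = c("k_in"))),
    "partition")
})
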