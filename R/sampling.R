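#' Sample the likelihood over kinetic and optical parameters
#'
#' Draws from `exp(-negLogLikelihood)` truncated to a log10-uniform box,
#' using a seeded adaptive random-walk Metropolis sampler (proposal
#' covariance adapted during burn-in, frozen afterwards) started from
#' jittered copies of a short multi-start maximum-likelihood fit. The
#' split-chain Rhat convergence diagnostic is computed per parameter; the
#' result is returned but flagged when `max(Rhat) > 1.05`.
#'
#' @param data a `ProfileBins` data.frame.
#' @param ranges truncation box, as [defaultRanges()].
#' @param n_draws total retained draws (>= 1000 recommended for
#'   summaries; the reference analysis uses 20,000).
#' @param seed integer seed; identical inputs and seed give identical
#'   draws.
#' @param fixed named vector of parameters held fixed.
#' @param config a [forwardConfig()].
#' @param n_chains number of chains.
#' @param burn burn-in iterations per chain (adaptation window).
#' @return A [ParameterSamples]; fixed parameters appear as constant
#'   columns so summaries and comparisons see the full vector.
#' @export
sampleLikelihood <- function(data, ranges = defaultRanges(),
                             n_draws = 2000, seed = 1,
                             fixed = defaultFixed(),
                             config = forwardConfig(), n_chains = 4,
                             burn = 6000) {
  blocks <- .attach_render_matrices(.bin_blocks(data), config)
  if (any(data$sem_au <= 0)) stop("all fitted positions must have SEM > 0")
  free <- setdiff(.PARAM_NAMES, names(fixed))
  cache <- new.env(parent = emptyenv())
  neg_ll <- function(theta) {
    p <- c(setNames(10^theta, free), fixed)[.PARAM_NAMES]
    names(p) <- .PARAM_NAMES
    .neg_ll_blocks(p, blocks, config, cache = cache)
  }
  map <- fitMaximumLikelihood(data, ranges, n_starts = 3, seed = seed,
                              fixed = fixed, config = config)
  init <- log10(map$par[free])
  res <- .adaptive_mh(neg_ll, lower = log10(ranges[free, 1]),
                      upper = log10(ranges[free, 2]), init = init,
                      n_draws = n_draws, n_chains = n_chains, burn = burn,
                      seed = seed, ridge = .ridge_directions(free))
  draws <- 10^res$draws
  colnames(draws) <- free
  if (length(fixed)) {
    fx <- matrix(rep(fixed, each = nrow(draws)), nrow = nrow(draws),
                 dimnames = list(NULL, names(fixed)))
    draws <- cbind(draws, fx)
  }
  draws <- draws[, .PARAM_NAMES[.PARAM_NAMES %in% colnames(draws)],
                 drop = FALSE]
  rng <- ranges[free, , drop = FALSE]
  if (length(fixed))
    rng <- rbind(rng, matrix(rep(fixed, 2), ncol = 2,
                             dimnames = list(names(fixed), NULL)))
  colnames(rng) <- c("lower", "upper")
  new("ParameterSamples", draws = draws,
      log_likelihoods = -res$neg_ll, sampler_seed = as.integer(seed),
      ranges = rng[colnames(draws), , drop = FALSE],
      rhat = setNames(res$rhat, free),
      converged = max(res$rhat) <= 1.05)
}

# Seeded adaptive random-walk Metropolis on a box-truncated target.
# Log target = -neg_ll(theta) for theta inside [lower, upper], -Inf outside.
# Proposal: N(0, s * (Sigma_hat + eps I)), Sigma_hat adapted during burn-in
# from the chain history (Haario-style), frozen for the retained phase.
.adaptive_mh <- function(neg_ll, lower, upper, init, n_draws, n_chains,
                         burn, seed, ridge = NULL) {
  d <- length(lower)
  keep_per <- ceiling(n_draws / n_chains)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  all_draws <- vector("list", n_chains)
  all_nll <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed) + 7919L * ch)
    theta <- pmin(upper, pmax(lower, init + rnorm(d, 0, 0.02)))
    f <- neg_ll(theta)
    if (!is.finite(f)) { theta <- (lower + upper) / 2; f <- neg_ll(theta) }
    sd0 <- 0.05 * (upper - lower)
    chol_prop <- diag(sd0, d, d)
    s_glob <- 2.38^2 / d
    hist_mat <- matrix(NA_real_, burn + keep_per, d)
    nll_vec <- numeric(burn + keep_per)
    n_acc <- 0L; n_reg <- 0L
    n_ridge <- if (is.null(ridge)) 0L else nrow(ridge)
    for (it in seq_len(burn + keep_per)) {
      is_ridge <- n_ridge > 0 && runif(1) < 0.2
      if (is_ridge) {
        # move along a weakly constrained direction of the likelihood (the
        # optical scale and the total concentration enter predictions
        # mainly through products with the binding rate constants);
        # symmetric proposal, so the usual acceptance rule applies
        dir_i <- ridge[sample.int(n_ridge, 1), ]
        prop <- theta + rnorm(1, 0, 0.3) * dir_i
      } else {
        prop <- theta + sqrt(s_glob) * as.numeric(chol_prop %*% rnorm(d))
        n_reg <- n_reg + 1L
      }
      if (all(prop >= lower & prop <= upper)) {
        fp <- neg_ll(prop)
        if (is.finite(fp) && log(runif(1)) < f - fp) {
          theta <- prop; f <- fp
          if (!is_ridge) n_acc <- n_acc + 1L
        }
      }
      hist_mat[it, ] <- theta
      nll_vec[it] <- f
      if (it <= burn && it %% 100 == 0 && it >= 200) {
        emp <- stats::cov(hist_mat[max(1, it - 3000):it, , drop = FALSE])
        emp <- emp + diag(1e-8 + 1e-4 * sd0^2, d)
        ch_try <- tryCatch(chol(emp), error = function(e) NULL)
        if (!is.null(ch_try)) chol_prop <- t(ch_try)
        s_glob <- s_glob * exp(0.5 * (n_acc / max(1L, n_reg) - 0.28))
      }
    }
    all_draws[[ch]] <- hist_mat[(burn + 1):(burn + keep_per), ,
                                drop = FALSE]
    all_nll[[ch]] <- nll_vec[(burn + 1):(burn + keep_per)]
  }
  rhat <- vapply(seq_len(d), function(j) {
    .split_rhat(lapply(all_draws, function(m) m[, j]))
  }, numeric(1))
  draws <- do.call(rbind, all_draws)
  nll <- unlist(all_nll)
  take <- seq_len(min(n_draws, nrow(draws)))
  list(draws = draws[take, , drop = FALSE], neg_ll = nll[take],
       rhat = rhat)
}

# flat directions of the profile likelihood in log10 parameter space:
# the data constrain k_in * c * scale and k_on * c * scale (with c the
# free concentration), so jointly raising c_total or scale while lowering
# both binding rate constants leaves predictions nearly unchanged
.ridge_directions <- function(free) {
  dirs <- list()
  mk <- function(plus, minus) {
    v <- setNames(numeric(length(free)), free)
    if (!all(c(plus, minus) %in% free)) return(NULL)
    v[plus] <- 1; v[minus] <- -1
    v
  }
  dirs$c <- mk("c_total", c("k_in", "k_on"))
  dirs$s <- mk("scale", c("k_in", "k_on"))
  dirs <- Filter(Negate(is.null), dirs)
  if (length(dirs) == 0) return(NULL)
  do.call(rbind, dirs)
}

.ridge_directions_joint <- function(shared_free, per_free, strains,
                                    par_names) {
  dirs <- list()
  all_rates <- unlist(lapply(strains, function(s)
    paste0(c("k_in", "k_on"), "_", s)))
  for (s in strains) {
    nm <- paste0(c("k_in", "k_on"), "_", s)
    if ("c_total" %in% per_free && all(nm %in% par_names)) {
      v <- setNames(numeric(length(par_names)), par_names)
      v[paste0("c_total_", s)] <- 1; v[nm] <- -1
      dirs[[paste0("c_", s)]] <- v
    }
  }
  for (glob in c("c_total", "scale")) {
    if (glob %in% shared_free && all(all_rates %in% par_names)) {
      v <- setNames(numeric(length(par_names)), par_names)
      v[glob] <- 1; v[all_rates] <- -1
      dirs[[glob]] <- v
    }
  }
  if (length(dirs) == 0) return(NULL)
  do.call(rbind, dirs)
}

# split-chain potential scale reduction factor
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize likelihood samples
#'
#' Per-parameter median, interquartile range, 1.5 x IQR whiskers (clipped
#' to the data range) and a kernel density estimate. Quantiles use the
#' averaged order-statistic convention (`type = 2`). Derived quantities
#' (expressions over the parameters, evaluated per draw) can be appended.
#'
#' @param samples a [ParameterSamples].
#' @param derived named character vector of expressions over parameter
#'   names, e.g. `c(in_on_ratio = "k_in / k_on")`.
#' @param kde_n grid size of the density estimates.
#' @return list with `table` (data.frame: parameter, median, q25, q75,
#'   iqr, whisker_lo, whisker_hi) and `kde` (named list of
#'   [stats::density()] objects).
#' @export
summarizeSamples <- function(samples, derived = NULL, kde_n = 512) {
  stopifnot(is(samples, "ParameterSamples"))
  if (nrow(samples@draws) < 100)
    stop("need >= 100 draws for summaries")
  df <- as.data.frame(samples@draws)
  for (nm in names(derived))
    df[[nm]] <- eval(parse(text = derived[[nm]]), envir = df)
  rows <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    qs <- quantile(x, c(0.25, 0.5, 0.75), type = 2, names = FALSE)
    iqr <- qs[3] - qs[1]
    data.frame(parameter = nm, median = qs[2], q25 = qs[1], q75 = qs[3],
               iqr = iqr,
               whisker_lo = max(min(x), qs[1] - 1.5 * iqr),
               whisker_hi = min(max(x), qs[3] + 1.5 * iqr))
  })
  kde <- lapply(df, function(x) {
    if (var(x) == 0) NULL else density(x, n = kde_n)
  })
  list(table = do.call(rbind, rows), kde = kde)
}

#' Compare parameters by counting likelihood draws against a predicate
#'
#' For a single sample set, the predicate is an expression over the
#' parameter columns (e.g. `"k_in > k_on"`). For a named list of two
#' sample sets (two strains), each strain's draws are first restricted to
#' the conditioning expression, randomly permuted (seeded), paired by
#' index, and the predicate sees columns suffixed with the strain names
#' (e.g. `"k_in_mut < k_in_wt"`). The reported p-value is the one-sided
#' fraction of draws violating the predicate, floored at `1 / n` when no
#' draw violates it.
#'
#' @param samples a [ParameterSamples] or a named list of exactly two.
#' @param predicate character expression expected to hold.
#' @param conditioning optional character expression restricting draws
#'   (applied per strain), e.g. `"c_total >= 35"`.
#' @param fold optional character expression evaluated on the per-column
#'   medians of the conditioned draws (e.g. `"k_in_wt / k_in_mut"`).
#' @param seed seed for the pairing permutation.
#' @return list with `predicate`, `p_value`, `p_is_floor`, `n_used`,
#'   `fold_difference`, `conditioning`.
#' @export
compareParameters <- function(samples, predicate, conditioning = NULL,
                              fold = NULL, seed = 1) {
  if (is(samples, "ParameterSamples")) {
    df <- as.data.frame(samples@draws)
    if (!is.null(conditioning))
      df <- df[eval(parse(text = conditioning), envir = df), , drop = FALSE]
  } else {
    stopifnot(is.list(samples), length(samples) == 2,
              !is.null(names(samples)))
    parts <- lapply(names(samples), function(nm) {
      d <- as.data.frame(samples[[nm]]@draws)
      if (!is.null(conditioning))
        d <- d[eval(parse(text = conditioning), envir = d), , drop = FALSE]
      names(d) <- paste0(names(d), "_", nm)
      d
    })
    n_pair <- min(vapply(parts, nrow, integer(1)))
    if (n_pair < 100)
      stop("conditioning leaves fewer than 100 draws to pair")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    parts <- lapply(parts, function(d)
      d[sample.int(nrow(d))[seq_len(n_pair)], , drop = FALSE])
    df <- do.call(cbind, lapply(parts, function(d) {
      rownames(d) <- NULL; d
    }))
  }
  if (nrow(df) < 100) stop("conditioning leaves fewer than 100 draws")
  holds <- eval(parse(text = predicate), envir = df)
  n <- length(holds)
  n_viol <- sum(!holds)
  p <- if (n_viol == 0) 1 / n else n_viol / n
  fold_val <- if (!is.null(fold)) {
    med_env <- as.list(vapply(df, median, numeric(1)))
    eval(parse(text = fold), envir = med_env)
  } else NA_real_
  list(predicate = predicate, p_value = p, p_is_floor = n_viol == 0,
       n_used = n, fold_difference = fold_val,
       conditioning = if (is.null(conditioning)) "none" else conditioning)
}

#' Joint likelihood sampling across strains with shared parameters
#'
#' Ties a set of parameters across strains while others are
#' strain-specific, and samples the joint likelihood (the sum of
#' per-strain profile likelihoods). By default `k_in` and `k_on` are
#' per-strain and everything else is shared: the motor's expression level
#' (`c_total`), its stepping and detachment kinetics, and the optical
#' nuisances are properties of the protein and the microscope, not of the
#' regulatory mutants, and sharing `c_total` keeps the cross-strain
#' rate-constant ratios free of the concentration-scale degeneracy.
#' Sharing everything reduces to a pooled single fit.
#'
#' @param datasets named list (>= 2) of `ProfileBins` data.frames.
#' @param sharing list with character vectors `shared` and `per_strain`
#'   partitioning the eight parameter names.
#' @param ranges,n_draws,seed,fixed,config,n_chains,burn as
#'   [sampleLikelihood()].
#' @return named list of [ParameterSamples], one per strain, each carrying
#'   the full eight-parameter draw matrix (shared columns identical across
#'   strains).
#' @export
jointFitStrains <- function(datasets,
                            sharing = list(
                              shared = c("k_step", "k_out", "k_off",
                                         "c_total", "scale", "background"),
                              per_strain = c("k_in", "k_on")),
                            ranges = defaultRanges(), n_draws = 2000,
                            seed = 1, fixed = defaultFixed(),
                            config = forwardConfig(), n_chains = 4,
                            burn = 12000) {
  stopifnot(is.list(datasets), length(datasets) >= 2,
            !is.null(names(datasets)))
  all_named <- sort(c(sharing$shared, sharing$per_strain))
  if (!identical(all_named, sort(.PARAM_NAMES)))
    stop("sharing must partition exactly: ",
         paste(.PARAM_NAMES, collapse = ", "))
  strains <- names(datasets)
  blocks <- lapply(datasets, function(d)
    .attach_render_matrices(.bin_blocks(d), config))
  for (d in datasets) if (any(d$sem_au <= 0))
    stop("all fitted positions must have SEM > 0")
  shared_free <- setdiff(sharing$shared, names(fixed))
  per_free <- setdiff(sharing$per_strain, names(fixed))
  par_names <- c(shared_free,
                 unlist(lapply(strains, function(s) paste0(per_free, "_", s))))
  lower <- log10(c(ranges[shared_free, 1],
                   rep(ranges[per_free, 1], times = length(strains))))
  upper <- log10(c(ranges[shared_free, 2],
                   rep(ranges[per_free, 2], times = length(strains))))
  names(lower) <- names(upper) <- par_names

  expand_strain <- function(theta, s) {
    i_s <- which(strains == s)
    vals <- c(setNames(10^theta[shared_free], shared_free),
              setNames(10^theta[paste0(per_free, "_", s)], per_free),
              fixed)
    p <- vals[.PARAM_NAMES]
    names(p) <- .PARAM_NAMES
    p
  }
  cache <- new.env(parent = emptyenv())
  neg_ll <- function(theta) {
    names(theta) <- par_names
    tot <- 0
    for (s in strains) {
      v <- .neg_ll_blocks(expand_strain(theta, s), blocks[[s]], config,
                          cache = cache, cache_prefix = s)
      if (!is.finite(v)) return(v)
      tot <- tot + v
    }
    tot
  }
  ridge <- .ridge_directions_joint(shared_free, per_free, strains,
                                   par_names)
  # initialization: the likelihood is flat along the concentration/scale
  # product ridge, so each strain's own maximum sits at an arbitrary ridge
  # position and shared parameters must not be averaged across strains.
  # Instead, anchor the shared set on one strain's maximum, refit every
  # other strain's per-strain rates conditionally on those shared values,
  # and keep the anchor whose assembled joint point scores best.
  init_fits <- lapply(seq_along(strains), function(i)
    fitMaximumLikelihood(datasets[[i]], ranges, n_starts = 3,
                         seed = seed + i, fixed = fixed, config = config))
  best_init <- NULL; best_val <- Inf
  for (anchor in seq_along(strains)) {
    shared_vals <- init_fits[[anchor]]$par[shared_free]
    cand <- numeric(length(par_names)); names(cand) <- par_names
    cand[shared_free] <- log10(shared_vals)
    for (i in seq_along(strains)) {
      pars_i <- if (i == anchor) {
        init_fits[[i]]$par
      } else {
        cf <- tryCatch(
          fitMaximumLikelihood(datasets[[i]], ranges, n_starts = 3,
                               seed = seed + 97L * i + anchor,
                               fixed = c(fixed, shared_vals),
                               config = config),
          error = function(e) NULL)
        if (is.null(cf)) init_fits[[i]]$par else cf$par
      }
      for (nm in per_free)
        cand[paste0(nm, "_", strains[i])] <- log10(pars_i[[nm]])
    }
    v <- neg_ll(cand)
    if (is.finite(v) && v < best_val) { best_val <- v; best_init <- cand }
  }
  init <- if (is.null(best_init)) {
    fallback <- numeric(length(par_names)); names(fallback) <- par_names
    fallback[shared_free] <- log10(init_fits[[1]]$par[shared_free])
    for (i in seq_along(strains))
      for (nm in per_free)
        fallback[paste0(nm, "_", strains[i])] <-
          log10(init_fits[[i]]$par[[nm]])
    fallback
  } else best_init
  res <- .adaptive_mh(neg_ll, lower, upper, init, n_draws = n_draws,
                      n_chains = n_chains, burn = burn, seed = seed,
                      ridge = ridge)
  colnames(res$draws) <- par_names
  rhat <- setNames(res$rhat, par_names)
  out <- list()
  for (s in strains) {
    cols <- 10^res$draws
    draws <- matrix(NA_real_, nrow(cols), 0)
    for (nm in .PARAM_NAMES) {
      v <- if (nm %in% shared_free) cols[, nm]
           else if (nm %in% per_free) cols[, paste0(nm, "_", s)]
           else rep(fixed[[nm]], nrow(cols))
      draws <- cbind(draws, v)
    }
    colnames(draws) <- .PARAM_NAMES
    rng <- .full_ranges(ranges, fixed)
    out[[s]] <- new("ParameterSamples", draws = draws,
                    log_likelihoods = -res$neg_ll,
                    sampler_seed = as.integer(seed), ranges = rng,
                    rhat = rhat, converged = max(rhat) <= 1.05)
  }
  out
}

.full_ranges <- function(ranges, fixed) {
  rng <- ranges[setdiff(.PARAM_NAMES, names(fixed)), , drop = FALSE]
  if (length(fixed))
    rng <- rbind(rng, matrix(rep(fixed, 2), ncol = 2,
                             dimnames = list(names(fixed), NULL)))
  colnames(rng) <- c("lower", "upper")
  rng[.PARAM_NAMES, , drop = FALSE]
}

#' Write likelihood samples as a tidy table
#'
#' One row per draw, one column per parameter, plus `log_likelihood`.
#' @param samples a [ParameterSamples].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeSamplesCSV <- function(samples, path) {
  df <- as.data.frame(samples@draws)
  df$log_likelihood <- samples@log_likelihoods
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
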