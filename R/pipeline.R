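#' Run a pipeline subcommand
#'
#' Orchestrates the package's modules as reproducible, seeded runs that
#' read a structured YAML config and write CSV/JSON artifacts plus the
#' fully resolved configuration next to the outputs. Subcommands:
#'
#' * `generate` — synthetic profile, SPB, speckle and dynamics datasets
#'   from a named preset truth.
#' * `quantify` — align raw line scans, bin them, and run the plus-end
#'   regression and speckle-speed statistics.
#' * `fit` — multi-start maximum-likelihood fit of binned profiles.
#' * `sample` — likelihood sampling plus parameter summaries.
#' * `compare` — cross-parameter or cross-strain draw-counting tests.
#' * `reproduce` — end-to-end synthetic reproduction of the headline
#'   strain comparisons (wild type vs the loading and landing mutants).
#'
#' All randomness flows from the single top-level seed through named
#' per-module substreams. Identical config and seed give identical result
#' tables.
#'
#' @param subcommand one of the names above.
#' @param config a named list or a path to a YAML file. Recognized keys
#'   include `preset`, `n_draws`, `n_cells`, `n_tracks`, `datasets`, and a
#'   `constants` block defaulting to [kip2Constants()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param verbose print progress.
#' @return named list of artifact paths, invisibly.
#' @export
runPipeline <- function(subcommand, config = list(), out_dir = tempdir(),
                        seed = 1L, verbose = FALSE) {
  subcommands <- c("generate", "quantify", "fit", "sample", "compare",
                   "reproduce")
  if (!subcommand %in% subcommands)
    stop("unknown subcommand '", subcommand, "'; usage: one of ",
         paste(subcommands, collapse = ", "))
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  resolved <- utils::modifyList(
    list(subcommand = subcommand, seed = as.integer(seed),
         preset = "wt", n_draws = 2000L, n_cells = 1407L, n_tracks = 192L,
         constants = kip2Constants()),
    config)
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- list(config = file.path(out_dir, "resolved_config.json"))
  truth <- truthConfig(resolved$preset, seed = seed)

  if (subcommand == "generate") {
    say("generating synthetic datasets (preset ", resolved$preset, ")")
    prof <- generateProfileDataset(truth, seed = seed)
    spb <- generateSpbDataset(truth, resolved$n_cells, seed = seed)
    tracks <- generateSpeckleTracks(truth, resolved$n_tracks, seed = seed)
    artifacts$bins <- .write_with_header(
      prof$bins, file.path(out_dir, "profile_bins.csv"), resolved)
    scans_df <- do.call(rbind, prof$scans)
    artifacts$scans <- .write_with_header(
      scans_df, file.path(out_dir, "line_scans.csv"), resolved)
    artifacts$spb <- .write_with_header(
      spb, file.path(out_dir, "spb_cells.csv"), resolved)
    artifacts$tracks <- .write_with_header(
      tracks, file.path(out_dir, "speckle_tracks.csv"), resolved)
    jsonlite::write_json(prof$truth_sidecar,
                         file.path(out_dir, "truth_sidecar.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$truth <- file.path(out_dir, "truth_sidecar.json")
  } else if (subcommand == "quantify") {
    scans_path <- config$scans %||% file.path(out_dir, "line_scans.csv")
    scans_df <- .read_skipping_header(scans_path)
    say("aligning ", length(unique(scans_df$cell_id)), " line scans")
    profiles <- lapply(split(scans_df, scans_df$cell_id), alignLineScan)
    bins <- binProfiles(profiles,
                        bin_size = resolved$constants$bin_nm)
    artifacts$bins <- .write_with_header(
      bins, file.path(out_dir, "quantified_bins.csv"), resolved)
    reg <- tryCatch(plusEndRegression(bins), error = function(e) NULL)
    tracks_path <- config$tracks %||%
      file.path(out_dir, "speckle_tracks.csv")
    speeds <- if (file.exists(tracks_path)) {
      tr <- .read_skipping_header(tracks_path)
      speckleSpeed(tr$start_frame, tr$start_px, tr$end_frame, tr$end_px)
    } else numeric(0)
    rejected <- vapply(profiles, isRejectedScan, logical(1))
    summary_doc <- list(
      n_profiles = sum(!rejected),
      n_rejected = sum(rejected),
      plus_end_slope_au_per_nm = if (is.null(reg)) NA else reg$slope,
      mean_speckle_speed_um_min = if (length(speeds)) mean(speeds) else NA)
    jsonlite::write_json(summary_doc,
                         file.path(out_dir, "quantify_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$summary <- file.path(out_dir, "quantify_summary.json")
  } else if (subcommand %in% c("fit", "sample")) {
    bins_path <- config$bins %||% file.path(out_dir, "profile_bins.csv")
    bins <- .read_skipping_header(bins_path)
    if (subcommand == "fit") {
      say("maximum-likelihood fit")
      fit <- fitMaximumLikelihood(bins, seed = seed)
      jsonlite::write_json(
        list(par = as.list(fit$par), neg_log_likelihood = fit$value,
             at_boundary = fit$at_boundary),
        file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      artifacts$fit <- file.path(out_dir, "fit.json")
    } else {
      say("likelihood sampling (", resolved$n_draws, " draws)")
      smp <- sampleLikelihood(bins, n_draws = resolved$n_draws,
                              seed = seed)
      artifacts$samples <- writeSamplesCSV(
        smp, file.path(out_dir, "likelihood_samples.csv"))
      summ <- summarizeSamples(smp,
                               derived = c(in_on_ratio = "k_in / k_on"))
      write.csv(summ$table, file.path(out_dir, "parameter_summary.csv"),
                row.names = FALSE, quote = FALSE)
      artifacts$summary <- file.path(out_dir, "parameter_summary.csv")
    }
  } else if (subcommand == "compare") {
    paths <- config$samples
    if (is.null(paths) || length(paths) != 2 || is.null(names(paths)))
      stop("compare needs config$samples: two named CSV paths")
    sets <- lapply(paths, .read_samples_csv)
    cmp <- compareParameters(
      sets, predicate = config$predicate,
      conditioning = config$conditioning %||%
        paste0("c_total >= ", resolved$constants$conditioning_nM),
      fold = config$fold, seed = seed)
    jsonlite::write_json(cmp, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$comparison <- file.path(out_dir, "comparison.json")
  } else if (subcommand == "reproduce") {
    say("end-to-end synthetic reproduction of the strain comparisons")
    artifacts$reproduce <- .reproduce_headline(out_dir, seed, resolved,
                                               say)
  }
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("preset", "n_draws", "n_cells", "n_tracks", "constants",
             "bins", "scans", "tracks", "samples", "predicate",
             "conditioning", "fold")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(config$preset) &&
      !config$preset %in% c("wt", "bfa1bub2", "S63A"))
    stop("config field 'preset' must be one of wt, bfa1bub2, S63A")
  invisible(TRUE)
}

# CSV writers emit a metadata header line with the constants used
.write_with_header <- function(df, path, resolved) {
  cst <- resolved$constants
  header <- sprintf(
    "# pixel_size_nm=%g, frame_interval_s=%g, bin_nm=%g, seed=%d",
    cst$pixel_size_nm, cst$frame_interval_s, cst$bin_nm, resolved$seed)
  con <- file(path, "w")
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  path
}

.read_skipping_header <- function(path) {
  first <- readLines(path, n = 1)
  read.csv(path, skip = if (startsWith(first, "#")) 1 else 0)
}

.read_samples_csv <- function(path) {
  df <- .read_skipping_header(path)
  ll <- df$log_likelihood %||% rep(NA_real_, nrow(df))
  df$log_likelihood <- NULL
  m <- as.matrix(df)
  new("ParameterSamples", draws = m, log_likelihoods = ll,
      sampler_seed = NA_integer_,
      ranges = cbind(lower = apply(m, 2, min), upper = apply(m, 2, max)),
      rhat = rep(NA_real_, ncol(m)), converged = NA)
}

.reproduce_headline <- function(out_dir, seed, resolved, say) {
  n_draws <- resolved$n_draws
  gen <- function(p) generateProfileDataset(truthConfig(p, seed))$bins
  say("fitting wild type")
  wt_smp <- sampleLikelihood(gen("wt"), n_draws = n_draws, seed = seed)
  say("joint fit: wt vs loading mutant")
  j_load <- jointFitStrains(list(wt = gen("wt"), mut = gen("bfa1bub2")),
                            n_draws = n_draws, seed = seed + 1)
  say("joint fit: wt vs landing mutant")
  j_land <- jointFitStrains(list(wt = gen("wt"), mut = gen("S63A")),
                            n_draws = n_draws, seed = seed + 2)
  cond <- paste0("c_total >= ", resolved$constants$conditioning_nM)
  res <- list(
    wt_in_on_ratio = compareParameters(
      wt_smp, "k_in > k_on", fold = "k_in / k_on"),
    loading_mutant_k_in_fold = compareParameters(
      j_load, "k_in_mut < k_in_wt",
      conditioning = sub("c_total", "c_total", cond),
      fold = "k_in_wt / k_in_mut", seed = seed),
    landing_mutant_k_on_fold = compareParameters(
      j_land, "k_on_mut > k_on_wt", conditioning = cond,
      fold = "k_on_mut / k_on_wt", seed = seed),
    landing_mutant_in_on_ratio = compareParameters(
      list(mut = j_land$mut, mut2 = j_land$mut), "k_in_mut > k_on_mut",
      conditioning = cond, fold = "k_in_mut / k_on_mut", seed = seed))
  path <- file.path(out_dir, "reproduction.json")
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}
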