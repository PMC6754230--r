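#' Acquisition and analysis constants
#'
#' The fixed constants of the imaging and quantification conventions:
#' pixel size 133.35 nm (the length bins are 2 pixels = 266.7 nm), stack
#' interval 1.07 s, 5-pixel (666.7 nm) detectability limit, 2 um spindle
#' cutoff, 85.6 s recording window (80 frames), 35 nM total-concentration
#' conditioning bound used in cross-strain likelihood comparisons, and the
#' default 20,000 likelihood draws.
#'
#' @return named list of constants.
#' @export
kip2Constants <- function() {
  list(pixel_size_nm = 133.35,
       frame_interval_s = 1.07,
       bin_nm = 266.7,
       detect_limit_nm = 666.7,
       spindle_max_um = 2.0,
       window_s = 85.6,
       n_frames = 80L,
       conditioning_nM = 35,
       n_draws = 20000L,
       site_length_nm = 8)
}
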