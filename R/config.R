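# Central registry of analysis constants. Every numeric constant of the
# pipeline lives here (and only here): stage code must pull values from
# gazerp_defaults()/run_config() rather than repeating literals, so that a
# single edit changes the behaviour everywhere and the defaults can be
# audited in one place.

.gazerp_defaults <- list(
  ## acquisition geometry / rates
  gaze_rate_hz            = 60,     # remote eye tracker sampling rate
  eeg_rate_hz             = 250,    # EEG amplifier sampling rate
  n_channels              = 128,    # geodesic net size (EGI numbering 1..128)
  target_eccentricity_deg = 12.9,   # horizontal target eccentricity

  ## online gaze-contingent detectors
  fix_radius_deg  = 2.6,            # central-fixation dispersion limit (strict <)
  fix_n_samples   = 20,             # consecutive samples (~330 ms at 60 Hz)
  acq_half_box_deg = 4,             # half-extent of the 8 x 8 deg target box
  acq_n_samples   = 20,

  ## post-hoc gaze analysis
  saccade_step_deg   = 2.2,         # suprathreshold inter-sample displacement
  noisy_fraction_max = 0.2,         # rule 2: max fraction of large excursions
  anticipatory_min_s = 0.1,         # rule 3: earliest stimulus-driven saccade
  sticky_max_s       = 5,           # no response within 5 s -> sticky fixation
  screen_half_x_deg  = 19.6,        # rule 1 tolerance box, horizontal
  screen_half_y_deg  = 11.0,        # rule 1 tolerance box, vertical

  ## timing corrections
  tracker_processing_ms      = 30,  # eye-tracker internal processing delay
  refresh_asynchrony_max_ms  = NA,  # one display frame; filled in below
  refresh_asynchrony_mean_ms = NA,  # uniform mean: half a frame
  gating_correction_ms       = 50,  # fixed correction when gating EEG epochs
  amp_delay_ms               = 24,  # EEG amplifier group delay

  ## EEG conditioning
  notch_band_hz = c(49, 51),
  highpass_hz   = 0.01,
  lowpass_hz    = 25,
  filter_order  = 4,
  min_filter_duration_s = 10,

  ## epoching and screening
  epoch_window_ms    = c(-200, 180),  # half-open [-200, 180)
  mad_multiplier     = 3,
  mad_consistency    = 1.483,         # normal-consistency rescaling of the MAD
  min_clean_channels = 70,            # strictly more than this many required
  sd_floor_uv        = 0.1,           # criterion (e): electrode received signal
  early_saccade_ms   = 180,           # corrected-latency gate

  ## ERP measurement
  peak_window_ms       = c(80, 180),  # occipital / frontocentral search window
  prefrontal_window_ms = c(120, 180),
  spline_order_m       = 4,           # spherical-spline stiffness
  spline_n_terms       = 20,          # Legendre series truncation
  fp_cluster_size      = 6            # nearest neighbours forming FP1/FP2
)
.gazerp_defaults$refresh_asynchrony_max_ms <-
  1000 / .gazerp_defaults$gaze_rate_hz
.gazerp_defaults$refresh_asynchrony_mean_ms <-
  1000 / (2 * .gazerp_defaults$gaze_rate_hz)

#' Default analysis parameters
#'
#' Returns the full set of pipeline constants: gaze-contingent detector
#' geometry, exclusion-rule thresholds, timing corrections, filter corner
#' frequencies, epoch window, robust-screening parameters and ERP search
#' windows. All stage functions take their defaults from this list, so the
#' constants are defined exactly once.
#'
#' @param name Optional name of a single parameter to extract.
#' @return A named list of parameters, or a single value if `name` is given.
#' @export
#' @examples
#' gazerp_defaults("saccade_step_deg")
gazerp_defaults <- function(name = NULL) {
  if (is.null(name)) return(.gazerp_defaults)
  if (!name %in% names(.gazerp_defaults))
    stop("unknown parameter: ", name, call. = FALSE)
  .gazerp_defaults[[name]]
}

#' Run configuration
#'
#' Merge user overrides into the default parameter set. Unknown parameter
#' names are rejected so misspelled overrides fail loudly.
#'
#' @param ... Named parameter overrides (see [gazerp_defaults()]).
#' @return A named list with class `gazerp_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  cfg <- .gazerp_defaults
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all overrides must be named", call. = FALSE)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  structure(cfg, class = "gazerp_config")
}

#' Saccade velocity threshold implied by the displacement criterion
#'
#' The post-hoc saccade detector flags an inter-sample horizontal
#' displacement larger than a fixed angle; at the tracker's sampling rate
#' this corresponds to an angular velocity of `step_deg * rate_hz` deg/s.
#'
#' @param step_deg Displacement criterion in degrees of visual angle.
#' @param rate_hz Gaze sampling rate in Hz.
#' @return Velocity threshold in degrees per second.
#' @export
#' @examples
#' velocity_threshold_dps()  # 132 deg/s
velocity_threshold_dps <- function(step_deg = gazerp_defaults("saccade_step_deg"),
                                   rate_hz = gazerp_defaults("gaze_rate_hz")) {
  step_deg * rate_hz
}

#' Latency corrections between display, tracker and EEG timelines
#'
#' Bundles the delays relevant when fusing eye-tracking with EEG: tracker
#' internal processing, the display-refresh asynchrony (at a 60 Hz refresh
#' the delay is at most one frame and half a frame on average), and the
#' fixed correction applied when eye-tracking latencies gate EEG epochs.
#' The fixed gating correction must cover at least the mean total delay.
#'
#' @param tracker_processing_ms Tracker processing delay (ms).
#' @param refresh_asynchrony_max_ms Maximum refresh asynchrony (ms).
#' @param refresh_asynchrony_mean_ms Mean refresh asynchrony (ms).
#' @param fixed_gating_correction_ms Fixed correction used for epoch gating (ms).
#' @return A named list with class `latency_corrections`.
#' @export
latency_corrections <- function(
    tracker_processing_ms = gazerp_defaults("tracker_processing_ms"),
    refresh_asynchrony_max_ms = gazerp_defaults("refresh_asynchrony_max_ms"),
    refresh_asynchrony_mean_ms = gazerp_defaults("refresh_asynchrony_mean_ms"),
    fixed_gating_correction_ms = gazerp_defaults("gating_correction_ms")) {
  if (fixed_gating_correction_ms <
      tracker_processing_ms + refresh_asynchrony_mean_ms)
    stop("fixed gating correction must cover tracker processing plus mean ",
         "refresh asynchrony", call. = FALSE)
  structure(list(tracker_processing_ms = tracker_processing_ms,
                 refresh_asynchrony_max_ms = refresh_asynchrony_max_ms,
                 refresh_asynchrony_mean_ms = refresh_asynchrony_mean_ms,
                 fixed_gating_correction_ms = fixed_gating_correction_ms),
            class = "latency_corrections")
}

#' Pooled-SD Cohen's d
#'
#' Standardized mean difference using the pooled standard deviation of the
#' two groups, \eqn{d = |M_1 - M_2| / \sqrt{(SD_1^2 + SD_2^2)/2}}.
#'
#' @param m1,s1 Mean and SD of group 1.
#' @param m2,s2 Mean and SD of group 2.
#' @return Non-negative effect size.
#' @export
#' @examples
#' cohens_d(0.308, 0.038, 0.480, 0.098)
cohens_d <- function(m1, s1, m2, s2) {
  pooled <- sqrt((s1^2 + s2^2) / 2)
  if (!is.finite(pooled) || pooled <= 0)
    stop("pooled SD is not positive; d undefined", call. = FALSE)
  abs(m1 - m2) / pooled
}
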