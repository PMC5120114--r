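# Synthetic co-registered session generator. Emulates a two-block
# fixation-shift session (manual-response block first, then saccade block)
# with the statistical structure the downstream analysis assumes: shifted
# lognormal response latencies with a double-target cost, three early ERP
# components with condition-dependent amplitude/latency and idealized scalp
# topographies, saccade artifacts, 1/f + white + 50 Hz line noise, missing
# gaze samples, behavioural anomalies and bad channels. A ground-truth log
# accompanies every session so recovery can be tested quantitatively.

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.cells <- c("saccade_1", "saccade_2", "manual_1", "manual_2")

#' Response-latency model of the synthetic session
#'
#' Shifted lognormal latencies per (response type x number of targets) cell.
#' Defaults echo the observed marginal means (saccadic 0.308 s, manual
#' 0.480 s) split by the reference double-target cost of 0.024 s, with the
#' marginal SDs (0.038 s saccadic, 0.098 s manual) and an 80 ms shift
#' giving the right-skew typical of empirical saccade latencies.
#'
#' @param means_s Named numeric: mean latency (s) per cell
#'   `saccade_1`, `saccade_2`, `manual_1`, `manual_2`.
#' @param sds_s Named numeric: SD (s) per cell.
#' @param shift_s Lognormal shift (s).
#' @return Data frame with one row per cell and the lognormal parameters.
#' @export
latency_model <- function(
    means_s = c(saccade_1 = 0.296, saccade_2 = 0.320,
                manual_1 = 0.468, manual_2 = 0.492),
    sds_s = c(saccade_1 = 0.038, saccade_2 = 0.038,
              manual_1 = 0.098, manual_2 = 0.098),
    shift_s = 0.080) {
  stopifnot(all(.cells %in% names(means_s)), all(.cells %in% names(sds_s)),
            all(means_s > shift_s), all(sds_s > 0))
  m <- means_s[.cells] - shift_s
  s <- sds_s[.cells]
  sigma2 <- log(1 + s^2 / m^2)
  data.frame(cell = .cells, mean_s = means_s[.cells], sd_s = s,
             shift_s = shift_s, mu_log = log(m) - sigma2 / 2,
             sigma_log = sqrt(sigma2), row.names = NULL)
}

.draw_latency <- function(model, cell, n, rng_ready = TRUE) {
  r <- model[model$cell == cell, ]
  r$shift_s + stats::rlnorm(n, r$mu_log, r$sigma_log)
}

#' ERP component specification
#'
#' One early ERP component of the synthetic EEG: a Gaussian time course
#' (width `temporal_sd_ms`, small trial-to-trial latency jitter) scaled by a
#' signed amplitude per condition cell and projected onto an idealized scalp
#' topography centred on the component's electrode-cluster sites. For
#' single-target trials the topography may be lateralized
#' (`contra_ratio` < 1 weights the hemisphere contralateral to the responded
#' side less than the ipsilateral one); double-target trials are symmetric.
#' Topographies are normalized so that, after average referencing, the mean
#' over the component's own cluster channels equals the specified amplitude
#' — this makes the injected amplitude directly recoverable from cluster
#' waveforms.
#'
#' @param name Component name.
#' @param sites Anchor sites, a subset of `c("O1","O2","FC3","FC4","FP1","FP2")`
#'   (a left/right pair).
#' @param amplitude_uV Named signed peak amplitude per cell (0 = absent).
#' @param peak_latency_ms Named peak latency per cell (ms after target onset).
#' @param temporal_sd_ms Gaussian time-course SD (ms); must be positive.
#' @param latency_jitter_ms SD of trial-to-trial peak-latency jitter (ms).
#' @param contra_ratio Contralateral/ipsilateral topography weight for
#'   single-target trials.
#' @return An `erp_component` list.
#' @export
erp_component <- function(name, sites, amplitude_uV, peak_latency_ms,
                          temporal_sd_ms = 20, latency_jitter_ms = 2,
                          contra_ratio = 1) {
  stopifnot(temporal_sd_ms > 0, all(.cells %in% names(amplitude_uV)),
            all(.cells %in% names(peak_latency_ms)),
            all(is.finite(unlist(amplitude_uV))))
  structure(list(name = name, sites = sites,
                 amplitude_uV = amplitude_uV[.cells],
                 peak_latency_ms = peak_latency_ms[.cells],
                 temporal_sd_ms = temporal_sd_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 contra_ratio = contra_ratio),
            class = "erp_component")
}

#' Default ERP components of the synthetic session
#'
#' Three components with amplitudes and latencies echoing the observed
#' condition means: an occipital positivity (larger for single than double
#' targets, ipsilateral-dominant for single targets, peaking ~141 ms), a
#' frontocentral negativity (~136 ms), and a prefrontal positivity confined
#' to manual-response and double-target cells, peaking late in the analysis
#' window (~146-154 ms).
#'
#' @return List of [erp_component()] specs.
#' @export
default_components <- function() {
  list(
    erp_component("occipital_positivity", c("O1", "O2"),
      amplitude_uV = c(saccade_1 = 2.01, saccade_2 = 0.83,
                       manual_1 = 2.01, manual_2 = 0.83),
      peak_latency_ms = c(saccade_1 = 150, saccade_2 = 140,
                          manual_1 = 142, manual_2 = 132),
      contra_ratio = 0.7),
    erp_component("frontal_negativity", c("FC3", "FC4"),
      amplitude_uV = c(saccade_1 = -1.18, saccade_2 = -1.18,
                       manual_1 = -1.18, manual_2 = -1.18),
      peak_latency_ms = c(saccade_1 = 146, saccade_2 = 138,
                          manual_1 = 134, manual_2 = 126)),
    erp_component("prefrontal_positivity", c("FP1", "FP2"),
      amplitude_uV = c(saccade_1 = 0, saccade_2 = 1.194,
                       manual_1 = 1.684, manual_2 = 1.796),
      peak_latency_ms = c(saccade_1 = NA, saccade_2 = 146,
                          manual_1 = 154, manual_2 = 154),
      temporal_sd_ms = 15)
  )
}

#' Synthetic session configuration
#'
#' The generator's study conditions: 400 trials per response block
#' (100 left / 100 right / 200 double), inter-trial interval uniform on
#' 0.5-2.5 s, 60 Hz gaze and 250 Hz 128-channel EEG, shifted lognormal
#' latencies, three ERP components, saccade artifacts, 1/f + white + line
#' noise, missing gaze samples, rare behavioural anomalies and a small set
#' of bad channels.
#'
#' @param n_trials_per_block Trials in each of the two response blocks.
#' @param condition_proportions Fractions of left / right / double-target
#'   trials; must sum to 1.
#' @param iti_range_s Uniform inter-trial-interval range (s).
#' @param latency_model See [latency_model()].
#' @param components List of [erp_component()] specs.
#' @param artifact_spec Saccade-artifact parameters: `step_uv`,
#'   `transient_uv`, `transient_tau_ms`, `duration_s`.
#' @param noise_spec Background-noise parameters: `white_sd_uv`,
#'   `pink_sd_uv`, `pink_exponent`, `line_amp_uv`, `line_freq_hz`,
#'   `bad_channel_sd_uv`.
#' @param p_missing_sample,p_anticipatory,p_sticky,p_misdirected Anomaly
#'   probabilities, each in [0, 1].
#' @param bad_channels Integer EGI ids overwritten with high-variance noise.
#' @param fixation_sd_deg Gaussian gaze jitter around fixation (deg).
#' @param post_window_s Scheduled post-onset trial duration (s).
#' @param seed Master seed; per-trial substreams are derived from it.
#' @param amp_delay_ms Emulated amplifier delay: the recorded EEG lags the
#'   trigger timeline by this amount (ms).
#' @param gaze_rate_hz,eeg_rate_hz,n_channels,target_eccentricity_deg
#'   Acquisition geometry (defaults from [gazerp_defaults()]).
#' @return A `session_config` list.
#' @export
session_config <- function(
    n_trials_per_block = 400,
    condition_proportions = c(left = 0.25, right = 0.25, double = 0.5),
    iti_range_s = c(0.5, 2.5),
    latency_model = gazerp::latency_model(),
    components = default_components(),
    artifact_spec = list(step_uv = 60, transient_uv = 80,
                         transient_tau_ms = 15, duration_s = 0.4),
    noise_spec = list(white_sd_uv = 1.0, pink_sd_uv = 1.4,
                      pink_exponent = 1, line_amp_uv = 10,
                      line_freq_hz = 50, bad_channel_sd_uv = 40,
                      channel_gain_sd_log = 0.2),
    p_missing_sample = 0.02,
    p_anticipatory = 0.005,
    p_sticky = 0.005,
    p_misdirected = 0.005,
    bad_channels = c(17L, 53L, 108L),
    fixation_sd_deg = 0.3,
    post_window_s = 1.0,
    seed = 1L,
    amp_delay_ms = gazerp_defaults("amp_delay_ms"),
    gaze_rate_hz = gazerp_defaults("gaze_rate_hz"),
    eeg_rate_hz = gazerp_defaults("eeg_rate_hz"),
    n_channels = gazerp_defaults("n_channels"),
    target_eccentricity_deg = gazerp_defaults("target_eccentricity_deg")) {
  probs <- c(p_missing_sample, p_anticipatory, p_sticky, p_misdirected)
  if (abs(sum(condition_proportions) - 1) > 1e-8)
    stop("condition proportions must sum to 1", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("anomaly probabilities must lie in [0, 1]", call. = FALSE)
  if (gaze_rate_hz <= 0 || eeg_rate_hz <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  if (n_trials_per_block < 0)
    stop("n_trials_per_block must be non-negative", call. = FALSE)
  stopifnot(length(iti_range_s) == 2, iti_range_s[1] <= iti_range_s[2],
            all(latency_model$mean_s > 0))
  structure(as.list(environment()), class = "session_config")
}

#' Noise-free session configuration
#'
#' Convenience wrapper over [session_config()] that disables every
#' stochastic nuisance (noise, artifacts handled downstream, anomalies,
#' missing samples, gaze jitter, latency jitter, bad channels) so the
#' downstream pipeline should recover every injected quantity to grid
#' resolution.
#'
#' @param ... Passed to [session_config()].
#' @return A `session_config`.
#' @export
session_config_noiseless <- function(...) {
  comps <- lapply(default_components(), function(cp) {
    cp$latency_jitter_ms <- 0
    cp
  })
  args <- list(
    noise_spec = list(white_sd_uv = 0, pink_sd_uv = 0, pink_exponent = 1,
                      line_amp_uv = 0, line_freq_hz = 50,
                      bad_channel_sd_uv = 0, channel_gain_sd_log = 0),
    p_missing_sample = 0, p_anticipatory = 0, p_sticky = 0,
    p_misdirected = 0, bad_channels = integer(0),
    fixation_sd_deg = 0, components = comps)
  over <- list(...)
  args[names(over)] <- over
  do.call(session_config, args)
}

# deterministic condition counts: largest-remainder apportionment
.condition_counts <- function(n, props) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base
}

#' Build the trial schedule of a synthetic session
#'
#' Two response blocks (manual first, then saccade), each containing
#' `n_trials_per_block` trials whose conditions follow
#' `condition_proportions` exactly (largest-remainder rounding) in a
#' shuffled order. Target onsets are separated by the previous trial's
#' scheduled duration plus an inter-trial interval drawn uniformly from
#' `iti_range_s`.
#'
#' @param config A [session_config()].
#' @return Data frame: `trial_id`, `block`, `condition`, `iti_s`,
#'   `target_onset_s`, `trial_end_s`.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials_per_block
  conds <- names(config$condition_proportions)
  if (is.null(conds)) conds <- c("left", "right", "double")
  counts <- .condition_counts(n, config$condition_proportions)
  sched <- with_seed(config$seed, {
    one_block <- function(block) {
      cond <- sample(rep(conds, counts))
      iti <- stats::runif(n, config$iti_range_s[1], config$iti_range_s[2])
      data.frame(block = rep(block, n), condition = cond, iti_s = iti,
                 stringsAsFactors = FALSE)
    }
    rbind(one_block("manual"), one_block("saccade"))
  })
  if (nrow(sched) == 0)
    return(data.frame(trial_id = integer(0), block = character(0),
                      condition = character(0), iti_s = numeric(0),
                      target_onset_s = numeric(0), trial_end_s = numeric(0)))
  sched$trial_id <- seq_len(nrow(sched))
  lead_in <- 5  # quiet EEG before the first trial
  onset <- numeric(nrow(sched))
  prev_end <- lead_in
  for (i in seq_len(nrow(sched))) {
    onset[i] <- prev_end + sched$iti_s[i]
    prev_end <- onset[i] + config$post_window_s
  }
  sched$target_onset_s <- onset
  sched$trial_end_s <- onset + config$post_window_s
  sched[, c("trial_id", "block", "condition", "iti_s", "target_onset_s",
            "trial_end_s")]
}

.cell_of <- function(block, condition) {
  paste(block, ifelse(condition == "double", 2L, 1L), sep = "_")
}

# draw a trial's behavioural truth (latency, anomaly, responded side)
.draw_trial_truth <- function(trial, config) {
  cell <- .cell_of(trial$block, trial$condition)
  u <- stats::runif(3)
  anomaly <- "none"
  if (u[1] < config$p_anticipatory) anomaly <- "anticipatory"
  else if (u[2] < config$p_sticky) anomaly <- "sticky"
  else if (u[3] < config$p_misdirected && trial$condition != "double")
    anomaly <- "misdirected"
  lat <- switch(anomaly,
    anticipatory = stats::runif(1, 0.02, 0.08),
    sticky = NA_real_,
    .draw_latency(config$latency_model, cell, 1))
  side <- switch(trial$condition,
    left = "left", right = "right",
    double = sample(c("left", "right"), 1))
  if (anomaly == "misdirected")
    side <- if (trial$condition == "left") "right" else "left"
  if (anomaly == "sticky") side <- NA_character_
  list(cell = cell, anomaly = anomaly, latency_s = lat, side = side)
}

#' Synthesize one trial's gaze trace
#'
#' 60 Hz gaze samples on the session clock covering the trial: Gaussian
#' jitter around central fixation and, for saccade-block trials, a linear
#' 3-sample ramp to the target eccentricity starting at the injected
#' latency. Anomalies (anticipatory / sticky / misdirected) and missing
#' samples are injected per the configured probabilities; the matching
#' ground-truth record is returned alongside.
#'
#' @param trial One row of the schedule from [build_schedule()].
#' @param config A [session_config()].
#' @param seed Integer substream seed for this trial.
#' @return List with elements `trace` (a `gaze_trace`) and `truth`.
#' @export
synth_gaze_trial <- function(trial, config, seed) {
  with_seed(seed, {
    truth <- .draw_trial_truth(trial, config)
    rate <- config$gaze_rate_hz
    onset <- trial$target_onset_s
    pre <- 0.5
    post <- if (identical(truth$anomaly, "sticky"))
      config$sticky_horizon_s %||% (gazerp_defaults("sticky_max_s") + 0.3)
    else (if (trial$block == "saccade" && is.finite(truth$latency_s))
            truth$latency_s else 0.5) + 0.5
    i0 <- ceiling((onset - pre) * rate)
    i1 <- floor((onset + post) * rate)
    times <- (i0:i1) / rate
    ns <- length(times)
    x <- stats::rnorm(ns, 0, config$fixation_sd_deg)
    y <- stats::rnorm(ns, 0, config$fixation_sd_deg)
    makes_saccade <- trial$block == "saccade" && !is.na(truth$latency_s)
    if (makes_saccade) {
      ecc <- config$target_eccentricity_deg *
        (if (truth$side == "right") 1 else -1)
      k <- which(times >= onset + truth$latency_s)[1]
      if (!is.na(k)) {
        ramp <- seq(k, min(k + 2, ns))
        x[ramp] <- x[ramp] + ecc * seq_along(ramp) / 3
        if (k + 3 <= ns) x[(k + 3):ns] <- x[(k + 3):ns] + ecc
      }
    }
    valid <- stats::runif(ns) >= config$p_missing_sample
    trace <- gaze_trace(times = times, x = x, y = y, valid = valid,
                        target_onset_s = onset, condition = trial$condition,
                        block = trial$block, trial_id = trial$trial_id)
    # behavioural response event (button press in the manual block,
    # saccade completion in the saccade block)
    resp_time <- if (is.na(truth$latency_s)) NA_real_
      else onset + truth$latency_s
    list(trace = trace,
         truth = data.frame(trial_id = trial$trial_id, block = trial$block,
                            condition = trial$condition, cell = truth$cell,
                            anomaly = truth$anomaly,
                            injected_latency_s = truth$latency_s,
                            responded_side = truth$side %||% NA_character_,
                            response_time_s = resp_time,
                            stringsAsFactors = FALSE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smooth scalp weight map centred on a pair of anchor sites, lateralized
# for single-target trials; unnormalized, uncentred
.component_raw_map <- function(comp, side, n_targets, layout) {
  anchors <- .site_anchors()
  pos <- as.matrix(layout[, c("x", "y", "z")])
  gauss <- function(site) {
    cosang <- pmin(1, pmax(-1, drop(pos %*% anchors[[site]])))
    ang <- acos(cosang) * 180 / pi
    exp(-ang^2 / (2 * 25^2))
  }
  left_site <- comp$sites[1]; right_site <- comp$sites[2]
  wl <- gauss(left_site); wr <- gauss(right_site)
  if (n_targets == 2) wl + wr
  else if (side == "left") wl + comp$contra_ratio * wr   # ipsi = left
  else wr + comp$contra_ratio * wl
}

# topographies of the active components of one trial, mixed so that each
# component's average-referenced map has unit mean over its own cluster
# union and zero mean over the other components' cluster unions: this
# makes the injected per-cell amplitudes identifiable from cluster
# waveforms (an idealization standing in for unknown source geometry).
# Maps are centred over the channels that will actually carry signal
# (bad channels are later overwritten with noise), so the pipeline's
# average reference does not re-introduce cross-cluster leakage.
.component_topographies <- function(comps, side, n_targets, layout,
                                    clusters, bad_channels = integer(0)) {
  k <- length(comps)
  if (!k) return(NULL)
  good <- setdiff(seq_len(nrow(layout)), bad_channels)
  maps <- vapply(comps, function(cp) {
    w <- .component_raw_map(cp, side, n_targets, layout)
    w - mean(w[good])
  }, numeric(nrow(layout)))
  unions <- lapply(comps, function(cp)
    c(clusters[[cp$sites[1]]], clusters[[cp$sites[2]]]))
  M <- matrix(0, k, k)  # M[i, j] = mean of map i over cluster union j
  for (i in seq_len(k)) for (j in seq_len(k))
    M[i, j] <- mean(maps[unions[[j]], i])
  A <- tryCatch(solve(t(M)), error = function(e) NULL)
  if (is.null(A)) {  # degenerate geometry: fall back to own-cluster scaling
    for (i in seq_len(k)) maps[, i] <- maps[, i] / M[i, i]
    return(maps)
  }
  maps %*% A
}

#' Synthesize one trial's EEG contribution
#'
#' Returns the deterministic signal content of one trial as a channels x
#' time block on the continuous recording: the sum of the configured ERP
#' components (Gaussian time course x idealized topography, with
#' condition-dependent amplitude and latency) plus, for saccade-block
#' trials, a lateralized frontal step-plus-transient artifact beginning at
#' the injected saccade onset. Background noise, line noise and bad
#' channels are added at session level by [assemble_session()].
#'
#' @param trial One schedule row.
#' @param truth The trial's truth record from [synth_gaze_trial()].
#' @param config A [session_config()].
#' @param layout Electrode layout.
#' @param clusters Cluster definitions from [erp_clusters()].
#' @param seed Integer substream seed for this trial.
#' @return List: `first_sample` (1-based index on the continuous recording),
#'   `block` (time x channel matrix), `component_truth` (injected per-trial
#'   peak latency/amplitude per component).
#' @export
synth_eeg_trial <- function(trial, truth, config, layout, clusters, seed) {
  with_seed(seed, {
    fs <- config$eeg_rate_hz
    # the amplifier delays the recorded EEG relative to the trigger
    # timeline, so signal content sits `amp_delay_ms` later than the
    # event sample index written to the events table
    delay <- round((config$amp_delay_ms %||% 0) / 1000 * fs)
    onset_idx <- round(trial$target_onset_s * fs) + 1L + delay
    i0 <- onset_idx - round(0.25 * fs)
    i1 <- onset_idx + round(0.6 * fs)
    nt <- i1 - i0 + 1L
    t_ms <- ((i0:i1) - onset_idx) / fs * 1000  # ms relative to target onset
    nch <- config$n_channels
    seg <- matrix(0, nt, nch)
    cell <- truth$cell
    n_targets <- if (trial$condition == "double") 2L else 1L
    side <- truth$responded_side
    comp_rows <- list()
    active <- Filter(function(cp) {
      a <- cp$amplitude_uV[[cell]]
      !is.na(a) && a != 0
    }, config$components)
    topo <- .component_topographies(active, if (is.na(side)) "left" else side,
                                    n_targets, layout, clusters,
                                    config$bad_channels)
    for (ci in seq_along(active)) {
      comp <- active[[ci]]
      amp <- comp$amplitude_uV[[cell]]
      lat <- comp$peak_latency_ms[[cell]] +
        stats::rnorm(1, 0, comp$latency_jitter_ms)
      tc <- amp * exp(-(t_ms - lat)^2 / (2 * comp$temporal_sd_ms^2))
      seg <- seg + tcrossprod(tc, topo[, ci])
      comp_rows[[comp$name]] <- data.frame(
        trial_id = trial$trial_id, component = comp$name, cell = cell,
        injected_amplitude_uV = amp, injected_latency_ms = lat,
        stringsAsFactors = FALSE)
    }
    if (trial$block == "saccade" && is.finite(truth$injected_latency_s)) {
      sp <- config$artifact_spec
      t_sac_ms <- truth$injected_latency_s * 1000
      on <- t_ms >= t_sac_ms & t_ms < t_sac_ms + sp$duration_s * 1000
      if (any(on)) {
        dirsign <- if (identical(side, "right")) 1 else -1
        anchors <- .site_anchors()
        pos <- as.matrix(layout[, c("x", "y", "z")])
        wart <- drop(pos %*% (anchors$FP2 - anchors$FP1)) * dirsign
        art <- numeric(nt)
        art[on] <- sp$step_uv +
          sp$transient_uv * exp(-(t_ms[on] - t_sac_ms) / sp$transient_tau_ms)
        seg <- seg + tcrossprod(art, wart)
      }
    }
    list(first_sample = i0, block = seg,
         component_truth = if (length(comp_rows))
           do.call(rbind, comp_rows) else NULL)
  })
}

# 1/f^alpha noise via spectral shaping, unit variance before scaling
.pink_noise <- function(n, alpha) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(nfft)
  spec <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1))  # avoid dividing by zero at DC
  f <- pmin(f, nfft - f + 1)    # symmetric frequency index
  spec <- spec / f^(alpha / 2)
  spec[1] <- 0
  out <- Re(stats::fft(spec, inverse = TRUE)) / nfft
  out <- out[seq_len(n)]
  out / stats::sd(out)
}

#' Assemble a complete synthetic session
#'
#' Builds the schedule, synthesizes every trial's gaze trace and EEG
#' contribution, overlays session-level background noise (white + 1/f +
#' line), overwrites the configured bad channels with high-variance noise,
#' and collects the ground-truth log. Identical seeds give identical
#' sessions.
#'
#' @param config A [session_config()].
#' @param layout Electrode layout (defaults to the synthetic net geometry).
#' @return A `gazerp_session` list: `gaze` (list of `gaze_trace`), `events`
#'   data frame, `eeg` ([eeg_recording()]), `layout`, `truth` (list with
#'   `trials`, `components`, `bad_channels`, `config_seed`).
#' @export
assemble_session <- function(config, layout = synthetic_egi_layout()) {
  stopifnot(inherits(config, "session_config"))
  sched <- build_schedule(config)
  n <- nrow(sched)
  clusters <- erp_clusters(layout)
  fs <- config$eeg_rate_hz
  dur <- if (n) max(sched$trial_end_s) + 2 else 10
  nt <- ceiling(dur * fs)
  nch <- config$n_channels
  trial_seeds <- with_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, max(1L, 2L * n + 1L)))
  noise_seed <- trial_seeds[length(trial_seeds)]

  gaze <- vector("list", n)
  truth_rows <- vector("list", n)
  comp_rows <- vector("list", n)
  eeg <- matrix(0, nt, nch)
  for (i in seq_len(n)) {
    trial <- sched[i, ]
    g <- synth_gaze_trial(trial, config, trial_seeds[2 * i - 1])
    gaze[[i]] <- g$trace
    truth_rows[[i]] <- g$truth
    e <- synth_eeg_trial(trial, g$truth, config, layout, clusters,
                         trial_seeds[2 * i])
    idx <- e$first_sample:(e$first_sample + nrow(e$block) - 1L)
    keep <- idx >= 1 & idx <= nt
    eeg[idx[keep], ] <- eeg[idx[keep], ] + e$block[keep, ]
    comp_rows[[i]] <- e$component_truth
  }
  ns <- config$noise_spec
  with_seed(noise_seed, {
    tgrid <- (seq_len(nt) - 1) / fs
    line_phase <- stats::runif(1, 0, 2 * pi)
    line_gain <- stats::runif(nch, 0.5, 1.5)
    # electrodes differ in noise level (impedance, contact quality):
    # per-channel lognormal gain on the background noise
    gsd <- ns$channel_gain_sd_log %||% 0
    ch_gain <- if (gsd > 0) stats::rlnorm(nch, 0, gsd) else rep(1, nch)
    line <- sin(2 * pi * ns$line_freq_hz * tgrid + line_phase)
    for (ch in seq_len(nch)) {
      col <- eeg[, ch]
      if (ns$white_sd_uv > 0)
        col <- col + stats::rnorm(nt, 0, ns$white_sd_uv * ch_gain[ch])
      if (ns$pink_sd_uv > 0)
        col <- col + ns$pink_sd_uv * ch_gain[ch] *
          .pink_noise(nt, ns$pink_exponent)
      if (ns$line_amp_uv > 0)
        col <- col + ns$line_amp_uv * line_gain[ch] * line
      eeg[, ch] <- col
    }
    for (ch in config$bad_channels)
      eeg[, ch] <- stats::rnorm(nt, 0, ns$bad_channel_sd_uv)
  })
  truth_trials <- if (n) do.call(rbind, truth_rows) else
    data.frame(trial_id = integer(0))
  events <- if (n) data.frame(
    trial_id = sched$trial_id, block = sched$block,
    condition = sched$condition, target_onset_s = sched$target_onset_s,
    eeg_sample = round(sched$target_onset_s * fs) + 1L,
    response_time_s = truth_trials$response_time_s,
    responded_side = truth_trials$responded_side,
    stringsAsFactors = FALSE) else
    data.frame(trial_id = integer(0), block = character(0),
               condition = character(0), target_onset_s = numeric(0),
               eeg_sample = integer(0), response_time_s = numeric(0),
               responded_side = character(0))
  structure(list(
    gaze = gaze, events = events,
    eeg = eeg_recording(eeg, rate_hz = fs),
    layout = layout,
    truth = list(trials = truth_trials,
                 components = do.call(rbind, comp_rows),
                 bad_channels = config$bad_channels,
                 config_seed = config$seed),
    config = config), class = "gazerp_session")
}

#' @export
print.gazerp_session <- function(x, ...) {
  cat("Synthetic co-registered session:", nrow(x$events), "trials,",
      ncol(x$eeg$samples), "EEG channels,",
      sprintf("%.1f", nrow(x$eeg$samples) / x$eeg$rate_hz), "s recording\n")
  invisible(x)
}
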