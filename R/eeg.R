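# Continuous-EEG conditioning and epoch-level robust artifact screening:
# zero-phase Butterworth notch/high-pass/low-pass cascade, average
# reference, epoching with amplifier-delay correction, per-channel epoch
# metrics, MAD-based thresholds, screening, and baseline correction.

#' EEG recording container
#'
#' Continuous multichannel potentials in microvolts, time along rows,
#' channels along columns (EGI numbering 1..n).
#'
#' @param samples Numeric matrix, time x channel.
#' @param rate_hz Sampling rate (Hz).
#' @param channel_ids Integer channel ids.
#' @return An `eeg_recording` list.
#' @export
eeg_recording <- function(samples, rate_hz = gazerp_defaults("eeg_rate_hz"),
                          channel_ids = seq_len(ncol(samples))) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples)))
    stop("EEG samples must be finite", call. = FALSE)
  stopifnot(rate_hz > 0, length(channel_ids) == ncol(samples))
  structure(list(samples = samples, rate_hz = rate_hz,
                 channel_ids = as.integer(channel_ids)),
            class = "eeg_recording")
}

#' Condition the continuous EEG
#'
#' Applies a cascade of zero-phase (forward-backward) Butterworth filters:
#' band-stop around the line-noise frequency, high-pass, and low-pass.
#' Zero-phase application preserves peak latencies, the quantity of
#' interest downstream.
#'
#' @param rec An [eeg_recording()].
#' @param notch_band_hz Band-stop corner frequencies (Hz).
#' @param highpass_hz High-pass cutoff (Hz).
#' @param lowpass_hz Low-pass cutoff (Hz).
#' @param order Butterworth order of each filter.
#' @param min_duration_s Minimum recording length; shorter recordings are
#'   rejected because the filter transients would dominate.
#' @return The filtered `eeg_recording`.
#' @export
filter_continuous <- function(rec,
    notch_band_hz = gazerp_defaults("notch_band_hz"),
    highpass_hz = gazerp_defaults("highpass_hz"),
    lowpass_hz = gazerp_defaults("lowpass_hz"),
    order = gazerp_defaults("filter_order"),
    min_duration_s = gazerp_defaults("min_filter_duration_s")) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- nrow(rec$samples) / rec$rate_hz
  if (dur < min_duration_s)
    stop("recording too short for stable filtering: ", round(dur, 2),
         " s < minimum ", min_duration_s, " s", call. = FALSE)
  nyq <- rec$rate_hz / 2
  flt <- list(
    signal::butter(order, notch_band_hz / nyq, type = "stop"),
    signal::butter(order, highpass_hz / nyq, type = "high"),
    signal::butter(order, lowpass_hz / nyq, type = "low"))
  out <- rec$samples
  for (ch in seq_len(ncol(out))) {
    x <- out[, ch]
    for (f in flt) x <- signal::filtfilt(f, x)
    out[, ch] <- x
  }
  rec$samples <- out
  rec
}

#' Re-reference to the channel average
#'
#' Subtracts, at every sample, the mean over channels from each channel.
#' Idempotent; pairwise channel differences are unchanged.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$samples <- rec$samples - rowMeans(rec$samples)
  rec
}

#' Segment the recording into epochs around corrected target onsets
#'
#' The amplifier delays the EEG relative to the trigger timeline by
#' `amp_delay_ms`, so each event's sample index is shifted later by that
#' amount before cutting. Epochs span the half-open window
#' `[window_ms[1], window_ms[2])` ms around the corrected onset (95 samples
#' at 250 Hz for the default -200..180 ms window), with t = 0 at the
#' corrected onset. Events whose window falls outside the recording are
#' flagged `bad_window`, not dropped.
#'
#' @param rec An [eeg_recording()].
#' @param events Data frame with `trial_id` and `eeg_sample` (1-based
#'   sample index of target onset on the trigger timeline).
#' @param window_ms Epoch window (ms), half-open.
#' @param amp_delay_ms Amplifier delay (ms); the EEG lags the triggers.
#' @return An `epoch_set`: array `data` (time x channel x epoch),
#'   `times_ms`, `trial_ids`, `status` per epoch, `channel_flags`
#'   (channel x epoch character matrix), `rate_hz`, `baseline_window_ms`.
#' @export
make_epochs <- function(rec, events,
    window_ms = gazerp_defaults("epoch_window_ms"),
    amp_delay_ms = gazerp_defaults("amp_delay_ms")) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$rate_hz
  off0 <- round(window_ms[1] / 1000 * fs)
  off1 <- round(window_ms[2] / 1000 * fs) - 1L  # half-open upper edge
  offs <- off0:off1
  times_ms <- offs / fs * 1000
  delay <- round(amp_delay_ms / 1000 * fs)
  nch <- ncol(rec$samples)
  nsamp <- nrow(rec$samples)
  nev <- nrow(events)
  data <- array(NA_real_, c(length(offs), nch, nev))
  status <- character(nev)
  for (i in seq_len(nev)) {
    centre <- events$eeg_sample[i] + delay
    idx <- centre + offs
    if (idx[1] < 1 || idx[length(idx)] > nsamp) {
      status[i] <- "bad_window"
      next
    }
    data[, , i] <- rec$samples[idx, ]
    status[i] <- "kept"
  }
  structure(list(
    data = data, times_ms = times_ms,
    trial_ids = events$trial_id, status = status,
    channel_flags = matrix("clean", nch, nev,
                           dimnames = list(rec$channel_ids, NULL)),
    channel_ids = rec$channel_ids, rate_hz = fs,
    baseline_window_ms = c(window_ms[1], 0)),
    class = "epoch_set")
}

#' Per-channel artifact metrics of one epoch
#'
#' For a baseline-uncorrected epoch matrix (time x channel) computes, per
#' channel: the SD over samples, the amplitude range (max - min), the
#' drift (absolute difference between the mean post-onset and mean
#' pre-onset amplitude), and the maximum absolute step between successive
#' samples.
#'
#' @param epoch Numeric matrix, time x channel.
#' @param times_ms Sample times (ms relative to target onset).
#' @return Data frame with columns `sd`, `range`, `drift`, `max_step`.
#' @export
epoch_metrics <- function(epoch, times_ms) {
  pre <- times_ms < 0
  post <- !pre
  sds <- apply(epoch, 2, stats::sd)
  rng <- apply(epoch, 2, function(v) max(v) - min(v))
  drift <- abs(colMeans(epoch[post, , drop = FALSE]) -
               colMeans(epoch[pre, , drop = FALSE]))
  step <- apply(epoch, 2, function(v)
    if (length(v) > 1) max(abs(diff(v))) else 0)
  data.frame(sd = sds, range = rng, drift = drift, max_step = step)
}

# metrics for every (channel, epoch) pair: list of channel x epoch matrices
.all_metrics <- function(epochs) {
  nev <- dim(epochs$data)[3]
  nch <- dim(epochs$data)[2]
  out <- list(sd = matrix(NA_real_, nch, nev),
              range = matrix(NA_real_, nch, nev),
              drift = matrix(NA_real_, nch, nev),
              max_step = matrix(NA_real_, nch, nev))
  for (i in seq_len(nev)) {
    if (epochs$status[i] == "bad_window") next
    m <- epoch_metrics(epochs$data[, , i], epochs$times_ms)
    out$sd[, i] <- m$sd
    out$range[, i] <- m$range
    out$drift[, i] <- m$drift
    out$max_step[, i] <- m$max_step
  }
  out
}

#' Robust upper MAD threshold
#'
#' Computes the median and the (unscaled) median absolute deviation of the
#' pooled values and returns the one-sided upper cutoff
#' `median + multiplier * consistency * MAD`; values above the cutoff are
#' flagged as outliers. The consistency factor 1.483 rescales the MAD to a
#' normal-consistent spread estimate. A zero MAD (degenerate spread)
#' flags nothing.
#'
#' @param values Numeric vector (at least 5 values).
#' @param multiplier,consistency Threshold parameters.
#' @return List `median`, `mad`, `cutoff`, and function `flag(values)`
#'   returning a logical outlier indicator.
#' @export
#' @examples
#' th <- mad_thresholds(c(1, 2, 3, 4, 100))
#' th$flag(c(1, 2, 3, 4, 100))  # only the 100 is flagged
mad_thresholds <- function(values,
    multiplier = gazerp_defaults("mad_multiplier"),
    consistency = gazerp_defaults("mad_consistency")) {
  values <- values[is.finite(values)]
  if (length(values) < 5)
    stop("need at least 5 values to estimate a MAD threshold",
         call. = FALSE)
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  cutoff <- med + multiplier * consistency * mad
  flag <- if (mad == 0) function(v) rep(FALSE, length(v))
    else function(v) !is.na(v) & v > cutoff
  list(median = med, mad = mad, cutoff = cutoff, flag = flag)
}

#' Screen epochs and channels with robust MAD criteria
#'
#' For each of the four epoch metrics (SD, range, drift, max step), an
#' upper MAD threshold is estimated from the values pooled over all
#' (channel, epoch) pairs of the session. A channel is clean within an
#' epoch iff none of its four metrics exceeds its threshold *and* its SD
#' exceeds the signal floor (a flat electrode received no signal). An
#' epoch is kept iff strictly more than `min_clean_channels` channels are
#' clean; non-clean channels of kept epochs are marked for interpolation.
#'
#' @param epochs An `epoch_set` from [make_epochs()].
#' @param multiplier,consistency MAD threshold parameters.
#' @param min_clean_channels Strict lower bound on clean channels.
#' @param sd_floor_uv Minimum SD for an electrode to count as recording.
#' @return The `epoch_set` with updated `status`
#'   (`kept`/`rejected`/`bad_window`), `channel_flags`
#'   (`clean`/`needs_interpolation`), and a `screening` element holding
#'   the thresholds and metric matrices.
#' @export
screen_epochs <- function(epochs,
    multiplier = gazerp_defaults("mad_multiplier"),
    consistency = gazerp_defaults("mad_consistency"),
    min_clean_channels = gazerp_defaults("min_clean_channels"),
    sd_floor_uv = gazerp_defaults("sd_floor_uv")) {
  stopifnot(inherits(epochs, "epoch_set"))
  metrics <- .all_metrics(epochs)
  thresholds <- lapply(metrics, function(m)
    mad_thresholds(as.vector(m), multiplier, consistency))
  clean <- !(thresholds$sd$flag(metrics$sd) |
             thresholds$range$flag(metrics$range) |
             thresholds$drift$flag(metrics$drift) |
             thresholds$max_step$flag(metrics$max_step)) &
    !is.na(metrics$sd) & metrics$sd > sd_floor_uv
  for (i in seq_along(epochs$status)) {
    if (epochs$status[i] == "bad_window") next
    n_clean <- sum(clean[, i])
    if (n_clean > min_clean_channels) {
      epochs$status[i] <- "kept"
      epochs$channel_flags[, i] <-
        ifelse(clean[, i], "clean", "needs_interpolation")
    } else {
      epochs$status[i] <- "rejected"
      epochs$channel_flags[, i] <- ifelse(clean[, i], "clean", "bad")
    }
  }
  epochs$screening <- list(metrics = metrics, thresholds = thresholds,
                           sd_floor_uv = sd_floor_uv,
                           min_clean_channels = min_clean_channels)
  epochs
}

#' Baseline-correct all epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (pre-onset samples, `t < 0`) from the whole epoch. Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  pre <- epochs$times_ms < 0
  for (i in seq_len(dim(epochs$data)[3])) {
    if (epochs$status[i] == "bad_window") next
    base <- colMeans(epochs$data[pre, , i, drop = FALSE][, , 1])
    epochs$data[, , i] <- sweep(epochs$data[, , i], 2, base)
  }
  epochs
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch set:", d[3], "epochs x", d[2], "channels x", d[1],
      "samples (", x$times_ms[1], "..",
      x$times_ms[length(x$times_ms)], "ms )\n")
  cat("Status:", paste(names(table(x$status)), table(x$status),
                       collapse = ", "), "\n")
  invisible(x)
}
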