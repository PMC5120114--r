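# Gaze-stream processing: trace container, missing-sample repair, the
# online gaze-contingent detectors (central fixation, target acquisition),
# velocity-based saccade-onset detection, trial classification with the
# exclusion rules, and behavioural latency summaries.

#' Gaze trace container
#'
#' One trial's gaze samples on the 60 Hz tracker grid, in degrees of visual
#' angle from screen centre (x positive rightward), with validity flags and
#' the trial's target-onset anchor.
#'
#' @param times Sample times (s), strictly increasing.
#' @param x,y Gaze position (deg).
#' @param valid Logical validity flags.
#' @param target_onset_s Target onset on the same clock (s).
#' @param condition Trial condition (`"left"`, `"right"`, `"double"`).
#' @param block Response block (`"manual"` or `"saccade"`).
#' @param trial_id Integer trial id.
#' @return A `gaze_trace` list.
#' @export
gaze_trace <- function(times, x, y, valid = rep(TRUE, length(times)),
                       target_onset_s = times[1], condition = NA_character_,
                       block = NA_character_, trial_id = NA_integer_) {
  stopifnot(length(times) == length(x), length(x) == length(y),
            length(valid) == length(x))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("gaze sample times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), valid = as.logical(valid),
                 interpolated = rep(FALSE, length(times)),
                 target_onset_s = target_onset_s, condition = condition,
                 block = block, trial_id = trial_id),
            class = "gaze_trace")
}

#' Repair missing gaze samples
#'
#' Each invalid sample is replaced, in temporal order, by the average of
#' the previous sample (after any earlier replacement) and the first
#' subsequent valid sample; for runs of missing samples the rule is applied
#' repeatedly. Leading and trailing gaps, which have no neighbour on one
#' side, are left invalid (positions set to `NA`) and remain flagged.
#' Valid samples are never altered, and repairing an already-repaired
#' trace is the identity.
#'
#' @param trace A [gaze_trace()].
#' @return The repaired `gaze_trace`, with `interpolated` marking filled
#'   samples.
#' @export
fill_missing <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  v <- trace$valid
  if (!any(v)) stop("gaze trace has no valid samples; unrepairable",
                    call. = FALSE)
  if (all(v)) return(trace)
  first_ok <- which(v)[1]
  last_ok <- max(which(v))
  x <- trace$x; y <- trace$y
  interp <- trace$interpolated
  for (i in seq_along(v)) {
    if (v[i] || i < first_ok || i > last_ok) next
    nxt <- i + which(v[(i + 1):length(v)])[1]  # first subsequent valid
    x[i] <- (x[i - 1] + x[nxt]) / 2
    y[i] <- (y[i - 1] + y[nxt]) / 2
    interp[i] <- TRUE
    v[i] <- TRUE  # repaired value participates in later replacements
  }
  lead_trail <- seq_along(v) < first_ok | seq_along(v) > last_ok
  x[lead_trail] <- NA_real_
  y[lead_trail] <- NA_real_
  trace$x <- x; trace$y <- y
  trace$valid <- v & !lead_trail
  trace$interpolated <- interp
  trace
}

# end time of the first run of >= n_samples consecutive TRUE values
.first_run_end <- function(ok, times, n_samples) {
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (isTRUE(ok[i])) run + 1L else 0L
    if (run >= n_samples) return(times[i])
  }
  NA_real_
}

#' Online central-fixation detector
#'
#' Scans a repaired trace for the first run of at least `n_samples`
#' consecutive samples whose Euclidean distance from `center` is strictly
#' less than `radius_deg` (~330 ms of stable fixation at 60 Hz), and
#' returns the time of the sample completing that run.
#'
#' @param trace A repaired [gaze_trace()].
#' @param center Fixated object centre, `c(x, y)` in deg.
#' @param radius_deg Dispersion limit (deg), strict inequality.
#' @param n_samples Required run length.
#' @return Fixation time (s) or `NA` if no qualifying run exists.
#' @export
detect_central_fixation <- function(trace, center = c(0, 0),
    radius_deg = gazerp_defaults("fix_radius_deg"),
    n_samples = gazerp_defaults("fix_n_samples")) {
  d <- sqrt((trace$x - center[1])^2 + (trace$y - center[2])^2)
  .first_run_end(!is.na(d) & d < radius_deg, trace$times, n_samples)
}

#' Online target-acquisition detector
#'
#' Returns the time at which gaze has remained inside the square
#' acceptance box around the target (half-extent `half_box_deg` in each
#' direction) for `n_samples` consecutive samples.
#'
#' @param trace A repaired [gaze_trace()].
#' @param target_center Target centre, `c(x, y)` in deg.
#' @param half_box_deg Half-extent of the acceptance box (deg).
#' @param n_samples Required run length.
#' @return Acquisition time (s) or `NA`.
#' @export
detect_target_acquisition <- function(trace, target_center,
    half_box_deg = gazerp_defaults("acq_half_box_deg"),
    n_samples = gazerp_defaults("acq_n_samples")) {
  inbox <- !is.na(trace$x) & !is.na(trace$y) &
    abs(trace$x - target_center[1]) <= half_box_deg &
    abs(trace$y - target_center[2]) <= half_box_deg
  .first_run_end(inbox, trace$times, n_samples)
}

#' Velocity-based saccade-onset detection
#'
#' The saccade onset is the time point *before* the first horizontal
#' gaze-position change exceeding `step_deg` between two successive
#' samples (at 60 Hz the default corresponds to a velocity above
#' 132 deg/s). The comparison is strict, so a step of exactly `step_deg`
#' does not qualify.
#'
#' @param trace A repaired [gaze_trace()].
#' @param step_deg Displacement criterion (deg).
#' @param from_time_s Optional earliest time: only steps starting at or
#'   after this time are considered.
#' @return List `onset_s` (time of the sample before the step, `NA` if
#'   none) and `direction` (+1 rightward, -1 leftward, `NA` if none).
#' @export
find_saccade_onset <- function(trace,
    step_deg = gazerp_defaults("saccade_step_deg"), from_time_s = NULL) {
  n <- length(trace$x)
  if (n < 2) return(list(onset_s = NA_real_, direction = NA_real_))
  dx <- diff(trace$x)
  ok <- !is.na(dx) & abs(dx) > step_deg
  if (!is.null(from_time_s)) ok <- ok & trace$times[-n] >= from_time_s
  i <- which(ok)[1]
  if (is.na(i)) return(list(onset_s = NA_real_, direction = NA_real_))
  list(onset_s = trace$times[i], direction = sign(dx[i]))
}

# fraction of successive samples displaced by more than step_deg
.large_excursion_fraction <- function(trace, step_deg) {
  d <- sqrt(diff(trace$x)^2 + diff(trace$y)^2)
  d <- d[!is.na(d)]
  if (!length(d)) return(0)
  mean(d > step_deg)
}

#' Classify one trial
#'
#' Applies the exclusion rules in order — (1) gaze off screen at target
#' onset (tolerance box `screen_half_x_deg` x `screen_half_y_deg`),
#' (2) noisy tracking (more than `noisy_fraction_max` of successive-sample
#' displacements exceed the saccade step criterion), (3) anticipatory
#' response (earlier than `anticipatory_min_s` after target onset), then
#' sticky fixation (no response within `sticky_max_s`) and misdirected
#' response (single-target trials whose first response went to the wrong
#' side). The first failing rule determines the category; otherwise the
#' trial is `valid_correct` with latency = response onset - target onset
#' (raw, uncorrected tracker time).
#'
#' In the saccade block the response event is the first suprathreshold
#' saccade; in the manual block it is the button press supplied via
#' `response`, while any detected saccade is still recorded (it marks a
#' fixation break, used later for EEG gating).
#'
#' @param trace A repaired [gaze_trace()] with a target onset.
#' @param response For manual-block trials, a list with `time_s` and
#'   `side` from the response log (`NULL` for no response).
#' @param params Parameter list from [run_config()]/[gazerp_defaults()].
#' @return A one-row data frame: `trial_id`, `block`, `condition`,
#'   `category`, `saccade_onset_s`, `saccade_direction`, `latency_s`,
#'   `responded_side`.
#' @export
classify_trial <- function(trace, response = NULL,
                           params = gazerp_defaults()) {
  stopifnot(inherits(trace, "gaze_trace"))
  onset <- trace$target_onset_s
  sacc <- find_saccade_onset(trace, params$saccade_step_deg,
                             from_time_s = onset)
  res <- data.frame(
    trial_id = trace$trial_id, block = trace$block,
    condition = trace$condition, target_onset_s = onset,
    category = NA_character_,
    saccade_onset_s = sacc$onset_s, saccade_direction = sacc$direction,
    latency_s = NA_real_, responded_side = NA_character_,
    stringsAsFactors = FALSE)
  finish <- function(category, latency = NA_real_, side = NA_character_) {
    res$category <- category
    res$latency_s <- latency
    res$responded_side <- side
    res
  }
  # rule 1: gaze on screen at target onset
  i_on <- which(trace$times >= onset)[1]
  if (is.na(i_on)) i_on <- length(trace$times)
  if (is.na(trace$x[i_on]) || is.na(trace$y[i_on]) ||
      abs(trace$x[i_on]) > params$screen_half_x_deg ||
      abs(trace$y[i_on]) > params$screen_half_y_deg)
    return(finish("excluded_offscreen"))
  # rule 2: too many large excursions over the trial
  if (.large_excursion_fraction(trace, params$saccade_step_deg) >
      params$noisy_fraction_max)
    return(finish("excluded_noisy"))
  # response event: saccade onset or button press
  if (identical(trace$block, "manual")) {
    ev_time <- if (!is.null(response)) response$time_s else NA_real_
    ev_side <- if (!is.null(response)) response$side else NA_character_
  } else {
    ev_time <- sacc$onset_s
    ev_side <- if (is.na(sacc$direction)) NA_character_
      else if (sacc$direction > 0) "right" else "left"
  }
  lat <- ev_time - onset
  # rule 3: anticipatory responses
  if (!is.na(lat) && lat < params$anticipatory_min_s)
    return(finish("excluded_anticipatory"))
  # sticky fixation: no response within the horizon
  if (is.na(lat) || lat > params$sticky_max_s)
    return(finish("sticky_fixation"))
  # misdirected response on single-target trials
  if (trace$condition %in% c("left", "right") &&
      !is.na(ev_side) && ev_side != trace$condition)
    return(finish("misdirected"))
  finish("valid_correct", latency = lat, side = ev_side)
}

#' Classify all trials of a session
#'
#' Repairs every gaze trace and applies [classify_trial()], joining
#' manual-block response events from the events table.
#'
#' @param gaze List of [gaze_trace()] objects.
#' @param events Events data frame (needs `trial_id`, and for manual
#'   trials `response_time_s`, `responded_side`).
#' @param params Parameter list.
#' @return Data frame with one classification row per trial.
#' @export
classify_session <- function(gaze, events, params = gazerp_defaults()) {
  rows <- lapply(gaze, function(tr) {
    repaired <- fill_missing(tr)
    resp <- NULL
    if (identical(tr$block, "manual")) {
      ev <- events[events$trial_id == tr$trial_id, ]
      if (nrow(ev) == 1 && !is.na(ev$response_time_s))
        resp <- list(time_s = ev$response_time_s, side = ev$responded_side)
    }
    classify_trial(repaired, resp, params)
  })
  do.call(rbind, rows)
}

#' Behavioural latency summary
#'
#' Per-cell (response type x number of targets x responded side) mean, SD
#' and n of the valid-correct latencies, plus session-wide exclusion
#' fractions per category. Cells without valid trials are reported with
#' `n = 0` and `NA` statistics, never as zero latency.
#'
#' @param classifications Output of [classify_session()].
#' @return List with class `behavior_summary`: `cells` data frame,
#'   `exclusions` data frame, `n_trials`.
#' @export
summarize_behavior <- function(classifications) {
  cl <- classifications
  cl$response_type <- cl$block
  cl$n_targets <- ifelse(cl$condition == "double", 2L, 1L)
  valid <- cl[cl$category == "valid_correct", ]
  grid <- expand.grid(response_type = c("manual", "saccade"),
                      n_targets = c(1L, 2L), side = c("left", "right"),
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    lat <- valid$latency_s[valid$response_type == g$response_type &
                           valid$n_targets == g$n_targets &
                           valid$responded_side == g$side]
    data.frame(g, n = length(lat),
               mean_latency_s = if (length(lat)) mean(lat) else NA_real_,
               sd_latency_s = if (length(lat) > 1) stats::sd(lat) else
                 if (length(lat) == 1) 0 else NA_real_)
  }))
  categories <- c("valid_correct", "excluded_offscreen", "excluded_noisy",
                  "excluded_anticipatory", "sticky_fixation", "misdirected")
  counts <- vapply(categories, function(k) sum(cl$category == k), 0L)
  stopifnot(sum(counts) == nrow(cl))  # classification is a partition
  excl <- data.frame(category = categories, n = as.integer(counts),
                     fraction = if (nrow(cl)) counts / nrow(cl) else
                       rep(NA_real_, length(counts)),
                     row.names = NULL)
  structure(list(cells = cells, exclusions = excl, n_trials = nrow(cl)),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Behavioral summary over", x$n_trials, "trials\n")
  cat("Valid-correct latencies (s) per cell:\n")
  print(x$cells, row.names = FALSE, digits = 4)
  cat("Trial categories:\n")
  print(x$exclusions, row.names = FALSE, digits = 3)
  invisible(x)
}
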