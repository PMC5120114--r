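# Fusing gaze and EEG: gating out epochs contaminated by early saccades,
# condition-cell assignment with the two lateralization factors, cluster
# ERP waveforms, peak measures, and descriptive condition tables with
# pooled-SD effect sizes.

#' Gate epochs on eye-tracking evidence of early saccades
#'
#' An epoch is excluded when the trial's measured saccade latency, after
#' subtracting the fixed gating correction for tracker/display delays,
#' falls below the analysis-window limit: saccades that early would
#' contaminate the EEG window. The rule applies in both blocks — a
#' manual-block trial with a detected fixation break is treated exactly
#' like a saccade-block trial — while trials with no detected saccade are
#' kept. Epochs without a gaze record are excluded with a logged reason.
#'
#' @param epochs An `epoch_set`.
#' @param classifications Classification table from [classify_session()].
#' @param corrections A [latency_corrections()].
#' @param early_ms Corrected-latency limit (ms).
#' @return The `epoch_set` with gated epochs set to status
#'   `rejected_early_saccade` (or `rejected_no_gaze`) and a `gating` data
#'   frame logging, per epoch, the measured and corrected latencies and
#'   the decision.
#' @export
gate_by_saccade <- function(epochs, classifications,
    corrections = latency_corrections(),
    early_ms = gazerp_defaults("early_saccade_ms")) {
  stopifnot(inherits(epochs, "epoch_set"))
  corr_s <- corrections$fixed_gating_correction_ms / 1000
  limit_s <- early_ms / 1000
  log <- data.frame(trial_id = epochs$trial_ids,
                    saccade_latency_s = NA_real_,
                    corrected_latency_s = NA_real_,
                    decision = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(epochs$trial_ids)) {
    if (!epochs$status[i] %in% "kept") {
      log$decision[i] <- epochs$status[i]
      next
    }
    cl <- classifications[classifications$trial_id == epochs$trial_ids[i], ]
    if (nrow(cl) != 1) {
      epochs$status[i] <- "rejected_no_gaze"
      log$decision[i] <- "rejected_no_gaze"
      next
    }
    if (!is.na(cl$saccade_onset_s)) {
      lat <- cl$saccade_onset_s - .trial_onset(cl, epochs, i)
      log$saccade_latency_s[i] <- lat
      log$corrected_latency_s[i] <- lat - corr_s
      if (lat - corr_s < limit_s) {
        epochs$status[i] <- "rejected_early_saccade"
        log$decision[i] <- "rejected_early_saccade"
        next
      }
    }
    log$decision[i] <- "kept"
  }
  epochs$gating <- log
  epochs
}

# target onset of the trial backing an epoch, from its classification row
.trial_onset <- function(cl, epochs, i) {
  if (!is.null(cl$target_onset_s)) return(cl$target_onset_s)
  stop("target onset unknown for trial ", cl$trial_id, call. = FALSE)
}

#' Assign condition cells to epochs
#'
#' Expands each kept epoch into one row per electrode cluster, labelled
#' with the full condition cell: response type (block), number of targets,
#' brain side (the cluster's hemisphere) and brain hemisphere relative to
#' the responded side — a left-hemisphere cluster is `contralateral` when
#' the response went right. Epochs with unknown responded side get `NA`
#' hemisphere (they still contribute to marginal cells).
#'
#' @param epochs A gated `epoch_set`.
#' @param classifications Classification table.
#' @param clusters Cluster list from [erp_clusters()].
#' @return Data frame: `trial_id`, `epoch`, `cluster`, `response_type`,
#'   `n_targets`, `brain_side`, `responded_side`, `hemisphere`.
#' @export
assign_cells <- function(epochs, classifications,
                         clusters = erp_clusters()) {
  kept <- which(epochs$status == "kept")
  side_of <- attr(clusters, "side")
  rows <- list()
  for (i in kept) {
    cl <- classifications[classifications$trial_id == epochs$trial_ids[i], ]
    if (nrow(cl) != 1) next
    for (cn in names(clusters)) {
      bs <- side_of[[cn]]
      hemi <- if (is.na(cl$responded_side)) NA_character_
        else if (bs == cl$responded_side) "ipsilateral" else "contralateral"
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = cl$trial_id, epoch = i, cluster = cn,
        response_type = cl$block,
        n_targets = ifelse(cl$condition == "double", 2L, 1L),
        brain_side = bs, responded_side = cl$responded_side,
        hemisphere = hemi, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Average cluster waveform over a set of epochs
#'
#' Averages the usable cluster channels (flagged `clean` or
#' `interpolated`) within each epoch, then averages over epochs.
#' An empty selection returns an explicit empty result (`n = 0`,
#' `NULL` waveform), never a vector of zeros.
#'
#' @param epochs A baseline-corrected `epoch_set`.
#' @param channels Integer EGI channel ids of the cluster.
#' @param epoch_idx Epoch indices to average.
#' @return List `times_ms`, `uv` (mean waveform, microvolts), `n` epochs.
#' @export
cluster_waveform <- function(epochs, channels, epoch_idx) {
  epoch_idx <- epoch_idx[epochs$status[epoch_idx] == "kept"]
  if (!length(epoch_idx))
    return(list(times_ms = epochs$times_ms, uv = NULL, n = 0L))
  chpos <- match(channels, epochs$channel_ids)
  acc <- numeric(length(epochs$times_ms))
  n <- 0L
  for (i in epoch_idx) {
    usable <- chpos[epochs$channel_flags[chpos, i] %in%
                      c("clean", "interpolated")]
    if (!length(usable)) next
    acc <- acc + rowMeans(epochs$data[, usable, i, drop = FALSE])
    n <- n + 1L
  }
  if (n == 0L) return(list(times_ms = epochs$times_ms, uv = NULL, n = 0L))
  list(times_ms = epochs$times_ms, uv = acc / n, n = n)
}

#' Peak amplitude and latency within a window
#'
#' Restricts the waveform to the closed window and returns the extremum of
#' the requested polarity (maximum for positive components, minimum for
#' negative ones) with the time of the sample attaining it; ties resolve
#' to the earliest sample.
#'
#' @param waveform List with `times_ms` and `uv` (as from
#'   [cluster_waveform()]).
#' @param window_ms Search window `c(lo, hi)` in ms.
#' @param polarity `"positive"` or `"negative"`.
#' @return List `amplitude_uV`, `latency_ms`.
#' @export
peak_measure <- function(waveform, window_ms,
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (is.null(waveform$uv)) stop("empty waveform has no peak", call. = FALSE)
  sel <- waveform$times_ms >= window_ms[1] & waveform$times_ms <= window_ms[2]
  if (!any(sel))
    stop("peak window [", window_ms[1], ", ", window_ms[2],
         "] ms lies outside the epoch span", call. = FALSE)
  v <- waveform$uv[sel]
  t <- waveform$times_ms[sel]
  i <- if (polarity == "positive") which.max(v) else which.min(v)
  list(amplitude_uV = v[i], latency_ms = t[i])
}

#' ERP peak measures per cluster and condition cell
#'
#' For every electrode cluster and every cell of the crossing
#' (response type x number of targets x hemisphere, plus the
#' hemisphere-marginal cells), forms the cluster waveform over the cell's
#' epochs and extracts the peak measure: occipital clusters use positive
#' polarity, frontocentral clusters negative, prefrontal positive with
#' its own later search window.
#'
#' @param epochs A gated, baseline-corrected `epoch_set`.
#' @param cells Cell table from [assign_cells()].
#' @param clusters Cluster list from [erp_clusters()].
#' @param peak_window_ms Occipital/frontocentral search window (ms).
#' @param prefrontal_window_ms Prefrontal search window (ms).
#' @return Data frame: `cluster`, `response_type`, `n_targets`,
#'   `hemisphere`, `polarity`, `amplitude_uV`, `latency_ms`, `n`.
#' @export
erp_measures <- function(epochs, cells, clusters = erp_clusters(),
    peak_window_ms = gazerp_defaults("peak_window_ms"),
    prefrontal_window_ms = gazerp_defaults("prefrontal_window_ms")) {
  if (!nrow(cells)) return(data.frame())
  spec <- list(
    O1 = list(polarity = "positive", window = peak_window_ms),
    O2 = list(polarity = "positive", window = peak_window_ms),
    FC3 = list(polarity = "negative", window = peak_window_ms),
    FC4 = list(polarity = "negative", window = peak_window_ms),
    FP1 = list(polarity = "positive", window = prefrontal_window_ms),
    FP2 = list(polarity = "positive", window = prefrontal_window_ms))
  hemis <- list("ipsilateral", "contralateral", NULL)  # NULL = marginal
  rows <- list()
  for (cn in names(clusters)) {
    sub <- cells[cells$cluster == cn, ]
    for (rt in unique(sub$response_type)) for (ntg in unique(sub$n_targets))
      for (h in hemis) {
        pick <- sub$response_type == rt & sub$n_targets == ntg
        if (!is.null(h)) pick <- pick & !is.na(sub$hemisphere) &
            sub$hemisphere == h
        idx <- unique(sub$epoch[pick])
        wf <- cluster_waveform(epochs, clusters[[cn]], idx)
        if (wf$n == 0) next
        pk <- peak_measure(wf, spec[[cn]]$window, spec[[cn]]$polarity)
        rows[[length(rows) + 1]] <- data.frame(
          cluster = cn, response_type = rt, n_targets = ntg,
          hemisphere = if (is.null(h)) "all" else h,
          polarity = spec[[cn]]$polarity,
          amplitude_uV = pk$amplitude_uV, latency_ms = pk$latency_ms,
          n = wf$n, stringsAsFactors = FALSE)
      }
  }
  do.call(rbind, rows)
}

#' Condition summary with effect sizes
#'
#' Descriptive statistics (mean, SD, n) of a measurement column per level
#' of a grouping factor, with the pooled-SD Cohen's d for the two-level
#' contrast (see [cohens_d()]). Degenerate groups (undefined SD) omit d
#' with a reason.
#'
#' @param values Numeric measurements.
#' @param group Factor with the contrasted levels (exactly 2 used).
#' @return List with class `condition_summary`: `groups` data frame and
#'   `d` (or `NA` with `d_reason`).
#' @export
condition_table <- function(values, group) {
  group <- as.factor(group)
  lev <- levels(droplevels(group))
  stats_df <- do.call(rbind, lapply(lev, function(l) {
    v <- values[group == l & !is.na(values)]
    data.frame(group = l, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  out <- list(groups = stats_df, d = NA_real_, d_reason = NULL)
  if (length(lev) == 2 && all(stats_df$n >= 2) &&
      all(is.finite(stats_df$sd)) && any(stats_df$sd > 0)) {
    out$d <- cohens_d(stats_df$mean[1], stats_df$sd[1],
                      stats_df$mean[2], stats_df$sd[2])
  } else {
    out$d_reason <- "degenerate or missing group (need 2 groups, n >= 2, positive pooled SD)"
  }
  structure(out, class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  print(x$groups, row.names = FALSE, digits = 4)
  if (is.finite(x$d)) cat(sprintf("Cohen's d = %.3f\n", x$d))
  else cat("Cohen's d omitted:", x$d_reason, "\n")
  invisible(x)
}
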