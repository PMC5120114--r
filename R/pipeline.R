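# End-to-end orchestration: gaze repair -> classification -> behaviour
# summary -> EEG filter -> average reference -> epoch -> screen ->
# interpolate -> baseline -> saccade gating -> ERP measures -> condition
# tables, with a machine-readable exclusion ledger at every stage.

# stage 1-2: gaze analysis
.stage_gaze <- function(session, params) {
  classifications <- classify_session(session$gaze, session$events, params)
  list(classifications = classifications,
       behavior = summarize_behavior(classifications))
}

# stage 3-9: EEG conditioning through baseline correction (pre-gating)
.stage_eeg <- function(session, params) {
  rec <- filter_continuous(session$eeg,
    notch_band_hz = params$notch_band_hz,
    highpass_hz = params$highpass_hz, lowpass_hz = params$lowpass_hz,
    order = params$filter_order,
    min_duration_s = params$min_filter_duration_s)
  rec <- average_reference(rec)
  epochs <- make_epochs(rec, session$events,
    window_ms = params$epoch_window_ms, amp_delay_ms = params$amp_delay_ms)
  epochs <- screen_epochs(epochs,
    multiplier = params$mad_multiplier,
    consistency = params$mad_consistency,
    min_clean_channels = params$min_clean_channels,
    sd_floor_uv = params$sd_floor_uv)
  epochs <- interpolate_bad_channels(epochs, session$layout,
    m = params$spline_order_m, n_terms = params$spline_n_terms)
  baseline_correct(epochs)
}

# stage 10-12: gating, cells, ERP measures, waveforms
.stage_erp <- function(epochs, classifications, layout, params) {
  corrections <- latency_corrections(
    fixed_gating_correction_ms = params$gating_correction_ms)
  epochs <- gate_by_saccade(epochs, classifications, corrections,
                            early_ms = params$early_saccade_ms)
  clusters <- erp_clusters(layout, fp_size = params$fp_cluster_size)
  cells <- assign_cells(epochs, classifications, clusters)
  measures <- erp_measures(epochs, cells, clusters,
    peak_window_ms = params$peak_window_ms,
    prefrontal_window_ms = params$prefrontal_window_ms)
  waveforms <- .collect_waveforms(epochs, cells, clusters)
  list(epochs = epochs, cells = cells, measures = measures,
       waveforms = waveforms)
}

# marginal condition-average waveforms in long format
.collect_waveforms <- function(epochs, cells, clusters) {
  if (!nrow(cells)) return(data.frame())
  rows <- list()
  for (cn in names(clusters)) {
    sub <- cells[cells$cluster == cn, ]
    for (rt in unique(sub$response_type)) for (ntg in unique(sub$n_targets)) {
      idx <- unique(sub$epoch[sub$response_type == rt &
                                sub$n_targets == ntg])
      wf <- cluster_waveform(epochs, clusters[[cn]], idx)
      if (wf$n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cn, response_type = rt, n_targets = ntg,
        time_ms = wf$times_ms, uv = wf$uv, n = wf$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.epoch_qc <- function(epochs) {
  nint <- colSums(epochs$channel_flags == "interpolated")
  nclean <- colSums(epochs$channel_flags == "clean")
  qc <- data.frame(trial_id = epochs$trial_ids, status = epochs$status,
                   n_clean = nclean, n_interpolated = nint,
                   stringsAsFactors = FALSE)
  if (!is.null(epochs$gating)) {
    qc$saccade_latency_s <- epochs$gating$saccade_latency_s
    qc$corrected_latency_s <- epochs$gating$corrected_latency_s
    qc$gating_decision <- epochs$gating$decision
  }
  qc
}

#' Run the full co-registered analysis pipeline
#'
#' Executes every stage on an in-memory session bundle: gaze repair and
#' trial classification, behavioural summaries, EEG conditioning
#' (notch/high-pass/low-pass, average reference), epoching with amplifier
#' delay correction, robust MAD screening, spherical-spline channel
#' repair, baseline correction, eye-tracking-based gating of early
#' saccades, electrode-cluster ERP peak measures and condition tables
#' with behavioural effect sizes. If `out_dir` is given, all result
#' tables and a machine-readable run log with stage-by-stage counts are
#' written there as TSV/JSON.
#'
#' @param session A `gazerp_session` (from [assemble_session()] or
#'   [read_session()]).
#' @param params Parameter list from [run_config()].
#' @param out_dir Optional output directory.
#' @return A `gazerp_run` object: `classifications`, `behavior`,
#'   `epochs`, `cells`, `erp` (measures table), `waveforms`, `qc`,
#'   `contrasts`, `stage_counts`, `params`.
#' @export
run_pipeline <- function(session, params = run_config(), out_dir = NULL) {
  stopifnot(inherits(session, "gazerp_session"))
  gz <- .stage_gaze(session, params)
  epochs <- .stage_eeg(session, params)
  erp <- .stage_erp(epochs, gz$classifications, session$layout, params)
  qc <- .epoch_qc(erp$epochs)

  cl <- gz$classifications
  valid <- cl[cl$category == "valid_correct", ]
  contrasts <- list(
    latency_by_response_type =
      condition_table(valid$latency_s, valid$block),
    latency_by_n_targets =
      condition_table(valid$latency_s,
                      ifelse(valid$condition == "double",
                             "double", "single")))
  n_epochs <- length(erp$epochs$status)
  stage_counts <- list(
    trials_total = nrow(cl),
    trials_valid_correct = sum(cl$category == "valid_correct"),
    trials_excluded = sum(cl$category != "valid_correct"),
    epochs_total = n_epochs,
    epochs_bad_window = sum(erp$epochs$status == "bad_window"),
    epochs_rejected_screening = sum(erp$epochs$status == "rejected"),
    epochs_rejected_early_saccade =
      sum(erp$epochs$status == "rejected_early_saccade"),
    epochs_rejected_no_gaze = sum(erp$epochs$status == "rejected_no_gaze"),
    epochs_kept = sum(erp$epochs$status == "kept"))
  run <- structure(list(
    classifications = cl, behavior = gz$behavior, epochs = erp$epochs,
    cells = erp$cells, erp = erp$measures, waveforms = erp$waveforms,
    qc = qc, contrasts = contrasts, stage_counts = stage_counts,
    params = params), class = "gazerp_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write the result tables of a pipeline run
#'
#' @param run A `gazerp_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(run$classifications, file.path(out_dir, "trials.tsv"))
  .write_tsv(run$behavior$cells, file.path(out_dir, "behavior_cells.tsv"))
  .write_tsv(run$behavior$exclusions,
             file.path(out_dir, "behavior_exclusions.tsv"))
  .write_tsv(run$qc, file.path(out_dir, "qc_epochs.tsv"))
  if (nrow(run$erp))
    .write_tsv(run$erp, file.path(out_dir, "erp_measures.tsv"))
  if (nrow(run$waveforms))
    .write_tsv(run$waveforms, file.path(out_dir, "waveforms.tsv"))
  jsonlite::write_json(run$stage_counts,
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.gazerp_run <- function(x, ...) {
  sc <- x$stage_counts
  cat("Co-registered pipeline run\n")
  cat(sprintf("  trials: %d (%d valid correct, %d excluded)\n",
              sc$trials_total, sc$trials_valid_correct, sc$trials_excluded))
  cat(sprintf(
    "  epochs: %d kept of %d (screening -%d, early saccade -%d, window -%d)\n",
    sc$epochs_kept, sc$epochs_total, sc$epochs_rejected_screening,
    sc$epochs_rejected_early_saccade, sc$epochs_bad_window))
  if (is.finite(x$contrasts$latency_by_response_type$d))
    cat(sprintf("  latency effect (manual vs saccade): d = %.3f\n",
                x$contrasts$latency_by_response_type$d))
  invisible(x)
}

#' @export
summary.gazerp_run <- function(object, ...) {
  print(object)
  cat("\nBehavior:\n")
  print(object$behavior)
  if (nrow(object$erp)) {
    cat("\nERP peak measures (hemisphere-marginal cells):\n")
    print(object$erp[object$erp$hemisphere == "all", ],
          row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Plot condition-average cluster waveforms
#'
#' Base-graphics panel per electrode cluster showing the
#' hemisphere-marginal condition-average waveforms of a pipeline run.
#'
#' @param x A `gazerp_run`.
#' @param clusters Cluster names to plot.
#' @param ... Unused.
#' @export
plot.gazerp_run <- function(x, clusters = unique(x$waveforms$cluster), ...) {
  wf <- x$waveforms
  if (!nrow(wf)) {
    warning("no waveforms to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(clusters), 1),
                       mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(old))
  for (cn in clusters) {
    sub <- wf[wf$cluster == cn, ]
    keys <- unique(sub[, c("response_type", "n_targets")])
    cols <- grDevices::hcl.colors(max(nrow(keys), 2), "Dark 2")
    graphics::plot(NA, xlim = range(sub$time_ms), ylim = range(sub$uv),
                   xlab = "time after target onset (ms)",
                   ylab = expression(mu * V), main = cn)
    graphics::abline(v = 0, lty = 3)
    for (k in seq_len(nrow(keys))) {
      s <- sub[sub$response_type == keys$response_type[k] &
                 sub$n_targets == keys$n_targets[k], ]
      graphics::lines(s$time_ms, s$uv, col = cols[k])
    }
    graphics::legend("topleft", bty = "n", col = cols, lty = 1, cex = 0.8,
      legend = paste0(keys$response_type, ", ", keys$n_targets, " target(s)"))
  }
  invisible(x)
}
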