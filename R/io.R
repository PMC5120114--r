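# On-disk session format: plain TSV for gaze, events, layout and truth;
# raw little-endian float32 + JSON sidecar for the continuous EEG (and
# float64 + sidecar for intermediate epoch tensors). Numeric TSV columns
# are written with 17 significant digits so a write/read round trip is
# value-exact for doubles.

.fmt_num <- function(v) {
  s <- sprintf("%.17g", v)
  s[!is.finite(v) & !is.na(v)] <- as.character(v[!is.finite(v) & !is.na(v)])
  s[is.na(v)] <- "NA"
  s
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path))
    stop("missing file: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write / read a session bundle
#'
#' `write_session()` persists a `gazerp_session` to a directory as plain
#' TSV files (gaze samples, events, layout, ground truth) plus the
#' continuous EEG as raw little-endian float32 with a JSON sidecar
#' describing rate, dimensions and storage order. `read_session()`
#' reconstructs the bundle, validating the layout against the recorded
#' channel count. Identical seeds produce byte-identical session
#' directories.
#'
#' @param session A `gazerp_session` from [assemble_session()].
#' @param dir Target directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `gazerp_session` (without the generator config).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "gazerp_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gz <- do.call(rbind, lapply(session$gaze, function(tr)
    data.frame(trial_id = tr$trial_id, time_s = tr$times, x_deg = tr$x,
               y_deg = tr$y, valid = as.integer(tr$valid),
               stringsAsFactors = FALSE)))
  .write_tsv(gz, file.path(dir, "gaze.tsv"))
  .write_tsv(session$events, file.path(dir, "events.tsv"))
  write_layout(session$layout, file.path(dir, "layout.tsv"))
  .write_tsv(session$truth$trials, file.path(dir, "truth_trials.tsv"))
  if (!is.null(session$truth$components))
    .write_tsv(session$truth$components,
               file.path(dir, "truth_components.tsv"))
  jsonlite::write_json(
    list(bad_channels = session$truth$bad_channels,
         config_seed = session$truth$config_seed),
    file.path(dir, "truth_meta.json"), auto_unbox = TRUE)
  eeg <- session$eeg
  con <- file(file.path(dir, "eeg.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(eeg$samples), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(format = "float32-le", order = "column-major time x channel",
         unit = "microvolt", rate_hz = eeg$rate_hz,
         n_samples = nrow(eeg$samples), n_channels = ncol(eeg$samples),
         channel_ids = eeg$channel_ids),
    file.path(dir, "eeg.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  if (!file.exists(file.path(dir, "eeg.json")))
    stop("not a session directory (missing eeg.json): ", dir,
         call. = FALSE)
  side <- jsonlite::read_json(file.path(dir, "eeg.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "eeg.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", size = 4,
                  n = side$n_samples * side$n_channels, endian = "little")
  if (length(vals) != side$n_samples * side$n_channels)
    stop("eeg.bin truncated: expected ", side$n_samples * side$n_channels,
         " samples, got ", length(vals), call. = FALSE)
  eeg <- eeg_recording(matrix(vals, side$n_samples, side$n_channels),
                       rate_hz = side$rate_hz,
                       channel_ids = side$channel_ids)
  layout <- read_layout(file.path(dir, "layout.tsv"),
                        n_channels = side$n_channels)
  events <- .read_tsv(file.path(dir, "events.tsv"))
  gz <- .read_tsv(file.path(dir, "gaze.tsv"))
  gaze <- lapply(split(gz, gz$trial_id), function(d) {
    ev <- events[events$trial_id == d$trial_id[1], ]
    gaze_trace(times = d$time_s, x = d$x_deg, y = d$y_deg,
               valid = d$valid == 1, target_onset_s = ev$target_onset_s,
               condition = ev$condition, block = ev$block,
               trial_id = d$trial_id[1])
  })
  gaze <- gaze[order(vapply(gaze, function(g) g$trial_id, 0))]
  names(gaze) <- NULL
  truth <- NULL
  if (file.exists(file.path(dir, "truth_trials.tsv"))) {
    meta <- jsonlite::read_json(file.path(dir, "truth_meta.json"),
                                simplifyVector = TRUE)
    truth <- list(
      trials = .read_tsv(file.path(dir, "truth_trials.tsv")),
      components = if (file.exists(file.path(dir, "truth_components.tsv")))
        .read_tsv(file.path(dir, "truth_components.tsv")) else NULL,
      bad_channels = meta$bad_channels, config_seed = meta$config_seed)
  }
  structure(list(gaze = gaze, events = events, eeg = eeg, layout = layout,
                 truth = truth, config = NULL),
            class = "gazerp_session")
}

#' Write / read an epoch tensor
#'
#' Persists an `epoch_set` (float64 raw + JSON sidecar + flag TSV) so
#' that pipeline stages can be re-run independently on intermediate
#' files. The round trip is value-exact.
#'
#' @param epochs An `epoch_set`.
#' @param dir Target directory.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` the
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "epochs.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(format = "float64-le", order = "column-major time x channel x epoch",
         dims = dim(epochs$data), times_ms = epochs$times_ms,
         trial_ids = epochs$trial_ids, status = epochs$status,
         channel_ids = epochs$channel_ids, rate_hz = epochs$rate_hz,
         baseline_window_ms = epochs$baseline_window_ms),
    file.path(dir, "epochs.json"), auto_unbox = TRUE, digits = NA)
  flags <- as.data.frame(epochs$channel_flags, stringsAsFactors = FALSE)
  names(flags) <- paste0("epoch_", seq_along(flags))
  flags <- cbind(data.frame(channel = epochs$channel_ids), flags)
  .write_tsv(flags, file.path(dir, "channel_flags.tsv"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "epochs.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", size = 8, n = prod(side$dims),
                  endian = "little")
  flags <- .read_tsv(file.path(dir, "channel_flags.tsv"))
  fl <- as.matrix(flags[, -1, drop = FALSE])
  dimnames(fl) <- list(side$channel_ids, NULL)
  structure(list(
    data = array(vals, side$dims), times_ms = side$times_ms,
    trial_ids = side$trial_ids, status = side$status,
    channel_flags = fl, channel_ids = side$channel_ids,
    rate_hz = side$rate_hz, baseline_window_ms = side$baseline_window_ms),
    class = "epoch_set")
}
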