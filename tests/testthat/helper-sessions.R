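# Shared fixtures: tiny session configurations and hand-built gaze traces.
# Everything is generated in code; no data files.

tiny_config <- function(seed = 101, n = 12, ...) {
  session_config(n_trials_per_block = n, seed = seed, ...)
}

tiny_noiseless_config <- function(seed = 101, n = 12, ...) {
  session_config_noiseless(n_trials_per_block = n, seed = seed, ...)
}

# a 60 Hz trace fixating the centre, with an optional saccade ramp
make_trace <- function(x, y = rep(0, length(x)), rate = 60,
                       target_onset_s = 0, valid = rep(TRUE, length(x)),
                       condition = "left", block = "saccade",
                       trial_id = 1L, t0 = -0.2) {
  n <- length(x)
  gaze_trace(times = t0 + seq_len(n) / rate, x = x, y = y, valid = valid,
             target_onset_s = target_onset_s, condition = condition,
             block = block, trial_id = trial_id)
}

# cached small epoch-set built from a synthetic recording
local_epochs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config(seed = 404, n = 10)
      s <- assemble_session(cfg)
      rec <- average_reference(filter_continuous(s$eeg))
      cache <<- list(session = s,
                     epochs = make_epochs(rec, s$events))
    }
    cache
  }
})

# cached full pipeline run on the same small session
local_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(local_epochs()$session)
    cache
  }
})
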