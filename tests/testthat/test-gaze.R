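# Gaze repair, online detectors, saccade-onset detection, classification.

test_that("missing samples are repaired by sequential neighbour averaging", {
  tr <- make_trace(c(1, 0, 3), valid = c(TRUE, FALSE, TRUE))
  out <- fill_missing(tr)
  expect_equal(out$x[2], 2)
  expect_true(out$interpolated[2])
  expect_true(all(out$valid))

  # runs of missing samples apply the rule repeatedly, in temporal order
  tr <- make_trace(c(0, 9, 9, 4), valid = c(TRUE, FALSE, FALSE, TRUE))
  out <- fill_missing(tr)
  expect_equal(out$x, c(0, 2, 3, 4))

  # fully valid traces pass through unchanged; repair is idempotent
  tr <- make_trace(c(1, 2, 3))
  expect_identical(fill_missing(tr), tr)
  tr <- make_trace(c(1, 5, 3, 7, 2),
                   valid = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  once <- fill_missing(tr)
  expect_identical(fill_missing(once), once)

  # valid samples are never altered
  expect_equal(once$x[c(1, 3, 5)], c(1, 3, 2))
})

test_that("leading/trailing gaps stay invalid and all-invalid traces error", {
  tr <- make_trace(c(9, 1, 9, 2, 9),
                   valid = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  out <- fill_missing(tr)
  expect_true(is.na(out$x[1]) && is.na(out$x[5]))
  expect_equal(out$valid, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(fill_missing(make_trace(c(1, 2), valid = c(FALSE, FALSE))),
               "unrepairable")
})

test_that("central-fixation detector needs a strict sub-radius run", {
  # 20 samples exactly at centre -> fixation at the 20th sample
  tr <- make_trace(rep(0, 25))
  expect_equal(detect_central_fixation(tr), tr$times[20])
  # an excursion to 3 deg restarts the run
  x <- rep(0, 30); x[10] <- 3
  tr <- make_trace(x)
  expect_equal(detect_central_fixation(tr), tr$times[30])
  # boundary: dispersion of exactly the radius never qualifies
  tr <- make_trace(rep(gazerp_defaults("fix_radius_deg"), 40), y = rep(0, 40))
  expect_true(is.na(detect_central_fixation(tr)))
})

test_that("target acquisition requires 20 consecutive in-box samples", {
  x <- c(rep(0, 5), rep(12.9, 25))
  tr <- make_trace(x)
  expect_equal(detect_target_acquisition(tr, c(12.9, 0)), tr$times[25])
  # 19 in-box samples then exit -> none
  x <- c(rep(0, 5), rep(12.9, 19), 0)
  expect_true(is.na(detect_target_acquisition(make_trace(x), c(12.9, 0))))
  # the box test is symmetric in the sign of the offset
  x <- c(rep(0, 5), rep(-12.9, 25))
  expect_equal(detect_target_acquisition(make_trace(x), c(-12.9, 0)),
               detect_target_acquisition(make_trace(-x), c(12.9, 0)))
})

test_that("saccade onset is the sample before the first suprathreshold step", {
  tr <- make_trace(c(0, 0, 0, 3, 6, 9))
  res <- find_saccade_onset(tr)
  expect_equal(res$onset_s, tr$times[3])
  expect_equal(res$direction, 1)
  # a step of exactly the criterion does not qualify (strict >)
  step <- gazerp_defaults("saccade_step_deg")
  tr <- make_trace(cumsum(c(0, rep(step, 5))))
  expect_true(is.na(find_saccade_onset(tr)$onset_s))
  # leftward saccades give negative direction
  tr <- make_trace(c(0, 0, -5, -10))
  expect_equal(find_saccade_onset(tr)$direction, -1)
})

test_that("saccade detection matches an exhaustive scan and its symmetries", {
  brute <- function(x, thr) {
    for (i in seq_len(length(x) - 1))
      if (isTRUE(abs(x[i + 1] - x[i]) > thr)) return(i)
    NA_integer_
  }
  set.seed(42)
  for (rep in 1:50) {
    x <- cumsum(stats::rnorm(30, 0, 1.4))
    tr <- make_trace(x)
    got <- find_saccade_onset(tr)
    i <- brute(x, gazerp_defaults("saccade_step_deg"))
    if (is.na(i)) {
      expect_true(is.na(got$onset_s))
    } else {
      expect_equal(got$onset_s, tr$times[i])
      # translation invariance in time and x; direction flips with x
      tr2 <- make_trace(x + 100, t0 = 3.7)
      expect_equal(find_saccade_onset(tr2)$onset_s, tr2$times[i])
      expect_equal(find_saccade_onset(make_trace(-x))$direction,
                   -got$direction)
    }
  }
})

test_that("classification applies the exclusion rules in order", {
  p <- gazerp_defaults()
  # rule 1: off-screen gaze at target onset
  tr <- make_trace(rep(25, 30), target_onset_s = 0.1)
  expect_equal(classify_trial(tr, params = p)$category, "excluded_offscreen")
  tr <- make_trace(rep(0, 30), y = rep(12, 30), target_onset_s = 0.1)
  expect_equal(classify_trial(tr, params = p)$category, "excluded_offscreen")
  # rule 2: too many large excursions (alternating jumps), and rule
  # order: this trace is also anticipatory but rule 2 fires first
  x <- rep(c(0, 5), 15)
  tr <- make_trace(x, target_onset_s = 0.1)
  expect_equal(classify_trial(tr, params = p)$category, "excluded_noisy")
  # rule 3: saccade earlier than 0.1 s after onset
  x <- c(rep(0, 13), rep(12.9, 17))  # step at sample 13->14
  tr <- make_trace(x, target_onset_s = 0, condition = "right")
  expect_lt(tr$times[13] - 0, 0.1)
  expect_equal(classify_trial(tr, params = p)$category,
               "excluded_anticipatory")
  # sticky fixation: no saccade within 5 s
  tr <- make_trace(rep(0, 320), target_onset_s = 0)
  expect_equal(classify_trial(tr, params = p)$category, "sticky_fixation")
  # misdirected: left target, first step rightward
  x <- c(rep(0, 20), rep(12.9, 20))
  tr <- make_trace(x, target_onset_s = 0, condition = "left")
  expect_equal(classify_trial(tr, params = p)$category, "misdirected")
  # valid: right target, rightward saccade, latency = onset - target onset
  tr <- make_trace(x, target_onset_s = 0, condition = "right")
  res <- classify_trial(tr, params = p)
  expect_equal(res$category, "valid_correct")
  expect_equal(res$latency_s, tr$times[20])
  expect_equal(res$responded_side, "right")
})

test_that("manual-block classification uses the button-press response", {
  p <- gazerp_defaults()
  tr <- make_trace(rep(0, 100), target_onset_s = 0, block = "manual",
                   condition = "left")
  res <- classify_trial(tr, list(time_s = 0.45, side = "left"), p)
  expect_equal(res$category, "valid_correct")
  expect_equal(res$latency_s, 0.45)
  # wrong button on a single-target trial is misdirected
  res <- classify_trial(tr, list(time_s = 0.45, side = "right"), p)
  expect_equal(res$category, "misdirected")
  # no response within 5 s is a sticky fixation
  res <- classify_trial(tr, NULL, p)
  expect_equal(res$category, "sticky_fixation")
  # anticipatory button press
  res <- classify_trial(tr, list(time_s = 0.05, side = "left"), p)
  expect_equal(res$category, "excluded_anticipatory")
})

test_that("behaviour summary conserves counts and handles empty cells", {
  cfg <- tiny_config(seed = 31, n = 40)
  s <- assemble_session(cfg)
  cl <- classify_session(s$gaze, s$events)
  expect_equal(nrow(cl), nrow(s$events))
  bs <- summarize_behavior(cl)
  expect_equal(sum(bs$exclusions$n), bs$n_trials)
  expect_true(all(bs$exclusions$fraction >= 0 & bs$exclusions$fraction <= 1))
  # all-equal latencies give sd 0
  fake <- cl[cl$category == "valid_correct", ][1:3, ]
  fake$latency_s <- 0.4
  fake$responded_side <- "left"
  fake$block <- "manual"
  fake$condition <- "left"
  bs2 <- summarize_behavior(fake)
  row <- bs2$cells[bs2$cells$response_type == "manual" &
                   bs2$cells$n_targets == 1 & bs2$cells$side == "left", ]
  expect_equal(row$sd_latency_s, 0)
  expect_equal(row$n, 3L)
  # cells with no valid trials report n = 0 and NA, not zero latency
  empty <- bs2$cells[bs2$cells$response_type == "saccade" &
                     bs2$cells$side == "right" & bs2$cells$n_targets == 2, ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean_latency_s))
})
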