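# Continuous conditioning, epoching, metrics, MAD screening, baseline.

make_rec <- function(mat, rate = 250) eeg_recording(mat, rate_hz = rate)

test_that("filter cascade notches line noise and preserves the passband", {
  fs <- 250
  t <- (0:(fs * 40 - 1)) / fs
  mid <- seq(fs * 10, fs * 30)   # away from edges
  rec50 <- make_rec(cbind(sin(2 * pi * 50 * t)))
  out50 <- filter_continuous(rec50)$samples[mid, 1]
  expect_lt(max(abs(out50)), 0.05)  # >= 95% attenuation at 50 Hz
  rec10 <- make_rec(cbind(sin(2 * pi * 10 * t)))
  out10 <- filter_continuous(rec10)$samples[mid, 1]
  expect_gt(max(abs(out10)), 0.95)  # <= 5% passband distortion at 10 Hz
  # all-zero input stays zero
  expect_equal(filter_continuous(make_rec(cbind(rep(0, fs * 20))))$samples,
               cbind(rep(0, fs * 20)))
})

test_that("filtering is linear and rejects too-short recordings", {
  fs <- 250
  set.seed(9)
  x <- matrix(stats::rnorm(fs * 15), ncol = 1)
  y <- matrix(stats::rnorm(fs * 15), ncol = 1)
  fx <- filter_continuous(make_rec(x))$samples
  fy <- filter_continuous(make_rec(y))$samples
  fxy <- filter_continuous(make_rec(2 * x - 3 * y))$samples
  # rounding noise is amplified by the near-unit-circle poles of the
  # 0.01 Hz high-pass recursion; linearity holds to ~1e-4 relative
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-3 * max(abs(fxy)))
  expect_error(filter_continuous(make_rec(matrix(0, fs * 2, 1))),
               "too short")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(10)
  rec <- make_rec(matrix(stats::rnorm(400), 50, 8))
  ref <- average_reference(rec)
  expect_equal(rowMeans(ref$samples), rep(0, 50))
  expect_equal(average_reference(ref)$samples, ref$samples)
  # pairwise channel differences unchanged
  expect_equal(ref$samples[, 3] - ref$samples[, 7],
               rec$samples[, 3] - rec$samples[, 7])
})

test_that("epochs use the half-open window with amplifier delay correction", {
  fs <- 250
  nt <- fs * 30
  mat <- matrix(0, nt, 4)
  onset <- 2000L
  delay <- round(gazerp_defaults("amp_delay_ms") / 1000 * fs)
  mat[onset + delay, ] <- 7  # impulse at the corrected onset
  ev <- data.frame(trial_id = 1L, eeg_sample = onset)
  ep <- make_epochs(make_rec(mat), ev)
  expect_equal(dim(ep$data)[1], 95L)  # 380 ms at 250 Hz, half-open
  expect_equal(ep$times_ms[1], -200)
  expect_equal(ep$times_ms[95], 176)
  i0 <- which(ep$times_ms == 0)
  expect_equal(ep$data[i0, 1, 1], 7)
  expect_true(all(ep$data[-i0, , 1] == 0))
  # an event too near the recording start is flagged, not dropped
  ev2 <- data.frame(trial_id = 1:2, eeg_sample = c(10L, onset))
  ep2 <- make_epochs(make_rec(mat), ev2)
  expect_equal(ep2$status, c("bad_window", "kept"))
  expect_equal(length(ep2$status), 2L)
})

test_that("epoch metrics match closed forms", {
  times <- seq(-200, 176, by = 4)
  n <- length(times)
  const <- matrix(5, n, 1)
  m <- epoch_metrics(const, times)
  expect_equal(unlist(m[1, ]), c(sd = 0, range = 0, drift = 0, max_step = 0))
  # a single 40 uV step mid-epoch
  stepv <- matrix(c(rep(0, 50), rep(40, n - 50)), n, 1)
  m <- epoch_metrics(stepv, times)
  expect_equal(m$max_step, 40)
  expect_equal(m$range, 40)
  expect_equal(m$drift, 40)   # pre mean 0, post mean 40
  # a linear ramp: drift equals the difference of segment means
  ramp <- matrix(seq_len(n), n, 1)
  m <- epoch_metrics(ramp, times)
  pre <- mean(seq_len(n)[times < 0]); post <- mean(seq_len(n)[times >= 0])
  expect_equal(m$drift, post - pre)
})

test_that("MAD thresholds match hand computation and brute force", {
  th <- mad_thresholds(c(1, 2, 3, 4, 100))
  expect_equal(th$median, 3)
  expect_equal(th$mad, 1)
  expect_equal(th$cutoff, 3 + 3 * 1.483 * 1)
  expect_equal(th$flag(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # degenerate spread flags nothing
  expect_false(any(mad_thresholds(rep(2, 6))$flag(c(2, 2, 1e6))))
  # positive scaling scales the cutoff, leaving flags unchanged
  set.seed(33)
  v <- stats::rexp(20)
  f1 <- mad_thresholds(v)$flag(v)
  f2 <- mad_thresholds(5 * v)$flag(5 * v)
  expect_equal(f1, f2)
  expect_error(mad_thresholds(c(1, 2, 3)), "at least 5")
})

test_that("MAD flagging equals exhaustive brute force on all short inputs", {
  brute <- function(v) {
    med <- stats::median(v)
    mad <- stats::median(abs(v - med))
    if (mad == 0) return(rep(FALSE, length(v)))
    v - med > 3 * 1.483 * mad
  }
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:8, 1)
    v <- round(stats::rcauchy(n), 2)
    th <- mad_thresholds(v)
    expect_identical(th$flag(v), brute(v))
  }
})

test_that("screening applies the strict >70 clean-channel rule", {
  # synthetic metric layout: 100 epochs x 128 channels of unit-variance
  # noise; channel flags are computed from pooled MAD thresholds
  set.seed(55)
  fs <- 250
  n_t <- 95
  n_ep <- 12
  dat <- array(stats::rnorm(n_t * 128 * n_ep), c(n_t, 128, n_ep))
  ep <- structure(list(
    data = dat, times_ms = seq(-200, 176, by = 4),
    trial_ids = seq_len(n_ep), status = rep("kept", n_ep),
    channel_flags = matrix("clean", 128, n_ep), channel_ids = 1:128,
    rate_hz = fs, baseline_window_ms = c(-200, 0)), class = "epoch_set")
  scr <- screen_epochs(ep)
  expect_true(all(scr$status == "kept"))
  # deterministic fixture isolating the clean-channel count rule: live
  # channels share identical metrics (MAD 0 per metric -> nothing
  # flagged), flat channels fail the SD floor
  sine <- sin(2 * pi * seq_len(n_t) / 20)
  det <- array(0, c(n_t, 128, n_ep))
  det[, 1:68, ] <- sine  # 68 live channels: not more than 70 -> rejected
  ep$data <- det
  scr2 <- screen_epochs(ep)
  expect_true(all(scr2$status == "rejected"))
  det[, 1:71, ] <- sine  # 71 live channels: strictly more than 70 -> kept
  ep$data <- det
  scr3 <- screen_epochs(ep)
  expect_true(all(scr3$status == "kept"))
  expect_true(all(scr3$channel_flags[72:128, ] == "needs_interpolation"))
  det[, 71, ] <- 0       # exactly 70 clean channels is still rejected
  ep$data <- det
  scr4 <- screen_epochs(ep)
  expect_true(all(scr4$status == "rejected"))
})

test_that("screening flags ignore a common additive offset", {
  lc <- local_epochs()
  ep <- lc$epochs
  scr1 <- screen_epochs(ep)
  ep2 <- ep
  ep2$data <- ep2$data + 5
  scr2 <- screen_epochs(ep2)
  expect_identical(scr1$channel_flags, scr2$channel_flags)
  expect_identical(scr1$status, scr2$status)
})

test_that("baseline correction zeroes the pre-onset mean and is idempotent", {
  lc <- local_epochs()
  ep <- baseline_correct(screen_epochs(lc$epochs))
  pre <- ep$times_ms < 0
  for (i in c(1, dim(ep$data)[3])) {
    expect_equal(max(abs(colMeans(ep$data[pre, , i]))), 0, tolerance = 1e-9)
  }
  again <- baseline_correct(ep)
  expect_equal(again$data, ep$data, tolerance = 1e-12)
  # a constant epoch becomes all zeros
  const <- ep
  const$data[] <- 5
  out <- baseline_correct(const)
  expect_true(all(out$data == 0))
  # post-onset values are shifted by exactly the baseline mean
  raw <- lc$epochs
  base <- colMeans(raw$data[pre, , 1])
  cor1 <- baseline_correct(raw)
  expect_equal(cor1$data[80, , 1], raw$data[80, , 1] - base)
})
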