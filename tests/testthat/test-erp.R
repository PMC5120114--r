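# Saccade gating, condition-cell assignment, cluster waveforms, peak
# measures, and effect sizes.

test_that("peak_measure finds the windowed extremum with earliest-tie rule", {
  t <- seq(-200, 176, by = 4)
  bump <- 2 * exp(-(t - 140)^2 / (2 * 15^2))
  wf <- list(times_ms = t, uv = bump)
  pk <- peak_measure(wf, c(80, 180), "positive")
  expect_equal(pk$amplitude_uV, 2)
  expect_equal(pk$latency_ms, 140)
  # negated bump, negative polarity
  pk <- peak_measure(list(times_ms = t, uv = -bump), c(80, 180), "negative")
  expect_equal(pk$amplitude_uV, -2)
  expect_equal(pk$latency_ms, 140)
  # two equal maxima: the earlier latency wins
  flat <- rep(0, length(t)); flat[t == 120] <- 3; flat[t == 160] <- 3
  pk <- peak_measure(list(times_ms = t, uv = flat), c(80, 180), "positive")
  expect_equal(pk$latency_ms, 120)
  # the restriction to the window is honoured
  spike <- rep(0, length(t)); spike[t == 40] <- 50; spike[t == 120] <- 1
  pk <- peak_measure(list(times_ms = t, uv = spike), c(80, 180), "positive")
  expect_equal(pk$amplitude_uV, 1)
  expect_error(peak_measure(wf, c(500, 600), "positive"), "outside")
})

test_that("peak_measure equals an exhaustive scan on random waveforms", {
  t <- seq(-200, 176, by = 4)
  set.seed(66)
  for (rep in 1:50) {
    uv <- stats::rnorm(length(t))
    win <- sort(sample(t, 2))
    if (win[1] == win[2]) next
    sel <- t >= win[1] & t <= win[2]
    pk <- peak_measure(list(times_ms = t, uv = uv), win, "positive")
    expect_equal(pk$amplitude_uV, max(uv[sel]))
    expect_equal(pk$latency_ms, t[sel][which.max(uv[sel])])
    pk <- peak_measure(list(times_ms = t, uv = uv), win, "negative")
    expect_equal(pk$amplitude_uV, min(uv[sel]))
  }
})

test_that("gating removes epochs whose corrected latency is too early", {
  lc <- local_epochs()
  ep <- screen_epochs(lc$epochs)
  n <- length(ep$trial_ids)
  cl <- data.frame(
    trial_id = ep$trial_ids, block = "saccade", condition = "right",
    target_onset_s = 0,
    saccade_onset_s = c(0.200, 0.300, NA, 0.229, 0.231,
                        rep(0.5, n - 5)),
    responded_side = "right", stringsAsFactors = FALSE)
  gated <- gate_by_saccade(ep, cl)
  # 0.200 - 0.050 = 0.150 < 0.180 -> excluded
  expect_equal(gated$status[1], "rejected_early_saccade")
  # 0.300 - 0.050 = 0.250 -> kept
  expect_equal(gated$status[2], "kept")
  # no detected saccade (e.g. held fixation in the manual block) -> kept
  expect_equal(gated$status[3], "kept")
  # boundary: 0.229 - 0.050 = 0.179 < 0.180 excluded; 0.231 kept
  expect_equal(gated$status[4], "rejected_early_saccade")
  expect_equal(gated$status[5], "kept")
  # a missing gaze record excludes the epoch with a logged reason
  cl2 <- cl[-6, ]
  gated2 <- gate_by_saccade(ep, cl2)
  expect_equal(gated2$status[6], "rejected_no_gaze")
  expect_equal(gated2$gating$decision[6], "rejected_no_gaze")
})

test_that("no retained epoch has corrected saccade latency below the limit", {
  run <- local_run()
  g <- run$qc
  kept <- g[g$status == "kept" & !is.na(g$corrected_latency_s), ]
  if (nrow(kept))
    expect_true(all(kept$corrected_latency_s >=
                      gazerp_defaults("early_saccade_ms") / 1000))
})

test_that("hemisphere labels derive from cluster side and responded side", {
  lc <- local_epochs()
  ep <- screen_epochs(lc$epochs)
  cl <- classify_session(lc$session$gaze, lc$session$events)
  gated <- gate_by_saccade(ep, cl)
  cells <- assign_cells(gated, cl, erp_clusters(lc$session$layout))
  left_resp <- cells[!is.na(cells$responded_side) &
                       cells$responded_side == "left", ]
  expect_true(all(left_resp$hemisphere[left_resp$cluster == "O2"] ==
                    "contralateral"))
  expect_true(all(left_resp$hemisphere[left_resp$cluster == "O1"] ==
                    "ipsilateral"))
  right_resp <- cells[!is.na(cells$responded_side) &
                        cells$responded_side == "right", ]
  expect_true(all(right_resp$hemisphere[right_resp$cluster == "O2"] ==
                    "ipsilateral"))
  # hemisphere-resolved counts sum to kept epochs with known side per cluster
  kept_known <- sum(gated$status == "kept" &
                      ep$trial_ids %in% cl$trial_id[!is.na(cl$responded_side)])
  o1 <- cells[cells$cluster == "O1" & !is.na(cells$hemisphere), ]
  expect_equal(nrow(o1), kept_known)
})

test_that("cluster waveforms average channels then epochs, linearly", {
  lc <- local_epochs()
  ep <- baseline_correct(screen_epochs(lc$epochs))
  occ <- erp_clusters(lc$session$layout)$O1
  kept <- which(ep$status == "kept")
  w12 <- cluster_waveform(ep, occ, kept[1:2])
  w1 <- cluster_waveform(ep, occ, kept[1])
  w2 <- cluster_waveform(ep, occ, kept[2])
  expect_equal(w12$uv, (w1$uv + w2$uv) / 2, tolerance = 1e-12)
  expect_equal(w12$n, 2L)
  # empty selection is explicit, never zeros
  w0 <- cluster_waveform(ep, occ, integer(0))
  expect_null(w0$uv)
  expect_equal(w0$n, 0L)
  # a single epoch with identical channels equals that channel
  ep2 <- ep
  ep2$data[, , kept[1]] <- ep$data[, occ[1], kept[1]]
  w <- cluster_waveform(ep2, occ, kept[1])
  expect_equal(w$uv, ep$data[, occ[1], kept[1]])
})

test_that("pooled-SD Cohen's d reproduces the reference effect sizes", {
  # response-type effect on behavioural latency
  expect_equal(cohens_d(0.308, 0.038, 0.480, 0.098), 2.317,
               tolerance = 0.005)
  # target-number effect on posterior peak amplitude
  expect_equal(cohens_d(2.01, 2.54, 0.83, 2.60), 0.457, tolerance = 0.005)
  # identical groups give d = 0
  expect_equal(cohens_d(1.5, 0.3, 1.5, 0.3), 0)
  expect_error(cohens_d(1, 0, 1, 0), "pooled SD")
})

test_that("condition_table summarizes groups and omits degenerate d", {
  x <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  ct <- condition_table(x, g)
  expect_equal(ct$groups$mean, c(2, 11))
  expect_equal(ct$d, cohens_d(2, 1, 11, 1))
  ct2 <- condition_table(c(1, 2), c("a", "b"))  # n = 1 per group
  expect_true(is.na(ct2$d))
  expect_match(ct2$d_reason, "degenerate")
})

test_that("mirrored sessions swap hemispheres but keep amplitudes", {
  cfg <- tiny_noiseless_config(seed = 56, n = 16)
  s <- assemble_session(cfg)
  run <- run_pipeline(s)
  # mirror the session: flip gaze and stimulus sides and reflect the
  # scalp geometry (x -> -x). The EEG data are untouched; spherical
  # distances are reflection-invariant, so screening and interpolation
  # are numerically identical, and only the labelling changes.
  flip <- function(v) ifelse(v == "left", "right",
                             ifelse(v == "right", "left", v))
  m <- s
  m$gaze <- lapply(s$gaze, function(tr) {
    tr$x <- -tr$x
    tr$condition <- flip(tr$condition)
    tr
  })
  m$events$condition <- flip(s$events$condition)
  m$events$responded_side <- flip(s$events$responded_side)
  m$layout$x <- -s$layout$x
  runm <- run_pipeline(m)
  a <- run$erp[run$erp$cluster %in% c("O1", "O2", "FC3", "FC4"), ]
  b <- runm$erp[runm$erp$cluster %in% c("O1", "O2", "FC3", "FC4"), ]
  # for the fixed-id clusters, ipsi and contra swap while every
  # amplitude, latency and count is unchanged; marginals are invariant
  b$hemi_orig <- c(ipsilateral = "contralateral",
                   contralateral = "ipsilateral", all = "all")[b$hemisphere]
  mrg <- merge(a, b,
               by.x = c("cluster", "response_type", "n_targets",
                        "hemisphere"),
               by.y = c("cluster", "response_type", "n_targets",
                        "hemi_orig"))
  expect_equal(nrow(mrg), nrow(a))
  expect_equal(mrg$amplitude_uV.x, mrg$amplitude_uV.y, tolerance = 1e-12)
  expect_equal(mrg$latency_ms.x, mrg$latency_ms.y)
  expect_equal(mrg$n.x, mrg$n.y)
})
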