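test_that("beat count of a periodic train matches the period arithmetic", {
  fs <- 250
  beat <- oracle_beat(fs)
  n_rep <- ceiling(30 / 0.8)
  x <- rep(beat$samples, n_rep)[seq_len(30 * fs)]
  beats <- segment_beats(x, fs)
  # 30 s at 75 bpm: full periods fully inside the window
  expect_true(abs(length(beats) - 36) <= 1)
  lens <- vapply(beats, function(b) length(b$samples), 0L)
  expect_true(all(abs(lens - 0.8 * fs) <= 2))
})

test_that("constant signals segment into zero beats", {
  expect_length(segment_beats(rep(0.5, 2500), 250), 0)
})

test_that("partial first and last periods are discarded", {
  fs <- 250
  beat <- oracle_beat(fs)
  # 2.2 periods: one complete onset-to-onset period flanked by partial
  # periods at both ends
  x <- rep(beat$samples, 3)[1:550]
  beats <- segment_beats(x, fs)
  expect_length(beats, 1L)
  expect_lte(abs(length(beats[[1]]$samples) - (0.8 * fs + 1)), 2)
})

test_that("fiducial detection matches the analytic template oracle", {
  fs <- 250
  beat <- oracle_beat(fs)
  b <- structure(list(onset_index = 1L, samples = beat$samples,
                      sampling_rate_hz = fs), class = "pulse_beat")
  f <- detect_fiducials(b)
  truth <- beat$fiducials_true
  expect_false(f$degenerate)
  expect_samples_close(f$dp1_time, truth$dp1_time, fs, 1)
  expect_samples_close(f$max_slope_time, truth$max_slope_time, fs, 1)
  expect_samples_close(f$systolic_time, truth$systolic_time, fs, 1)
  expect_samples_close(f$notch_time, truth$notch_time, fs, 1)
  expect_samples_close(f$dicrotic_time, truth$dicrotic_time, fs, 1)
  expect_samples_close(f$dp2_time, truth$dp2_time, fs, 1)
})

test_that("beats without a dicrotic bump are flagged degenerate", {
  fs <- 250
  p <- beat_template_params(0.3, 1.0, 0.5, 0, 0.4, 0.8)
  beat <- generate_beat_template(p, fs)
  b <- structure(list(onset_index = 1L, samples = beat$samples,
                      sampling_rate_hz = fs), class = "pulse_beat")
  expect_true(detect_fiducials(b)$degenerate)
})

test_that("equal-height early maxima resolve to the first (systolic) peak", {
  fs <- 250
  t <- (0:199) / fs
  x <- exp(-(t - 0.2)^2 / (2 * 0.03^2)) + exp(-(t - 0.35)^2 / (2 * 0.03^2)) +
    0.4 * exp(-(t - 0.55)^2 / (2 * 0.04^2))
  b <- structure(list(onset_index = 1L, samples = x, sampling_rate_hz = fs),
                 class = "pulse_beat")
  f <- detect_fiducials(b)
  expect_samples_close(f$systolic_time, 0.2, fs, 1)
})

test_that("feature formulas follow their interval and ratio definitions", {
  fid <- structure(list(
    dp1_time = 0, dp1_amp = 0,
    max_slope_time = 0.07, max_slope = 12.5,
    systolic_time = 0.15, systolic_amp = 1.0,
    notch_time = 0.3, notch_amp = 0.35,
    dicrotic_time = 0.40, dicrotic_amp = 0.5,
    dp2_time = 0.80, dp2_amp = 0.02,
    degenerate = FALSE), class = "fiducial_points")
  v <- compute_features(fid, prev_systolic_time = 0.15 - 0.8)
  expect_equal(unname(v["heart_rate_bpm"]), 75)            # 60 / 0.8
  expect_equal(unname(v["aug_index"]), 2.0)                # 1.0 / 0.5
  expect_equal(unname(v[c("t1_s", "t2_s", "t3_s")]), c(0.15, 0.25, 0.40))
  expect_equal(unname(v["max_slope"]), 12.5)
  expect_equal(unname(v["systolic_peak_amp"]), 1.0)

  # literature convention inverts the ratio
  v2 <- compute_features(fid, 0.15 - 0.8, ai_convention = "dicrotic_over_systolic")
  expect_equal(unname(v2["aug_index"]), 0.5)

  # non-positive dicrotic amplitude after baseline shift excludes the beat
  fid_bad <- fid; fid_bad$dicrotic_amp <- -0.1
  expect_null(compute_features(fid_bad, 0.15 - 0.8))
  expect_error(compute_features(fid, prev_systolic_time = 0.2), "precede")
})

test_that("record features are the median over beats and robust to outliers", {
  fs <- 250
  # sharp-footed template so segmented onsets coincide with the beat start
  p <- beat_template_params(0.15, 1.0, 0.40, 0.4, 0.275, 0.8, valley_amp = 0.5)
  beat <- generate_beat_template(p, fs)
  x <- rep(beat$samples, 12)
  fz <- featurize_recording(x, fs)
  expect_false(fz$rejected)
  # identical beats: the median equals any single beat's feature vector
  beats <- segment_beats(x, fs)
  f_prev <- detect_fiducials(beats[[2]])
  single <- compute_features(detect_fiducials(beats[[3]]), f_prev$systolic_time)
  expect_equal(fz$features, single, tolerance = 1e-10)

  # one distorted beat among many leaves the median unchanged
  x_out <- x
  x_out[2000:2100] <- x_out[2000:2100] + 0.8
  fz_out <- featurize_recording(x_out, fs)
  expect_equal(unname(fz_out$features["t1_s"]), unname(fz$features["t1_s"]))

  # records with too few beats are rejected with a reason
  short <- rep(beat$samples, 2)
  fz_short <- featurize_recording(short, fs)
  expect_true(fz_short$rejected)
  expect_match(fz_short$reason, "too_few")
})

test_that("fiducial times are shift-equivariant and features shift-invariant", {
  fs <- 250
  beat <- oracle_beat(fs)
  x <- rep(beat$samples, 10)
  k <- 37L
  x_shift <- c(x[(k + 1):length(x)])
  f1 <- featurize_recording(x, fs)
  f2 <- featurize_recording(x_shift, fs)
  # beats common to both windows give identical feature medians
  expect_equal(f1$features, f2$features, tolerance = 1e-9)
  # and individual fiducial times move by exactly k / fs
  b1 <- detect_fiducials(segment_beats(x, fs)[[3]])
  b2 <- detect_fiducials(segment_beats(x_shift, fs)[[3]])
  shift <- b1$systolic_time - b2$systolic_time
  expect_equal(b1$dp1_time - b2$dp1_time, shift, tolerance = 1e-9)
  expect_equal(b1$notch_time - b2$notch_time, shift, tolerance = 1e-9)
  expect_equal(b1$dicrotic_time - b2$dicrotic_time, shift, tolerance = 1e-9)
})

test_that("amplitude scaling scales amplitudes and preserves ratios/timings", {
  fs <- 250
  x <- rep(oracle_beat(fs)$samples, 10)
  f1 <- featurize_recording(x, fs)$features
  f2 <- featurize_recording(3 * x, fs)$features
  for (nm in c("systolic_peak_amp", "dicrotic_peak_amp", "notch_amp",
               "dp2_amp", "max_slope"))
    expect_equal(unname(f2[nm]), 3 * unname(f1[nm]), tolerance = 1e-9)
  for (nm in c("aug_index", "heart_rate_bpm", "t1_s", "t2_s", "t3_s"))
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 1e-9)
})

test_that("fiducial ordering holds for every accepted beat across seeds", {
  cfg <- tiny_sim_config()
  for (seed in c(3, 17)) {
    set.seed(seed)
    rec <- generate_recording(cfg, c(runif(1, 98, 138), runif(1, 58, 81)),
                              seed = 500 + seed)
    den <- denoise(rec$channels[, 2], cfg$sampling_rate_hz)
    for (b in segment_beats(den, cfg$sampling_rate_hz)) {
      f <- detect_fiducials(b)
      if (isTRUE(f$degenerate)) next
      times <- c(f$dp1_time, f$max_slope_time, f$systolic_time,
                 f$notch_time, f$dicrotic_time, f$dp2_time)
      expect_true(all(diff(times) > 0))
      expect_gte(f$systolic_amp, f$dicrotic_amp)
      expect_gte(f$dicrotic_amp, f$notch_amp)
    }
  }
})
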