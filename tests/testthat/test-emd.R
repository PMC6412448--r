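test_that("monotone and constant signals yield zero IMFs", {
  ramp <- seq(0, 1, length.out = 200)
  dec <- emd_decompose(ramp, 100)
  expect_length(dec$imfs, 0)
  expect_equal(dec$residue, ramp)

  dec2 <- emd_decompose(rep(1, 50), 100)
  expect_length(dec2$imfs, 0)
  expect_equal(dec2$residue, rep(1, 50))
})

test_that("decomposition is complete to 1e-8 of the signal range", {
  set.seed(42)
  for (i in 1:5) {
    x <- cumsum(rnorm(600)) + sin(2 * pi * 3 * seq(0, 6, length.out = 600))
    dec <- emd_decompose(x, 100)
    rec <- Reduce(`+`, c(dec$imfs, list(dec$residue)))
    expect_lt(max(abs(rec - x)), 1e-8 * diff(range(x)))
  }
})

test_that("IMFs satisfy the extrema / zero-crossing balance", {
  set.seed(7)
  t <- seq(0, 10, by = 1 / 100)
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 0.4 * t) + rnorm(length(t), 0, 0.05)
  dec <- emd_decompose(x, 100)
  for (imf in dec$imfs) {
    ex <- pulsebp:::find_extrema(imf)
    n_ext <- length(ex$maxima) + length(ex$minima)
    s <- sign(imf); s <- s[s != 0]
    n_zc <- sum(diff(s) != 0)
    # allow the small boundary slack inherent to finite-support sifting
    expect_lte(abs(n_ext - n_zc), 3)
  }
})

test_that("a two-tone mixture separates into its components", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  hi <- sin(2 * pi * 5 * t)
  lo <- sin(2 * pi * 0.5 * t)
  dec <- emd_decompose(hi + lo, fs)
  ctr <- seq(floor(0.1 * length(t)) + 1, ceiling(0.9 * length(t)))
  expect_gt(cor(dec$imfs[[1]][ctr], hi[ctr]), 0.95)
})

test_that("the envelope of a sinusoid is flat at its amplitude", {
  t <- seq(0, 5, by = 1 / 100)
  x <- 1.5 * sin(2 * pi * 2 * t)
  up <- envelope(x, "upper")
  mid <- seq(floor(0.1 * length(x)) + 1, ceiling(0.9 * length(x)))
  expect_lt(max(abs(up[mid] - 1.5)) / 1.5, 0.02)
  # lower envelope mirrors the upper envelope of the negated signal
  lo <- envelope(x, "lower")
  expect_equal(lo, -envelope(-x, "upper"), tolerance = 1e-12)
})

test_that("envelope requires at least two extrema", {
  expect_error(envelope(seq_len(100) / 10, "upper"), "monotone")
})

test_that("IMF classification partitions by dominant frequency", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  dec <- emd_decompose(sin(2 * pi * 1 * t), fs)
  cls <- classify_imfs(dec, beat_band_hz = c(0.5, 8))
  expect_true(all(seq_along(dec$imfs) %in%
                    c(cls$signal, cls$noise, cls$baseline)))
  expect_true(1 %in% cls$signal)
  expect_identical(cls$residue_class, "baseline")

  # a 30 Hz oscillation is noise for a (0.5, 8) Hz pulse band
  dec_hi <- emd_decompose(sin(2 * pi * 30 * t), fs)
  cls_hi <- classify_imfs(dec_hi, beat_band_hz = c(0.5, 8))
  expect_true(1 %in% cls_hi$noise)
})

test_that("denoising removes wander and noise but keeps the beat shape", {
  cfg <- tiny_sim_config(noise_sd = 0, baseline_amp = 0, artifact_prob = 0)
  rec <- generate_recording(cfg, c(120, 70), seed = 5)
  clean <- rec$clean
  fs <- cfg$sampling_rate_hz

  # clean input: output approximates the drift-free, mean-centred input
  den <- denoise(clean, fs)
  ctr <- function(v) v - mean(v)
  mid <- seq(floor(0.1 * length(clean)) + 1, ceiling(0.9 * length(clean)))
  beat_amp <- diff(range(clean))
  rmse_mid <- sqrt(mean((ctr(den)[mid] - ctr(clean)[mid])^2))
  expect_lt(rmse_mid, 0.05 * beat_amp)

  # noisy input: denoising strictly reduces RMSE to the clean reference
  set.seed(9)
  noisy <- clean + rnorm(length(clean), 0, sqrt(var(clean) / 10))
  den_n <- denoise(noisy, fs)
  expect_lt(sqrt(mean((ctr(den_n) - ctr(clean))^2)),
            sqrt(mean((ctr(noisy) - ctr(clean))^2)))

  # denoising an already-denoised signal changes it by < 5% RMSE
  den2 <- denoise(den_n, fs)
  expect_lt(sqrt(mean((den2 - den_n)^2)) / diff(range(den_n)), 0.05)
})

test_that("denoising 0.1 Hz wander removes >= 90% of sub-0.3 Hz power", {
  cfg <- tiny_sim_config(noise_sd = 0, baseline_amp = 0.4,
                         baseline_freq_hz = 0.1, artifact_prob = 0)
  rec <- generate_recording(cfg, c(115, 72), seed = 21)
  fs <- cfg$sampling_rate_hz
  x <- rec$channels[, 2]
  den <- denoise(x, fs)
  lf_power <- function(v) {
    sp <- Mod(stats::fft(v - mean(v)))^2
    fr <- (seq_along(v) - 1) * fs / length(v)
    sum(sp[fr > 0 & fr < 0.3])
  }
  expect_lt(lf_power(den), 0.1 * lf_power(x))
})

test_that("channel selection picks the aligned channel and breaks ties low", {
  cfg <- tiny_sim_config()
  rec <- generate_recording(cfg, c(125, 75), seed = 11)
  sq <- select_best_channel(rec)
  expect_s3_class(sq, "signal_quality")
  expect_identical(sq$selected_channel, which.max(sq$scores))
  expect_identical(sq$selected_channel, 2L)

  # single channel: that channel wins
  one <- select_best_channel(rec$channels[, 2, drop = FALSE],
                             sampling_rate_hz = cfg$sampling_rate_hz)
  expect_identical(one$selected_channel, 1L)

  # identical channels: lowest index wins
  two <- select_best_channel(cbind(rec$channels[, 2], rec$channels[, 2]),
                             sampling_rate_hz = cfg$sampling_rate_hz)
  expect_identical(two$selected_channel, 1L)

  # flat channels are an error
  expect_error(select_best_channel(matrix(0, 1000, 2), sampling_rate_hz = 250),
               "no usable channel")
})
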