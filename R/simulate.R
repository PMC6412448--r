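#' Simulation configuration for synthetic pulse-wave corpora
#'
#' Builds and validates the configuration for the synthetic multi-channel
#' radial pulse-wave generator. The generator emulates a tonometric
#' measurement scenario: a 3-element linear sensor array in which exactly one
#' element sits well-aligned over the artery (the channel with the maximal
#' gain), while the others pick up an attenuated copy of the same pressure
#' waveform. All channels share baseline wander (respiration-like drift),
#' additive wide-band noise, and occasional motion-artifact transients.
#'
#' Defaults reflect a screening-clinic population: systolic pressure between
#' 98 and 138 mmHg, diastolic between 58 and 81 mmHg, 23 subjects with 49
#' records each (1127 records).
#'
#' @param n_subjects number of subjects in the corpus.
#' @param records_per_subject recordings per subject.
#' @param duration_s length of each recording in seconds.
#' @param sampling_rate_hz sampling rate in Hz (>= 100).
#' @param hr_range_bpm length-2 numeric, subject heart-rate range in bpm.
#' @param sbp_range_mmHg length-2 numeric, systolic reference range in mmHg.
#' @param dbp_range_mmHg length-2 numeric, diastolic reference range in mmHg.
#' @param noise_sd additive white-noise standard deviation as a fraction of
#'   the beat amplitude.
#' @param baseline_amp baseline-wander amplitude as a fraction of the beat
#'   amplitude.
#' @param baseline_freq_hz baseline-wander frequency in Hz.
#' @param artifact_prob probability, per beat, of a motion-artifact transient.
#' @param channel_gains 3-vector of channel attenuation factors in [0, 1];
#'   exactly one entry must equal the maximum (the aligned channel).
#' @param seed integer seed controlling the whole corpus.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 23L,
                       records_per_subject = 49L,
                       duration_s = 10,
                       sampling_rate_hz = 250,
                       hr_range_bpm = c(60, 90),
                       sbp_range_mmHg = c(98, 138),
                       dbp_range_mmHg = c(58, 81),
                       noise_sd = 0.05,
                       baseline_amp = 0.3,
                       baseline_freq_hz = 0.25,
                       artifact_prob = 0.05,
                       channel_gains = c(0.3, 1.0, 0.4),
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    records_per_subject = as.integer(records_per_subject),
    duration_s = duration_s,
    sampling_rate_hz = sampling_rate_hz,
    hr_range_bpm = as.numeric(hr_range_bpm),
    sbp_range_mmHg = as.numeric(sbp_range_mmHg),
    dbp_range_mmHg = as.numeric(dbp_range_mmHg),
    noise_sd = noise_sd,
    baseline_amp = baseline_amp,
    baseline_freq_hz = baseline_freq_hz,
    artifact_prob = artifact_prob,
    channel_gains = as.numeric(channel_gains),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L, cfg$records_per_subject >= 1L)
  if (cfg$sampling_rate_hz < 100)
    stop("sampling_rate_hz must be >= 100")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  rng_ok <- function(r) length(r) == 2 && r[1] < r[2]
  if (!rng_ok(cfg$sbp_range_mmHg)) stop("sbp_range_mmHg must be (low, high) with low < high")
  if (!rng_ok(cfg$dbp_range_mmHg)) stop("dbp_range_mmHg must be (low, high) with low < high")
  if (!rng_ok(cfg$hr_range_bpm)) stop("hr_range_bpm must be (low, high) with low < high")
  if (cfg$sbp_range_mmHg[1] <= cfg$dbp_range_mmHg[2])
    stop("sbp range must lie strictly above dbp range (per-draw SBP > DBP)")
  if (cfg$artifact_prob < 0 || cfg$artifact_prob > 1)
    stop("artifact_prob must be in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$baseline_amp < 0)
    stop("noise_sd and baseline_amp must be non-negative")
  g <- cfg$channel_gains
  if (any(g < 0 | g > 1)) stop("channel_gains must lie in [0, 1]")
  if (sum(g == max(g)) != 1L)
    stop("exactly one channel_gain must equal the maximum (the aligned channel)")
  invisible(cfg)
}

#' Beat template parameters
#'
#' Parameters of a single-beat pressure template: a systolic bump and a later
#' dicrotic bump (each a Gaussian) on a diastolic baseline. `dicrotic_amp = 0`
#' gives a degenerate single-peaked beat whose dicrotic landmarks are
#' undefined.
#'
#' @param systolic_time_s time of the systolic bump centre (s from onset).
#' @param systolic_amp systolic bump amplitude (arbitrary pressure units).
#' @param dicrotic_time_s time of the dicrotic bump centre (s from onset).
#' @param dicrotic_amp dicrotic bump amplitude; 0 allowed (degenerate beat).
#' @param notch_time_s nominal dicrotic-notch time; must lie between the two
#'   bump centres. The true notch is located numerically on the sampled beat.
#' @param beat_period_s beat period in seconds.
#' @param onset_amp diastolic baseline level.
#' @param valley_amp amplitude of a beat-periodic half-sine fundamental
#'   (`sin(pi * t / period)`), zero at the beat boundaries; concatenated
#'   beats then meet in a V-shaped diastolic foot like a real arterial
#'   waveform, so the onset minimum is sharply localized. 0 gives the plain
#'   two-bump template.
#' @return a validated list of class `beat_template_params`.
#' @export
beat_template_params <- function(systolic_time_s, systolic_amp,
                                 dicrotic_time_s, dicrotic_amp,
                                 notch_time_s, beat_period_s,
                                 onset_amp = 0, valley_amp = 0) {
  p <- list(systolic_time_s = systolic_time_s, systolic_amp = systolic_amp,
            dicrotic_time_s = dicrotic_time_s, dicrotic_amp = dicrotic_amp,
            notch_time_s = notch_time_s, beat_period_s = beat_period_s,
            onset_amp = onset_amp, valley_amp = valley_amp)
  if (beat_period_s <= 0) stop("beat_period_s must be positive")
  if (!(0 < systolic_time_s && systolic_time_s < notch_time_s &&
        notch_time_s < dicrotic_time_s && dicrotic_time_s < beat_period_s))
    stop("require 0 < systolic_time < notch_time < dicrotic_time < beat_period")
  if (!(systolic_amp > dicrotic_amp && dicrotic_amp >= 0))
    stop("require systolic_amp > dicrotic_amp >= 0")
  if (onset_amp >= dicrotic_amp && dicrotic_amp > 0)
    stop("require dicrotic_amp > onset_amp for a non-degenerate beat")
  if (valley_amp < 0 || valley_amp >= systolic_amp)
    stop("require 0 <= valley_amp < systolic_amp")
  class(p) <- "beat_template_params"
  p
}

# Gaussian bump widths as fractions of the template timings; chosen so that
# the two bumps merge into the canonical peak-notch-peak morphology over the
# physiological parameter range.
.sys_width <- function(p) 0.34 * p$systolic_time_s
.dic_width <- function(p) 0.26 * (p$dicrotic_time_s - p$systolic_time_s)

#' Generate one sampled beat from a template
#'
#' Evaluates the two-bump beat template over one period and locates the six
#' beat landmarks numerically on the sampled waveform: onset (diastolic point
#' 1), maximum-slope point, systolic peak, dicrotic notch, dicrotic peak, and
#' end of period (diastolic point 2). The systolic peak is the sample argmax
#' over the first portion of the beat; the notch is the interior minimum
#' between the bumps. With `dicrotic_amp = 0` the beat is single-peaked and
#' the dicrotic landmarks are returned as `NA` with `degenerate = TRUE`.
#'
#' @param params a [beat_template_params()] object.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return list with `samples`, `time_s`, `fiducials_true` (named times in s
#'   and amplitudes) and `degenerate`.
#' @export
generate_beat_template <- function(params, sampling_rate_hz) {
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive")
  p <- params
  n <- round(p$beat_period_s * sampling_rate_hz)
  if (n < 4) stop("beat period too short for the sampling rate")
  t <- (seq_len(n) - 1) / sampling_rate_hz
  ws <- .sys_width(p); wd <- .dic_width(p)
  y <- p$onset_amp +
    p$systolic_amp * exp(-(t - p$systolic_time_s)^2 / (2 * ws^2))
  if (p$dicrotic_amp > 0)
    y <- y + p$dicrotic_amp * exp(-(t - p$dicrotic_time_s)^2 / (2 * wd^2))
  if (!is.null(p$valley_amp) && p$valley_amp > 0)
    y <- y + p$valley_amp * sin(pi * t / p$beat_period_s)

  # landmark ground truth from the sampled template
  i_sys_lim <- max(which(t <= (p$systolic_time_s + p$notch_time_s) / 2))
  i_sys <- which.max(y[seq_len(i_sys_lim)])
  d <- diff(y[seq_len(i_sys)])
  i_ms <- if (length(d)) which.max(d) else 1L
  fid <- list(
    dp1_time = 0, dp1_amp = y[1],
    max_slope_time = (i_ms - 0.5) / sampling_rate_hz,
    max_slope = if (length(d)) max(d) * sampling_rate_hz else NA_real_,
    systolic_time = t[i_sys], systolic_amp = y[i_sys],
    notch_time = NA_real_, notch_amp = NA_real_,
    dicrotic_time = NA_real_, dicrotic_amp = NA_real_,
    dp2_time = p$beat_period_s, dp2_amp = y[1]
  )
  degenerate <- TRUE
  if (p$dicrotic_amp > 0) {
    i_dic_lim <- max(which(t <= (p$dicrotic_time_s + p$beat_period_s) / 2))
    i_dc <- min(round(p$dicrotic_time_s * sampling_rate_hz) + 1L, n)
    # notch: interior minimum between the systolic peak and the dicrotic
    # bump centre; dicrotic peak: maximum after the notch
    i_ntc <- i_sys + which.min(y[(i_sys + 1L):i_dc])
    i_dic <- i_ntc + which.max(y[(i_ntc + 1L):i_dic_lim])
    if (i_ntc > i_sys && i_ntc < i_dic && y[i_dic] > y[i_ntc]) {
      fid$notch_time <- t[i_ntc]; fid$notch_amp <- y[i_ntc]
      fid$dicrotic_time <- t[i_dic]; fid$dicrotic_amp <- y[i_dic]
      degenerate <- FALSE
    }
  }
  list(samples = y, time_s = t, fiducials_true = fid, degenerate = degenerate)
}

# Monotone map from a (SBP, DBP) pair to beat-template morphology.
# Documented contract (also in the vignette):
#   * systolic bump amplitude is affine in SBP,
#   * upstroke time T1 shrinks affinely with pulse pressure (so the maximum
#     slope grows with SBP),
#   * the dicrotic-to-systolic amplitude ratio and the systolic-to-dicrotic
#     spacing both grow affinely with DBP,
#   * the diastolic baseline level is affine in DBP.
# This makes feature -> BP recovery learnable by construction while keeping
# every template inside the valid morphology envelope for SBP in [98, 138]
# and DBP in [58, 81] mmHg.
bp_morphology <- function(sbp, dbp, hr_bpm) {
  pp <- sbp - dbp
  systolic_time <- 0.16 - 0.0008 * (pp - 40)
  systolic_amp <- 0.90 + 0.012 * (sbp - 118)
  ratio <- 0.32 + 0.006 * (dbp - 69.5)
  dicrotic_time <- systolic_time + 0.22 + 0.0025 * (dbp - 69.5)
  beat_template_params(
    systolic_time_s = systolic_time,
    systolic_amp = systolic_amp,
    dicrotic_time_s = dicrotic_time,
    dicrotic_amp = ratio * systolic_amp,
    notch_time_s = (systolic_time + dicrotic_time) / 2,
    beat_period_s = 60 / hr_bpm,
    onset_amp = 0.10 + 0.004 * (dbp - 69.5),
    valley_amp = 0.55 * systolic_amp
  )
}

#' Generate one multi-channel pulse recording with ground truth
#'
#' Concatenates template beats with per-beat lognormal heart-period jitter,
#' then forms each sensor channel as `gain * clean + baseline wander + white
#' noise + artifacts`. Artifact transients (damped sinusoids) occur per beat
#' with probability `artifact_prob` and hit all channels simultaneously, as a
#' wrist movement would. Ground truth records every beat's six landmark times
#' and the reference pressures.
#'
#' @param config a [sim_config()] object.
#' @param subject_bp length-2 numeric `(SBP, DBP)` in mmHg for this record.
#' @param seed integer seed for this record.
#' @param hr_bpm heart rate; drawn from `config$hr_range_bpm` when `NULL`.
#' @param record_id,subject_id identifiers carried into the output.
#' @return object of class `pulse_recording`: `channels` (samples x 3
#'   matrix), `sampling_rate_hz`, ids, and `ground_truth` (per-beat fiducial
#'   table, reference SBP/DBP, aligned-channel index).
#' @export
generate_recording <- function(config, subject_bp, seed, hr_bpm = NULL,
                               record_id = "rec1", subject_id = "subj1") {
  validate_sim_config(config)
  sbp <- subject_bp[1]; dbp <- subject_bp[2]
  if (sbp <= dbp) stop("SBP must exceed DBP")
  set.seed(seed)
  fs <- config$sampling_rate_hz
  if (is.null(hr_bpm))
    hr_bpm <- stats::runif(1, config$hr_range_bpm[1], config$hr_range_bpm[2])
  base <- bp_morphology(sbp, dbp, hr_bpm)
  if (config$duration_s < base$beat_period_s)
    stop("duration_s shorter than one beat period")

  n_total <- round(config$duration_s * fs)
  clean <- numeric(0)
  fids <- list()
  onset <- 0
  while (length(clean) < n_total + round(base$beat_period_s * fs)) {
    p <- base
    p$beat_period_s <- base$beat_period_s * stats::rlnorm(1, 0, 0.02)
    beat <- generate_beat_template(p, fs)
    t0 <- length(clean) / fs
    f <- beat$fiducials_true
    fids[[length(fids) + 1L]] <- data.frame(
      onset_time = t0,
      dp1_time = t0 + f$dp1_time,
      max_slope_time = t0 + f$max_slope_time,
      systolic_time = t0 + f$systolic_time,
      notch_time = t0 + f$notch_time,
      dicrotic_time = t0 + f$dicrotic_time,
      dp2_time = t0 + f$dp2_time,
      systolic_amp = f$systolic_amp, dicrotic_amp = f$dicrotic_amp,
      notch_amp = f$notch_amp, dp1_amp = f$dp1_amp
    )
    clean <- c(clean, beat$samples)
  }
  fid_tab <- do.call(rbind, fids)
  # drop beats not fully inside the kept window
  fid_tab <- fid_tab[fid_tab$dp2_time <= n_total / fs, , drop = FALSE]
  clean <- clean[seq_len(n_total)]
  tt <- (seq_len(n_total) - 1) / fs
  amp0 <- base$systolic_amp

  # shared artifact transients (one draw per beat)
  art <- numeric(n_total)
  if (config$artifact_prob > 0) {
    for (b in seq_len(nrow(fid_tab))) {
      if (stats::runif(1) < config$artifact_prob) {
        t_a <- stats::runif(1, fid_tab$onset_time[b], fid_tab$dp2_time[b])
        f_a <- stats::runif(1, 8, 15)
        a_a <- stats::runif(1, 0.3, 0.7) * amp0
        rel <- tt - t_a
        w <- rel >= 0
        art[w] <- art[w] + a_a * exp(-rel[w] / 0.12) * sin(2 * pi * f_a * rel[w])
      }
    }
  }

  ch <- matrix(0, n_total, length(config$channel_gains))
  for (k in seq_along(config$channel_gains)) {
    phase <- stats::runif(1, 0, 2 * pi)
    ch[, k] <- config$channel_gains[k] * clean +
      config$baseline_amp * amp0 * sin(2 * pi * config$baseline_freq_hz * tt + phase) +
      stats::rnorm(n_total, 0, config$noise_sd * amp0) +
      art
  }
  colnames(ch) <- paste0("ch", seq_len(ncol(ch)))

  structure(list(
    channels = ch,
    clean = clean,
    sampling_rate_hz = fs,
    record_id = record_id,
    subject_id = subject_id,
    ground_truth = list(
      fiducials = fid_tab,
      sbp_mmHg = sbp, dbp_mmHg = dbp, hr_bpm = hr_bpm,
      aligned_channel = which.max(config$channel_gains)
    )
  ), class = "pulse_recording")
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat(sprintf("pulse_recording %s (subject %s): %d channels x %d samples @ %g Hz\n",
              x$record_id, x$subject_id, ncol(x$channels), nrow(x$channels),
              x$sampling_rate_hz))
  cat(sprintf("  reference BP %g/%g mmHg, %d beats, aligned channel %d\n",
              x$ground_truth$sbp_mmHg, x$ground_truth$dbp_mmHg,
              nrow(x$ground_truth$fiducials), x$ground_truth$aligned_channel))
  invisible(x)
}

# Deterministic per-record plan: subject identities, reference pressures,
# heart rates and per-record seeds, all derived from config$seed. Subject
# means are drawn from the inner 70% of each configured range and record-level
# draws are clamped back into the range, giving a roughly bell-shaped corpus
# histogram strictly inside the configured bounds.
dataset_plan <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  plans <- vector("list", config$n_subjects * config$records_per_subject)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    sbp_r <- config$sbp_range_mmHg; dbp_r <- config$dbp_range_mmHg
    sbp_mu <- stats::runif(1, sbp_r[1] + 0.15 * diff(sbp_r), sbp_r[2] - 0.15 * diff(sbp_r))
    dbp_mu <- stats::runif(1, dbp_r[1] + 0.15 * diff(dbp_r), dbp_r[2] - 0.15 * diff(dbp_r))
    hr <- stats::runif(1, config$hr_range_bpm[1], config$hr_range_bpm[2])
    for (r in seq_len(config$records_per_subject)) {
      i <- i + 1L
      plans[[i]] <- list(
        record_id = sprintf("s%02d_r%03d", s, r),
        subject_id = sprintf("s%02d", s),
        sbp = clamp(stats::rnorm(1, sbp_mu, 3), sbp_r),
        dbp = clamp(stats::rnorm(1, dbp_mu, 2.5), dbp_r),
        hr_bpm = hr * stats::rlnorm(1, 0, 0.03),
        seed = sample.int(.Machine$integer.max - 1L, 1)
      )
    }
  }
  plans
}

#' Generate a labelled synthetic corpus
#'
#' Draws per-subject mean pressures and heart rates, then per-record
#' reference SBP/DBP (clamped into the configured ranges) and generates every
#' recording. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list with `records` (list of `pulse_recording`), `references`
#'   (data.frame `record_id, subject_id, sbp_mmHg, dbp_mmHg`), and `config`.
#' @export
generate_dataset <- function(config) {
  plans <- dataset_plan(config)
  records <- lapply(plans, function(p)
    generate_recording(config, c(p$sbp, p$dbp), seed = p$seed, hr_bpm = p$hr_bpm,
                       record_id = p$record_id, subject_id = p$subject_id))
  references <- data.frame(
    record_id = vapply(plans, `[[`, "", "record_id"),
    subject_id = vapply(plans, `[[`, "", "subject_id"),
    sbp_mmHg = vapply(plans, `[[`, 0, "sbp"),
    dbp_mmHg = vapply(plans, `[[`, 0, "dbp"),
    stringsAsFactors = FALSE
  )
  list(records = records, references = references, config = config)
}
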