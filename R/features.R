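# Beat segmentation, fiducial-point detection and waveform features.
#
# A beat runs from one onset minimum (diastolic point 1) to the next. Eleven
# features are computed per beat: heart rate, five amplitudes (systolic peak,
# dicrotic peak, diastolic points 1 and 2, dicrotic notch), maximum upstroke
# slope, augmentation index, and the three timing intervals T1 (onset to
# systolic peak), T2 (systolic to dicrotic peak), T3 (dicrotic peak to end of
# beat). Amplitudes other than diastolic point 1 are measured relative to
# the beat onset level, which makes the augmentation index invariant to the
# recording's amplitude scale.

.feature_names <- c("heart_rate_bpm", "systolic_peak_amp", "dicrotic_peak_amp",
                    "dp1_amp", "dp2_amp", "notch_amp", "max_slope",
                    "aug_index", "t1_s", "t2_s", "t3_s")

#' Segment a denoised pulse signal into beats
#'
#' Detects systolic peaks (local maxima above an adaptive amplitude
#' threshold, with a minimum separation of `60 / hr_bounds_bpm[2]` seconds),
#' then places beat onsets at the signal minimum between consecutive peaks.
#' Each beat spans one onset to the next, so partial first/last periods are
#' discarded by construction. Beats shorter than 0.25 s or longer than one
#' period at the lower heart-rate bound are dropped.
#'
#' @param signal numeric vector (denoised channel).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param hr_bounds_bpm plausible heart-rate range `(low, high)` in bpm,
#'   within (25, 250).
#' @return list of `pulse_beat` objects (possibly empty), each with
#'   `onset_index` (1-based index into `signal`), `samples` (onset to next
#'   onset, inclusive) and `sampling_rate_hz`.
#' @export
segment_beats <- function(signal, sampling_rate_hz, hr_bounds_bpm = c(40, 180)) {
  stopifnot(hr_bounds_bpm[1] > 25, hr_bounds_bpm[2] < 250,
            hr_bounds_bpm[1] < hr_bounds_bpm[2])
  n <- length(signal)
  min_sep <- round(60 / hr_bounds_bpm[2] * sampling_rate_hz)
  ex <- find_extrema(signal)
  if (length(ex$maxima) < 2) return(list())
  qlo <- stats::quantile(signal, 0.02, names = FALSE)
  qhi <- stats::quantile(signal, 0.98, names = FALSE)
  if (qhi - qlo <= 0) return(list())
  thr <- qlo + 0.6 * (qhi - qlo)
  cand <- ex$maxima[signal[ex$maxima] >= thr]
  if (length(cand) < 2) return(list())
  # greedy peak pruning: keep the tallest, discard any peak within min_sep
  keep <- logical(length(cand))
  for (i in order(signal[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 2) return(list())
  # onset = the last sufficiently deep local minimum before the next peak
  # (the trough preceding the steep systolic upstroke); a plain argmin can
  # land on mid-diastolic dips left by band-limited reconstruction
  onsets <- vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    v <- signal[seg]
    mins <- find_extrema(v)$minima
    if (!length(mins)) return(seg[which.min(v)])
    deep <- mins[v[mins] <= stats::quantile(v, 0.2, names = FALSE)]
    if (length(deep)) mins <- deep
    seg[mins[length(mins)]]
  }, 0L)
  beats <- list()
  min_len <- round(0.25 * sampling_rate_hz)
  max_len <- round(60 / hr_bounds_bpm[1] * sampling_rate_hz)
  for (i in seq_len(length(onsets) - 1L)) {
    len <- onsets[i + 1L] - onsets[i] + 1L
    if (len < min_len || len > max_len) next
    beats[[length(beats) + 1L]] <- structure(
      list(onset_index = onsets[i],
           samples = signal[onsets[i]:onsets[i + 1L]],
           sampling_rate_hz = sampling_rate_hz),
      class = "pulse_beat")
  }
  beats
}

#' Locate the six fiducial landmarks of one beat
#'
#' Diastolic point 1 is the beat onset (first sample); the systolic peak is
#' the first local maximum reaching at least 60% of the beat's maximal
#' onset-relative height (ties resolve to the earliest); the maximum-slope
#' point is the argmax of the first difference between onset and systolic
#' peak; the dicrotic notch is the first local minimum after the systolic
#' peak; the dicrotic peak is the first local maximum after the notch;
#' diastolic point 2 is the final sample (the next beat's onset). Beats with
#' no dicrotic bump, or violating the landmark ordering, are flagged
#' degenerate.
#'
#' @param beat a `pulse_beat` from [segment_beats()].
#' @return object of class `fiducial_points` with absolute times (s, from
#'   the start of the parent signal), amplitudes, the upstroke slope, and a
#'   `degenerate` flag.
#' @export
detect_fiducials <- function(beat) {
  x <- beat$samples
  n <- length(x)
  fs <- beat$sampling_rate_hz
  t0 <- (beat$onset_index - 1) / fs
  out <- structure(list(
    dp1_time = t0, dp1_amp = x[1],
    max_slope_time = NA_real_, max_slope = NA_real_,
    systolic_time = NA_real_, systolic_amp = NA_real_,
    notch_time = NA_real_, notch_amp = NA_real_,
    dicrotic_time = NA_real_, dicrotic_amp = NA_real_,
    dp2_time = t0 + (n - 1) / fs, dp2_amp = x[n],
    degenerate = TRUE), class = "fiducial_points")
  ex <- find_extrema(x)
  if (!length(ex$maxima)) return(out)
  h <- x - x[1]
  prominent <- ex$maxima[h[ex$maxima] >= 0.6 * max(h)]
  if (!length(prominent)) return(out)
  i_sys <- prominent[1]
  d <- diff(x[1:i_sys])
  if (!length(d)) return(out)
  i_ms <- which.max(d)
  out$max_slope_time <- t0 + (i_ms - 0.5) / fs
  out$max_slope <- d[i_ms] * fs
  out$systolic_time <- t0 + (i_sys - 1) / fs
  out$systolic_amp <- x[i_sys]
  i_ntc <- ex$minima[ex$minima > i_sys][1]
  if (is.na(i_ntc)) return(out)
  i_dic <- ex$maxima[ex$maxima > i_ntc][1]
  if (is.na(i_dic)) return(out)
  if (!(i_sys < i_ntc && i_ntc < i_dic && i_dic < n)) return(out)
  if (!(x[i_sys] >= x[i_dic] && x[i_dic] >= x[i_ntc])) return(out)
  out$notch_time <- t0 + (i_ntc - 1) / fs
  out$notch_amp <- x[i_ntc]
  out$dicrotic_time <- t0 + (i_dic - 1) / fs
  out$dicrotic_amp <- x[i_dic]
  out$degenerate <- FALSE
  out
}

#' Compute the eleven waveform features of one beat
#'
#' Heart rate is 60 over the systolic peak-to-peak interval between this
#' beat and the previous one. Amplitude features other than diastolic point
#' 1 are reported relative to the diastolic point 1 level; the augmentation
#' index is the amplitude ratio of the systolic and dicrotic peaks (both
#' onset-relative) — `"systolic_over_dicrotic"` by default, with the common
#' literature convention available as `"dicrotic_over_systolic"`. T1, T2 and
#' T3 are the onset-to-systolic, systolic-to-dicrotic and dicrotic-to-end
#' intervals in seconds.
#'
#' @param fiducials a non-degenerate [detect_fiducials()] result.
#' @param prev_systolic_time systolic-peak time of the preceding beat (s);
#'   must precede this beat's systolic time.
#' @param ai_convention direction of the augmentation-index ratio.
#' @return named numeric vector of length 11, or `NULL` when the beat is
#'   degenerate or its dicrotic amplitude does not exceed the onset level.
#' @export
compute_features <- function(fiducials, prev_systolic_time,
                             ai_convention = c("systolic_over_dicrotic",
                                               "dicrotic_over_systolic")) {
  ai_convention <- match.arg(ai_convention)
  f <- fiducials
  if (isTRUE(f$degenerate)) return(NULL)
  if (!(prev_systolic_time < f$systolic_time))
    stop("prev_systolic_time must precede the current systolic time")
  sys_rel <- f$systolic_amp - f$dp1_amp
  dic_rel <- f$dicrotic_amp - f$dp1_amp
  if (dic_rel <= 0) return(NULL)  # AI undefined, beat excluded
  ai <- if (ai_convention == "systolic_over_dicrotic") sys_rel / dic_rel
        else dic_rel / sys_rel
  v <- c(heart_rate_bpm = 60 / (f$systolic_time - prev_systolic_time),
         systolic_peak_amp = sys_rel,
         dicrotic_peak_amp = dic_rel,
         dp1_amp = f$dp1_amp,
         dp2_amp = f$dp2_amp - f$dp1_amp,
         notch_amp = f$notch_amp - f$dp1_amp,
         max_slope = f$max_slope,
         aug_index = ai,
         t1_s = f$systolic_time - f$dp1_time,
         t2_s = f$dicrotic_time - f$systolic_time,
         t3_s = f$dp2_time - f$dicrotic_time)
  if (!all(is.finite(v))) return(NULL)
  if (v["heart_rate_bpm"] <= 25 || v["heart_rate_bpm"] >= 250) return(NULL)
  v
}

#' Featurize one denoised recording channel
#'
#' Segments the channel into beats, locates fiducials, computes per-beat
#' feature vectors and aggregates them by the componentwise median over
#' non-degenerate beats. The first beat has no preceding systolic peak and
#' inherits the record's median heart rate. Records with fewer than
#' `min_beats` usable beats are rejected with a diagnostic.
#'
#' @param signal denoised channel.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param hr_bounds_bpm passed to [segment_beats()].
#' @param ai_convention passed to [compute_features()].
#' @param min_beats minimum usable beats per record (default 3).
#' @return list with `features` (named length-11 vector or `NULL`),
#'   `n_beats_total`, `n_beats_used`, `rejected`, `reason`, and the per-beat
#'   `fiducials` list.
#' @export
featurize_recording <- function(signal, sampling_rate_hz,
                                hr_bounds_bpm = c(40, 180),
                                ai_convention = "systolic_over_dicrotic",
                                min_beats = 3L) {
  beats <- segment_beats(signal, sampling_rate_hz, hr_bounds_bpm)
  reject <- function(reason, fids = list(), used = 0L) {
    list(features = NULL, n_beats_total = length(beats), n_beats_used = used,
         rejected = TRUE, reason = reason, fiducials = fids)
  }
  if (length(beats) < min_beats) return(reject("too_few_beats"))
  fids <- lapply(beats, detect_fiducials)
  ok <- !vapply(fids, function(f) isTRUE(f$degenerate), TRUE)
  sys_times <- vapply(fids, function(f)
    if (is.na(f$systolic_time)) NA_real_ else f$systolic_time, 0)
  # peak-to-peak heart rate; the first beat takes the record median interval
  iv <- diff(sys_times)
  med_iv <- stats::median(iv, na.rm = TRUE)
  prev_times <- c(sys_times[1] - med_iv, sys_times[-length(sys_times)])
  rows <- vector("list", length(beats))
  for (i in which(ok)) {
    if (!is.na(prev_times[i]) && prev_times[i] < sys_times[i])
      rows[[i]] <- compute_features(fids[[i]], prev_times[i], ai_convention)
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < min_beats)
    return(reject("too_few_valid_beats", fids, length(rows)))
  mat <- do.call(rbind, rows)
  list(features = apply(mat, 2, stats::median),
       n_beats_total = length(beats), n_beats_used = nrow(mat),
       rejected = FALSE, reason = NA_character_, fiducials = fids)
}
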