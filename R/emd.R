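# Empirical mode decomposition and Hilbert-Huang style denoising.
#
# The decomposition follows the classical sifting scheme: cubic-spline
# envelopes through the local maxima and minima (with two extrema mirrored
# across each boundary), repeated subtraction of the mean envelope until a
# Cauchy-type stopping criterion SD = sum((h_prev - h)^2) / sum(h_prev^2)
# falls below a threshold, extraction of the resulting intrinsic mode
# function (IMF), and recursion on the remainder until it is monotone.
# Completeness (sum of IMFs + residue == input) holds exactly by
# construction.

# Locate interior local extrema; plateaus contribute their centre sample.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(maxima = integer(0), minima = integer(0)))
  sf <- s[nz]
  chg <- which(diff(sf) != 0)
  if (!length(chg)) return(list(maxima = integer(0), minima = integer(0)))
  # extremum between the end of one run and the start of the next
  pos <- as.integer(round((nz[chg] + 1L + nz[chg + 1L]) / 2))
  kind <- sf[chg] # +1 -> maximum, -1 -> minimum
  list(maxima = pos[kind > 0], minima = pos[kind < 0])
}

# Cubic-spline envelope through the given extrema, with up to two extrema
# mirrored across each endpoint to tame spline end swings.
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  m <- min(2L, k)
  xi <- c(2L - idx[seq_len(m)], idx, 2L * n - idx[k - seq_len(m) + 1L])
  yi <- c(val[seq_len(m)], val, val[k - seq_len(m) + 1L])
  o <- order(xi)
  xi <- xi[o]; yi <- yi[o]
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

#' Interpolated extrema envelope of a signal
#'
#' Cubic-spline envelope through the local maxima (`"upper"`) or minima
#' (`"lower"`), defined over the full support by mirroring up to two extrema
#' across each endpoint. This is the interpolation step used inside the
#' sifting loop of [emd_decompose()].
#'
#' @param signal numeric vector.
#' @param extrema_kind `"upper"` or `"lower"`.
#' @return numeric vector the same length as `signal`.
#' @export
envelope <- function(signal, extrema_kind = c("upper", "lower")) {
  extrema_kind <- match.arg(extrema_kind)
  ex <- find_extrema(signal)
  idx <- if (extrema_kind == "upper") ex$maxima else ex$minima
  if (length(idx) < 2)
    stop("fewer than 2 ", extrema_kind, " extrema: signal is monotone")
  spline_envelope(idx, signal[idx], length(signal))
}

sift_imf <- function(x, sd_threshold, max_sift) {
  h <- x
  n <- length(x)
  for (it in seq_len(max_sift)) {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    u <- spline_envelope(ex$maxima, h[ex$maxima], n)
    l <- spline_envelope(ex$minima, h[ex$minima], n)
    m <- (u + l) / 2
    h1 <- h - m
    crit <- sum((h - h1)^2) / sum(h^2)
    h <- h1
    if (is.na(crit) || crit < sd_threshold) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs, ordered from
#' highest to lowest frequency) plus a monotone residue. Sifting stops per
#' IMF when the normalized successive-difference criterion drops below
#' `sd_threshold` (classical default 0.2) or after `max_sift` iterations;
#' decomposition stops when the remainder has fewer than three extrema or
#' `max_imfs` is reached. Constant or very short signals yield zero IMFs with
#' `residue = signal`.
#'
#' @param signal numeric vector (finite values, length >= 8 for a non-trivial
#'   decomposition).
#' @param sampling_rate_hz sampling rate in Hz (carried for classification).
#' @param sd_threshold sifting stop threshold.
#' @param max_imfs maximum number of IMFs.
#' @param max_sift per-IMF sifting iteration cap.
#' @return object of class `imf_set`: `imfs` (list, index 1 = highest
#'   frequency), `residue`, `sampling_rate_hz`, `source_length`.
#' @export
emd_decompose <- function(signal, sampling_rate_hz, sd_threshold = 0.2,
                          max_imfs = 10L, max_sift = 100L) {
  if (!all(is.finite(signal))) stop("signal must be finite")
  imfs <- list()
  r <- signal
  if (length(signal) >= 8) {
    for (k in seq_len(max_imfs)) {
      ex <- find_extrema(r)
      if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
      imf <- sift_imf(r, sd_threshold, max_sift)
      imfs[[k]] <- imf
      r <- r - imf
    }
  }
  structure(list(imfs = imfs, residue = r,
                 sampling_rate_hz = sampling_rate_hz,
                 source_length = length(signal)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("imf_set: %d IMFs + residue over %d samples @ %g Hz\n",
              length(x$imfs), x$source_length, x$sampling_rate_hz))
  if (length(x$imfs)) {
    f <- vapply(x$imfs, dominant_frequency, 0, sampling_rate_hz = x$sampling_rate_hz)
    cat("  dominant frequencies (Hz):", paste(signif(f, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

# Dominant frequency estimate: zero-crossing rate / 2.
dominant_frequency <- function(imf, sampling_rate_hz) {
  s <- sign(imf)
  s <- s[s != 0]
  zc <- sum(diff(s) != 0)
  duration <- length(imf) / sampling_rate_hz
  (zc / duration) / 2
}

#' Classify IMFs into noise, signal, and baseline components
#'
#' An IMF whose dominant frequency (zero-crossing rate / 2) exceeds the upper
#' edge of `beat_band_hz` is classified as noise; below the lower edge, as
#' baseline; otherwise as signal. The residue is always baseline. The default
#' band (0.5, 12) Hz covers the physiological pulse fundamental and its
#' harmonics; the upper edge is deliberately generous because wide-band noise
#' inflates the zero-crossing count of the IMF that carries the beat
#' waveform, and a tight edge would intermittently discard it.
#'
#' @param imfset an [emd_decompose()] result.
#' @param beat_band_hz length-2 numeric `(low, high)` in Hz.
#' @return list with integer index vectors `noise`, `signal`, `baseline`
#'   (into `imfset$imfs`), the per-IMF `dominant_freq_hz`, and
#'   `residue_class = "baseline"`.
#' @export
classify_imfs <- function(imfset, beat_band_hz = c(0.5, 12)) {
  if (!inherits(imfset, "imf_set")) stop("imfset must be an imf_set")
  k <- length(imfset$imfs)
  if (k == 0)
    return(list(noise = integer(0), signal = integer(0), baseline = integer(0),
                dominant_freq_hz = numeric(0), residue_class = "baseline"))
  f <- vapply(imfset$imfs, dominant_frequency, 0,
              sampling_rate_hz = imfset$sampling_rate_hz)
  list(noise = which(f > beat_band_hz[2]),
       signal = which(f >= beat_band_hz[1] & f <= beat_band_hz[2]),
       baseline = which(f < beat_band_hz[1]),
       dominant_freq_hz = f,
       residue_class = "baseline")
}

#' Denoise a pulse channel by selective IMF reconstruction
#'
#' Hilbert-Huang style preprocessing: decompose the channel with
#' [emd_decompose()], classify the IMFs with [classify_imfs()], and
#' reconstruct the signal from the in-band (signal) IMFs only, discarding
#' high-frequency noise and low-frequency baseline wander/residue.
#'
#' @param signal numeric vector, one channel.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param beat_band_hz pulse band `(low, high)` in Hz; see [classify_imfs()].
#' @param ... passed on to [emd_decompose()].
#' @return denoised numeric vector, same length as the input.
#' @export
denoise <- function(signal, sampling_rate_hz, beat_band_hz = c(0.5, 12), ...) {
  dec <- emd_decompose(signal, sampling_rate_hz, ...)
  cls <- classify_imfs(dec, beat_band_hz)
  if (!length(cls$signal))
    stop("unusable channel: no IMF falls inside the pulse band")
  Reduce(`+`, dec$imfs[cls$signal])
}

# Light moving-average smoothing used only for beat detection inside the
# channel-quality score (the quality metric must work on raw, noisy input).
.smooth_ma <- function(x, fs, width_s = 0.04) {
  w <- max(3L, round(width_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  stats::filter(x, rep(1 / w, w), sides = 2) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; as.numeric(y) })()
}

#' Score channels and select the best-aligned one
#'
#' Operationalizes "most distinguishable peaks, least noise": each channel is
#' scored by the mean Pearson correlation of its detected beats against the
#' channel's median beat, multiplied by the median beat peak-to-trough
#' amplitude. A well-aligned sensor element shows large, repeatable beats and
#' wins on both factors. Ties break to the lowest channel index.
#'
#' @param recording a `pulse_recording` (or a plain samples x channels
#'   matrix) plus `sampling_rate_hz` when a matrix is given.
#' @param sampling_rate_hz required when `recording` is a matrix.
#' @param hr_bounds_bpm plausible heart-rate range for beat detection.
#' @return object of class `signal_quality`: numeric `scores` per channel and
#'   `selected_channel`.
#' @export
select_best_channel <- function(recording, sampling_rate_hz = NULL,
                                hr_bounds_bpm = c(40, 180)) {
  if (inherits(recording, "pulse_recording")) {
    ch <- recording$channels
    fs <- recording$sampling_rate_hz
  } else {
    ch <- as.matrix(recording)
    fs <- sampling_rate_hz
    if (is.null(fs)) stop("sampling_rate_hz required for a matrix input")
  }
  scores <- vapply(seq_len(ncol(ch)), function(k)
    channel_quality_score(ch[, k], fs, hr_bounds_bpm), 0)
  if (all(!is.finite(scores))) stop("no usable channel: all channels flat or beatless")
  structure(list(scores = scores,
                 selected_channel = which.max(replace(scores, !is.finite(scores), -Inf))),
            class = "signal_quality")
}

channel_quality_score <- function(x, fs, hr_bounds_bpm) {
  if (stats::sd(x) == 0) return(-Inf)
  xs <- .smooth_ma(x, fs)
  beats <- segment_beats(xs, fs, hr_bounds_bpm)
  if (length(beats) < 2) return(-Inf)
  # resample each beat to a common length and correlate with the median beat
  L <- 80L
  mat <- vapply(beats, function(b) {
    stats::approx(seq_along(b$samples), b$samples, n = L)$y
  }, numeric(L))
  template <- apply(mat, 1, stats::median)
  if (stats::sd(template) == 0) return(-Inf)
  cors <- apply(mat, 2, function(v)
    if (stats::sd(v) == 0) 0 else stats::cor(v, template))
  amp <- stats::median(vapply(beats, function(b) diff(range(b$samples)), 0))
  mean(cors) * amp
}

#' @export
print.signal_quality <- function(x, ...) {
  cat("channel quality scores:", paste(signif(x$scores, 4), collapse = ", "), "\n")
  cat("selected channel:", x$selected_channel, "\n")
  invisible(x)
}
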