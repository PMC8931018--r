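#' Zero-phase low-pass filter
#'
#' Removes power-frequency (50 Hz) interference from lip-motion recordings
#' with a Butterworth low-pass at 20 Hz, applied forward-backward
#' (`signal::filtfilt`) so the filter is zero-phase and onsets are not
#' shifted. The default 4th-order design attenuates 50 Hz by well over
#' 40 dB after the double pass while leaving the sub-10 Hz passband within
#' 1 dB.
#'
#' @param w A [waveform()].
#' @param cutoff_hz Cut-off frequency in Hz (default 20); must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward filtering (default `TRUE`);
#'   otherwise a single causal pass.
#' @return The filtered [waveform()].
#' @export
lowpass <- function(w, cutoff_hz = 20, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(w, "waveform"))
  stop_if_not_scalar_num(cutoff_hz, "cutoff_hz", lower = .Machine$double.eps)
  stop_if_not_scalar_num(order, "order", 1, 12)
  if (cutoff_hz >= w$rate / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (w$rate / 2), type = "low")
  y <- if (zero_phase) signal::filtfilt(bf, w$samples)
       else as.numeric(signal::filter(bf, w$samples))
  waveform(y, w$rate, units = w$units, kind = w$kind)
}

#' Peak-normalize a waveform
#'
#' Divides by the maximum absolute value so the peak magnitude is exactly 1
#' while signs and all relative sub-peak amplitudes are preserved. This
#' removes the amplitude interference between recordings (mask pretension,
#' contact quality) so waveform shape alone is compared. Idempotent.
#'
#' @param w A [waveform()]; must not be identically zero.
#' @return The normalized [waveform()] with units `"normalized"`.
#' @export
normalize <- function(w) {
  stopifnot(inherits(w, "waveform"))
  peak <- max(abs(w$samples))
  if (peak == 0) stop("cannot normalize an all-zero waveform", call. = FALSE)
  waveform(w$samples / peak, w$rate, units = "normalized", kind = w$kind)
}

#' Detect active segments (word onsets/offsets)
#'
#' Marks samples whose magnitude reaches `threshold_frac` of the waveform's
#' peak as active, merges active runs separated by less than
#' `min_gap_s` (closed-state pauses shorter than a word gap, including
#' brief dips between lobes), and returns one segment per remaining run.
#'
#' @param w A [waveform()] (normalization is not required; the threshold is
#'   relative to the peak).
#' @param threshold_frac Fraction of the peak defining activity (default 0.05).
#' @param min_gap_s Minimum closed-state duration separating two words
#'   (default 0.2 s); shorter gaps are bridged.
#' @return A data frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @export
detect_onsets <- function(w, threshold_frac = 0.05, min_gap_s = 0.2) {
  stopifnot(inherits(w, "waveform"))
  stop_if_not_scalar_num(threshold_frac, "threshold_frac", lower = 1e-12)
  a <- abs(w$samples)
  thr <- threshold_frac * max(a)
  active <- a >= thr
  if (max(a) == 0 || threshold_frac > 1 || !any(active)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge short inactive gaps
  min_gap <- round(min_gap_s * w$rate)
  out <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - out$end[nrow(out)] - 1 < min_gap) {
        out$end[nrow(out)] <- seg$end[i]
      } else {
        out <- rbind(out, seg[i, ])
      }
    }
  }
  data.frame(start_s = (out$start - 1) / w$rate, end_s = (out$end - 1) / w$rate)
}

#' Lip-to-sound onset advance
#'
#' Time by which the lip-motion signal leads the sound signal, in ms:
#' the mouth begins to move before any sound is produced, so the advance is
#' positive when lip leads. Both onsets are located with the same relative
#' threshold rule ([detect_onsets()]).
#'
#' @param lip,sound [waveform()]s at the same sampling rate.
#' @param threshold_frac Onset threshold as a fraction of each signal's peak.
#' @return Advance in ms (`sound onset - lip onset`).
#' @export
onset_advance <- function(lip, sound, threshold_frac = 0.05) {
  stopifnot(inherits(lip, "waveform"), inherits(sound, "waveform"))
  if (lip$rate != sound$rate) stop("sampling rates differ", call. = FALSE)
  seg_l <- detect_onsets(lip, threshold_frac)
  seg_s <- detect_onsets(sound, threshold_frac)
  if (nrow(seg_l) == 0 || nrow(seg_s) == 0) {
    stop("no onset detected in lip and/or sound signal", call. = FALSE)
  }
  (seg_s$start_s[1] - seg_l$start_s[1]) * 1000
}

#' Duration efficiency of continuous over separate speech
#'
#' Continuous pronunciation omits parts of the isolated words; the
#' efficiency is the percentage reduction of the continuous duration
#' relative to the summed separate durations:
#' `100 * (sum(separate) - continuous) / sum(separate)`.
#'
#' @param separate_durations Durations of the separately spoken words, s.
#' @param continuous_duration Duration of the connected phrase, s; must not
#'   exceed the summed separate durations.
#' @return Efficiency in percent.
#' @examples
#' efficiency(c(0.55, 0.62, 0.60, 0.628), 1.648)  # ~31.3
#' @export
efficiency <- function(separate_durations, continuous_duration) {
  if (any(separate_durations <= 0) || continuous_duration <= 0) {
    stop("durations must be positive", call. = FALSE)
  }
  tot <- sum(separate_durations)
  if (continuous_duration > tot) {
    stop("continuous duration exceeds the summed separate durations", call. = FALSE)
  }
  100 * (tot - continuous_duration) / tot
}

#' Sound-to-lip duration fraction
#'
#' Percentage of the lip-motion duration occupied by the sound signal
#' (observed band roughly 60.8-85.4% for connected phrases).
#'
#' @param sound_duration,lip_duration Durations in the same time unit;
#'   `lip_duration` must be positive.
#' @return `100 * sound_duration / lip_duration`.
#' @export
duration_fraction <- function(sound_duration, lip_duration) {
  if (lip_duration <= 0) stop("lip duration must be positive", call. = FALSE)
  if (sound_duration < 0) stop("sound duration must be non-negative", call. = FALSE)
  100 * sound_duration / lip_duration
}

#' Lip-to-sound data volume ratio
#'
#' Ratio of the storage taken by a lip-motion recording to that of the
#' synchronized sound recording (e.g. 12 KB vs 576 KB = 1/48).
#'
#' @param lip_bytes,sound_bytes Positive sizes in any common unit.
#' @return `lip_bytes / sound_bytes`.
#' @export
data_volume_ratio <- function(lip_bytes, sound_bytes) {
  if (lip_bytes <= 0 || sound_bytes <= 0) stop("sizes must be positive", call. = FALSE)
  lip_bytes / sound_bytes
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Windowed spectral analysis of a lip-motion waveform (Hanning window via
#' `signal::specgram`), returning the magnitude matrix with its frequency
#' and time axes.
#'
#' @param w A [waveform()].
#' @param window_len Window length in samples (default 256); must not
#'   exceed the signal length.
#' @param hop Hop between windows in samples (default `window_len / 4`).
#' @return An object of class `lip_spectrogram`: list with `magnitude`
#'   (frequency x time), `freq_hz`, `time_s`, `window_len`, `hop`.
#' @export
stft <- function(w, window_len = 256, hop = window_len %/% 4) {
  stopifnot(inherits(w, "waveform"))
  stop_if_not_scalar_num(window_len, "window_len", 4)
  if (hop <= 0) stop("`hop` must be positive", call. = FALSE)
  if (window_len > length(w$samples)) {
    stop("`window_len` exceeds the signal length", call. = FALSE)
  }
  sg <- signal::specgram(w$samples, n = window_len, Fs = w$rate,
                         overlap = window_len - hop)
  structure(list(magnitude = abs(sg$S), freq_hz = as.numeric(sg$f),
                 time_s = as.numeric(sg$t), window_len = as.integer(window_len),
                 hop = as.integer(hop)),
            class = "lip_spectrogram")
}

#' Fixed-length model input
#'
#' Maps a waveform to the fixed-length sequence fed to the recurrent
#' classifier. Longer inputs are anti-alias filtered (zero-phase low-pass
#' at 45% of the output Nyquist) and resampled by linear interpolation at
#' stride `n/target_len` (plain decimation when the ratio is an integer);
#' shorter inputs are zero-padded symmetrically so the original is
#' centered. Deterministic.
#'
#' @param w A [waveform()] (typically filtered and normalized).
#' @param target_len Output length in samples.
#' @return Numeric vector of length `target_len`.
#' @export
to_model_input <- function(w, target_len = 1000) {
  stopifnot(inherits(w, "waveform"))
  stop_if_not_scalar_num(target_len, "target_len", 2)
  target_len <- as.integer(target_len)
  x <- w$samples
  n <- length(x)
  if (n == target_len) return(x)
  if (n > target_len) {
    ratio <- n / target_len
    cutoff <- 0.45 * (w$rate / ratio)
    if (cutoff < w$rate / 2) {
      x <- lowpass(w, cutoff_hz = cutoff, order = 4, zero_phase = TRUE)$samples
    }
    pos <- 1 + (seq_len(target_len) - 1) * ratio
    return(stats::approx(seq_len(n), x, xout = pos, rule = 2)$y)
  }
  left <- (target_len - n) %/% 2L
  c(numeric(left), x, numeric(target_len - n - left))
}

# Standard conditioning chain for classification: low-pass, normalize,
# trim to the active (word) span, then decimate at a fixed model rate and
# center the span in a fixed-length window. Trimming removes the variable
# closed-mouth padding so the network sees the segmented word (as in the
# recognition pipeline) while the fixed decimation rate preserves the
# word's duration as an explicit cue. Returns a plain numeric vector.
condition_signal <- function(w, cutoff_hz = 20, target_len = 1000,
                             trim = TRUE, margin_s = 0.03, model_rate = 50) {
  wn <- normalize(lowpass(w, cutoff_hz))
  if (!trim) return(to_model_input(wn, target_len))
  seg <- detect_onsets(wn)
  if (nrow(seg) > 0) {
    i0 <- max(1L, round((seg$start_s[1] - margin_s) * wn$rate) + 1L)
    i1 <- min(length(wn$samples),
              round((seg$end_s[nrow(seg)] + margin_s) * wn$rate) + 1L)
    wn <- waveform(wn$samples[i0:i1], wn$rate, units = wn$units,
                   kind = wn$kind)
  }
  n_out <- round(duration(wn) * model_rate)
  if (n_out >= target_len) return(to_model_input(wn, target_len))
  x <- to_model_input(wn, max(2L, n_out))
  to_model_input(waveform(x, model_rate, units = wn$units), target_len)
}
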