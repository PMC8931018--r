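#' Word template for lip-motion synthesis
#'
#' A word is an ordered sequence of mouth states: `closed` (no signal),
#' `opening` (positive charge-transfer lobe) and `closing` (negative return
#' lobe). Each non-closed segment carries a normalized peak amplitude in
#' (0, 1]. A valid template starts and ends in the closed state.
#'
#' @param label Word label.
#' @param segments Data frame with columns `state` (`"closed"`, `"opening"`,
#'   `"closing"`), `duration_s` (> 0) and `peak` (in (0, 1] for non-closed
#'   segments; ignored for closed segments).
#' @return An object of class `word_template`.
#' @export
word_template <- function(label, segments) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("`label` must be a non-empty string", call. = FALSE)
  }
  segments <- as.data.frame(segments)
  need <- c("state", "duration_s", "peak")
  if (!all(need %in% names(segments))) {
    stop("`segments` needs columns state, duration_s, peak", call. = FALSE)
  }
  if (!all(segments$state %in% c("closed", "opening", "closing"))) {
    stop("segment states must be closed/opening/closing", call. = FALSE)
  }
  if (any(!is.finite(segments$duration_s)) || any(segments$duration_s <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  if (segments$state[1] != "closed" || segments$state[nrow(segments)] != "closed") {
    stop("a word template must start and end in the closed state", call. = FALSE)
  }
  active <- segments$state != "closed"
  if (!any(active)) stop("template has no opening/closing segments", call. = FALSE)
  pk <- segments$peak[active]
  if (any(!is.finite(pk)) || any(pk <= 0 | pk > 1)) {
    stop("non-closed peaks must lie in (0, 1]", call. = FALSE)
  }
  structure(list(label = label, segments = segments), class = "word_template")
}

# Build a template from per-syllable lobe parameters: each syllable is an
# opening lobe followed by a closing return lobe; syllables are separated
# by a short closed micro-gap. `close_ratio` (negative-lobe depth relative
# to the opening peak) and `close_dur_ratio` (closing vs opening duration)
# shape the release phase; both survive per-utterance normalization and so
# carry class identity alongside lobe count, relative peaks and durations.
syllable_template <- function(label, open_peaks, open_durs,
                              close_ratio = 0.75, close_dur_ratio = 0.8,
                              gap_s = 0.06, pad_s = 0.12) {
  stopifnot(length(open_peaks) == length(open_durs), length(open_peaks) >= 1)
  rows <- list(data.frame(state = "closed", duration_s = pad_s, peak = NA_real_))
  for (i in seq_along(open_peaks)) {
    rows[[length(rows) + 1L]] <- data.frame(
      state = c("opening", "closing"),
      duration_s = c(open_durs[i], close_dur_ratio * open_durs[i]),
      peak = c(open_peaks[i], pmin(1, close_ratio * open_peaks[i]))
    )
    if (i < length(open_peaks)) {
      rows[[length(rows) + 1L]] <-
        data.frame(state = "closed", duration_s = gap_s, peak = NA_real_)
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(state = "closed", duration_s = pad_s, peak = NA_real_)
  word_template(label, do.call(rbind, rows))
}

#' Built-in word templates
#'
#' Hand-authored lip-motion templates: the 20 fruit names used for the
#' default classification dataset and the 4 directional commands. Template
#' syllable counts, relative peaks and durations are chosen so most classes
#' have distinct waveforms while a few pairs (e.g. Berry/Olive) are
#' naturally close, mirroring the structure of real lip-motion vocabularies.
#'
#' @param set `"fruits"` (20 classes) or `"commands"` (4 classes).
#' @return Named list of [word_template()] objects.
#' @export
builtin_templates <- function(set = c("fruits", "commands")) {
  set <- match.arg(set)
  # class identity is carried by normalization-invariant cues: lobe count,
  # relative peaks, durations and the release (closing) asymmetry
  spec <- if (set == "fruits") {
    list(
      Apple    = list(p = c(1.00, 0.55), d = c(0.26, 0.20), cr = 0.75, cd = 0.8, g = 0.06),
      Banana   = list(p = c(0.90, 0.70, 0.50), d = c(0.18, 0.18, 0.18), cr = 0.75, cd = 0.8, g = 0.05),
      Cherry   = list(p = c(1.00, 0.40), d = c(0.22, 0.16), cr = 0.60, cd = 0.8, g = 0.10),
      Date     = list(p = 0.95, d = 0.30, cr = 0.50, cd = 1.4, g = 0.06),
      Berry    = list(p = c(0.85, 0.50), d = c(0.20, 0.18), cr = 0.75, cd = 0.8, g = 0.06),
      Olive    = list(p = c(0.80, 0.55), d = c(0.21, 0.19), cr = 0.75, cd = 0.8, g = 0.06),
      Grape    = list(p = 1.00, d = 0.45, cr = 0.50, cd = 0.8, g = 0.06),
      Lemon    = list(p = c(0.70, 0.95), d = c(0.20, 0.24), cr = 0.75, cd = 0.8, g = 0.06),
      Mango    = list(p = c(0.90, 0.60), d = c(0.30, 0.22), cr = 0.90, cd = 0.8, g = 0.12),
      Peach    = list(p = 0.75, d = 0.26, cr = 0.45, cd = 0.6, g = 0.06),
      Pear     = list(p = 0.60, d = 0.36, cr = 0.90, cd = 1.2, g = 0.06),
      Plum     = list(p = 0.50, d = 0.22, cr = 1.00, cd = 1.0, g = 0.06),
      Kiwi     = list(p = c(0.65, 0.65), d = c(0.16, 0.16), cr = 0.50, cd = 0.8, g = 0.14),
      Lime     = list(p = 0.85, d = 0.20, cr = 0.55, cd = 1.5, g = 0.06),
      Melon    = list(p = c(0.80, 0.45), d = c(0.24, 0.30), cr = 0.60, cd = 0.8, g = 0.08),
      Papaya   = list(p = c(0.60, 0.90, 0.60), d = c(0.16, 0.22, 0.16), cr = 0.70, cd = 0.8, g = 0.05),
      Guava    = list(p = c(0.95, 0.80), d = c(0.28, 0.18), cr = 0.55, cd = 0.8, g = 0.07),
      Fig      = list(p = 0.55, d = 0.16, cr = 0.90, cd = 0.7, g = 0.06),
      Coconut  = list(p = c(0.70, 0.50, 0.80), d = c(0.17, 0.15, 0.20), cr = 0.80, cd = 0.8, g = 0.07),
      Apricot  = list(p = c(1.00, 0.45, 0.70), d = c(0.22, 0.15, 0.19), cr = 0.65, cd = 0.8, g = 0.06)
    )
  } else {
    list(
      `Go forwards`  = list(p = c(0.90, 0.60), d = c(0.20, 0.28), cr = 0.75, cd = 0.8, g = 0.06),
      `Go backwards` = list(p = c(0.90, 0.45, 0.70), d = c(0.20, 0.16, 0.22), cr = 0.75, cd = 0.8, g = 0.06),
      Left           = list(p = 0.80, d = 0.30, cr = 0.55, cd = 1.2, g = 0.06),
      Right          = list(p = c(0.65, 0.95), d = c(0.16, 0.22), cr = 0.60, cd = 0.8, g = 0.06)
    )
  }
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    syllable_template(nm, s$p, s$d, close_ratio = s$cr,
                      close_dur_ratio = s$cd, gap_s = s$g)
  })
  names(out) <- names(spec)
  out
}

# Blend two templates toward their common mean (used by the dataset
# generator's class-similarity knob); requires equal segment structure or
# falls back to blending peaks of the shorter common prefix.
blend_templates <- function(a, b, s) {
  stopifnot(inherits(a, "word_template"), inherits(b, "word_template"),
            s >= 0, s < 1)
  if (s == 0) return(list(a, b))
  blend_one <- function(x, y) {
    seg <- x$segments
    n <- min(nrow(seg), nrow(y$segments))
    m_dur <- (x$segments$duration_s[seq_len(n)] + y$segments$duration_s[seq_len(n)]) / 2
    m_pk <- (x$segments$peak[seq_len(n)] + y$segments$peak[seq_len(n)]) / 2
    seg$duration_s[seq_len(n)] <- (1 - s) * seg$duration_s[seq_len(n)] + s * m_dur
    same_state <- x$segments$state[seq_len(n)] == y$segments$state[seq_len(n)]
    idx <- which(same_state & seg$state[seq_len(n)] != "closed")
    seg$peak[idx] <- pmin(1, (1 - s) * x$segments$peak[idx] + s * m_pk[idx])
    word_template(x$label, seg)
  }
  list(blend_one(a, b), blend_one(b, a))
}

#' Speaker style profile
#'
#' Captures the per-speaker habits visible in lip-motion recordings:
#' overall speed, a small downward trough some speakers produce at the
#' start of each word, the sample-to-sample variability of amplitudes and
#' durations, and the range of lip-to-sound onset advances.
#'
#' @param name Speaker identifier.
#' @param speed_factor Overall speed multiplier (> 0); durations scale by
#'   `1/speed_factor`.
#' @param initial_trough Whether each word starts with a small downward dip.
#' @param trough_depth Depth of that dip in normalized units.
#' @param amplitude_jitter_cv Coefficient of variation of per-lobe amplitudes.
#' @param duration_jitter_cv Coefficient of variation of segment durations.
#' @param speed_jitter_cv Coefficient of variation of per-utterance speed.
#' @param onset_advance_ms_range Range (low, high) in ms, within \[0, 1000\],
#'   of the head start of lip motion over the sound.
#' @return An object of class `speaker_profile`.
#' @export
speaker_profile <- function(name = "S1", speed_factor = 1,
                            initial_trough = FALSE, trough_depth = 0.08,
                            amplitude_jitter_cv = 0.10,
                            duration_jitter_cv = 0.05,
                            speed_jitter_cv = 0.08,
                            onset_advance_ms_range = c(18, 417)) {
  stop_if_not_scalar_num(speed_factor, "speed_factor", lower = 1e-6)
  stop_if_not_scalar_num(trough_depth, "trough_depth", 0, 1)
  stop_if_not_scalar_num(amplitude_jitter_cv, "amplitude_jitter_cv", 0)
  stop_if_not_scalar_num(duration_jitter_cv, "duration_jitter_cv", 0)
  stop_if_not_scalar_num(speed_jitter_cv, "speed_jitter_cv", 0)
  if (length(onset_advance_ms_range) != 2L ||
      any(onset_advance_ms_range < 0 | onset_advance_ms_range > 1000) ||
      diff(onset_advance_ms_range) < 0) {
    stop("`onset_advance_ms_range` must be an increasing pair within [0, 1000] ms",
         call. = FALSE)
  }
  structure(list(name = name, speed_factor = speed_factor,
                 initial_trough = isTRUE(initial_trough),
                 trough_depth = trough_depth,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 duration_jitter_cv = duration_jitter_cv,
                 speed_jitter_cv = speed_jitter_cv,
                 onset_advance_ms_range = as.numeric(onset_advance_ms_range)),
            class = "speaker_profile")
}
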