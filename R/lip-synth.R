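# Internal renderer: turn a segment table into a clean waveform.
# Sample counts come from cumulative boundaries so total length is exact to
# one sample regardless of how many segments the template has. Returns the
# clean samples plus per-word bookkeeping (words = list of row index ranges
# into `segments` belonging to each word).
render_segments <- function(segments, rate, word_of_segment, profile,
                            jitter = TRUE) {
  dur <- segments$duration_s
  if (jitter && profile$duration_jitter_cv > 0) {
    dur <- dur * exp(stats::rnorm(length(dur), 0, profile$duration_jitter_cv))
  }
  dur <- dur / profile$speed_factor
  bounds <- round(cumsum(c(0, dur)) * rate)
  n_total <- bounds[length(bounds)]
  x <- numeric(n_total)
  active_dur <- 0
  word_span <- list()
  first_open_of_word <- tapply(seq_len(nrow(segments)),
                               word_of_segment,
                               function(ix) ix[segments$state[ix] == "opening"][1])
  for (i in seq_len(nrow(segments))) {
    n <- bounds[i + 1] - bounds[i]
    if (n <= 0) next
    st <- segments$state[i]
    if (st == "closed") {
      next
    }
    pk <- segments$peak[i]
    if (jitter && profile$amplitude_jitter_cv > 0) {
      pk <- pk * exp(stats::rnorm(1, 0, profile$amplitude_jitter_cv))
    }
    u <- (seq_len(n) - 0.5) / n
    lobe <- 0.5 * (1 - cos(2 * pi * u))
    sgn <- if (st == "opening") 1 else -1
    x[(bounds[i] + 1):bounds[i + 1]] <- sgn * pk * lobe
    active_dur <- active_dur + n / rate
    w <- word_of_segment[i]
    sp <- word_span[[as.character(w)]]
    word_span[[as.character(w)]] <- if (is.null(sp)) {
      c(bounds[i] + 1, bounds[i + 1])
    } else {
      c(min(sp[1], bounds[i] + 1), max(sp[2], bounds[i + 1]))
    }
  }
  # optional speaker habit: a small downward trough just before each word
  if (profile$initial_trough) {
    n_tr <- round(0.06 * rate)
    for (w in names(word_span)) {
      i0 <- word_span[[w]][1]
      lo <- max(1, i0 - n_tr)
      n <- i0 - lo
      if (n > 2) {
        u <- (seq_len(n) - 0.5) / n
        x[lo:(i0 - 1)] <- x[lo:(i0 - 1)] -
          profile$trough_depth * 0.5 * (1 - cos(2 * pi * u))
      }
    }
  }
  list(x = x, active_s = active_dur, word_span = word_span)
}

# Threshold-consistent boundaries on the clean waveform: the convention the
# onset detector shares (first/last crossing of `thr` x global peak).
truth_from_clean <- function(x, rate, word_span, thr = 0.05) {
  peak <- max(abs(x))
  above <- which(abs(x) >= thr * peak)
  words <- do.call(rbind, lapply(word_span, function(sp) {
    ix <- above[above >= sp[1] & above <= sp[2]]
    data.frame(start_s = (min(ix) - 1) / rate, end_s = (max(ix) - 1) / rate)
  }))
  rownames(words) <- NULL
  list(onset_s = (min(above) - 1) / rate,
       offset_s = (max(above) - 1) / rate,
       words = words)
}

add_noise <- function(x, rate, powerline_amp, white_amp) {
  peak <- max(abs(x))
  if (peak == 0) return(x)
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  if (powerline_amp > 0) {
    x <- x + powerline_amp * peak *
      sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
  }
  if (white_amp > 0) {
    # white_amp is an amplitude (+-3 sigma excursion) like the power-line
    # term, so the Gaussian sd is one third of it
    x <- x + stats::rnorm(n, 0, white_amp / 3 * peak)
  }
  x
}

new_utterance <- function(lip, label, speaker, seed, truth, profile,
                          sound = NULL) {
  structure(list(lip = lip, sound = sound, label = label, speaker = speaker,
                 seed = seed, truth = truth, profile = profile),
            class = "utterance")
}

#' @export
print.utterance <- function(x, ...) {
  cat(sprintf("<utterance> \"%s\" (speaker %s, seed %d): %d samples @ %g Hz%s\n",
              x$label, x$speaker, x$seed, length(x$lip$samples), x$lip$rate,
              if (is.null(x$sound)) "" else " + sound envelope"))
  invisible(x)
}

#' Synthesize one lip-motion word
#'
#' Renders a [word_template()] as a voltage-like waveform: zero while the
#' mouth is closed, a positive raised-cosine lobe while opening and a
#' negative return lobe while closing (the polarity of the press-release
#' charge transfer). Durations scale with the speaker's speed, per-lobe
#' amplitudes and segment durations are jittered by the profile's
#' coefficients of variation, and measurement noise is added as a 50 Hz
#' power-line sinusoid plus Gaussian white noise. Fully reproducible per
#' seed.
#'
#' The returned utterance carries ground-truth bookkeeping in `$truth`:
#' `active_s` (exact rendered active duration), `onset_s`/`offset_s` and
#' per-word boundaries under the package's 5%-of-peak crossing convention,
#' all computed on the clean pre-noise waveform.
#'
#' @param template A [word_template()].
#' @param profile A [speaker_profile()].
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default 1000).
#' @param powerline_amp 50 Hz interference amplitude as a fraction of the
#'   clean peak (default 0.10).
#' @param white_amp White-noise standard deviation as a fraction of the
#'   clean peak (default 0.02).
#' @return An `utterance` object.
#' @examples
#' tpl <- builtin_templates("fruits")$Apple
#' u <- synth_word(tpl, speaker_profile(), seed = 1)
#' @export
synth_word <- function(template, profile = speaker_profile(), seed = 1,
                       rate = 1000, powerline_amp = 0.10, white_amp = 0.02) {
  stopifnot(inherits(template, "word_template"),
            inherits(profile, "speaker_profile"))
  with_seed(seed, {
    seg <- template$segments
    r <- render_segments(seg, rate, rep(1L, nrow(seg)), profile)
    truth <- truth_from_clean(r$x, rate, r$word_span)
    truth$active_s <- r$active_s
    x <- add_noise(r$x, rate, powerline_amp, white_amp)
    new_utterance(waveform(x, rate, units = "V", kind = "lip"),
                  template$label, profile$name, as.integer(seed), truth, profile)
  })
}

#' Synthesize a connected phrase with coarticulation compression
#'
#' Continuous speech omits parts of the isolated pronunciations: the
#' inter-word closed gaps disappear and every word is shortened. The phrase
#' waveform concatenates the words' active segments with each duration
#' multiplied by `(1 - compression)`, so the phrase's active duration is
#' exactly `(1 - compression)` times the summed isolated durations.
#'
#' @param templates List of [word_template()] objects (>= 1).
#' @param compression Fraction of each word's duration omitted, in \[0, 1).
#' @param profile A [speaker_profile()].
#' @param seed Integer seed.
#' @inheritParams synth_word
#' @return An `utterance` labeled by the concatenated word labels, with
#'   per-word ground-truth boundaries in `$truth$words`.
#' @export
synth_phrase <- function(templates, compression = 0, profile = speaker_profile(),
                         seed = 1, rate = 1000, powerline_amp = 0.10,
                         white_amp = 0.02) {
  if (!is.list(templates) || length(templates) == 0L ||
      !all(vapply(templates, inherits, TRUE, "word_template"))) {
    stop("`templates` must be a non-empty list of word templates", call. = FALSE)
  }
  stop_if_not_scalar_num(compression, "compression", 0, 1 - 1e-9)
  stopifnot(inherits(profile, "speaker_profile"))
  pad <- data.frame(state = "closed", duration_s = 0.12, peak = NA_real_)
  rows <- list(pad)
  word_of <- 0L
  for (k in seq_along(templates)) {
    seg <- templates[[k]]$segments
    act <- seg[seg$state != "closed", , drop = FALSE]
    act$duration_s <- act$duration_s * (1 - compression)
    rows[[length(rows) + 1L]] <- act
    word_of <- c(word_of, rep(k, nrow(act)))
  }
  rows[[length(rows) + 1L]] <- pad
  word_of <- c(word_of, 0L)
  seg_all <- do.call(rbind, rows)
  label <- paste(vapply(templates, function(t) t$label, ""), collapse = " ")
  with_seed(seed, {
    r <- render_segments(seg_all, rate, word_of, profile)
    truth <- truth_from_clean(r$x, rate, r$word_span)
    truth$active_s <- r$active_s
    truth$compression <- compression
    x <- add_noise(r$x, rate, powerline_amp, white_amp)
    new_utterance(waveform(x, rate, units = "V", kind = "lip"),
                  label, profile$name, as.integer(seed), truth, profile)
  })
}

#' Attach a synthetic sound envelope to an utterance
#'
#' The sound envelope is a rectified, smoothed copy of the lip waveform,
#' delayed by the lip-to-sound onset advance (the mouth starts moving
#' before any sound is produced) and truncated so the sound occupies only a
#' fraction of the lip-motion duration (syllables end before the mouth
#' finishes closing). When `advance_ms` is `NULL` the advance is drawn
#' uniformly from the speaker profile's `onset_advance_ms_range`.
#'
#' @param utt An `utterance` from [synth_word()] or [synth_phrase()].
#' @param advance_ms Lip-to-sound onset advance in ms (>= 0), or `NULL` to
#'   draw one from the speaker's range.
#' @param per_word_advances Optional vector of per-word advances in ms (one
#'   per word in `utt$truth$words`); overrides `advance_ms`.
#' @param duration_frac Sound duration as a fraction of lip duration
#'   (default 0.75, the middle of the observed 60.8-85.4% band).
#' @param smooth_ms Zero-phase moving-average width in ms for the envelope.
#' @param seed Seed used when the advance is drawn.
#' @return The utterance with `$sound` set (a normalized envelope waveform)
#'   and the applied advance(s) recorded in `$truth$advance_ms`.
#' @export
synth_sound_envelope <- function(utt, advance_ms = NULL, per_word_advances = NULL,
                                 duration_frac = 0.75, smooth_ms = 10, seed = 1) {
  stopifnot(inherits(utt, "utterance"))
  stop_if_not_scalar_num(duration_frac, "duration_frac", 0.05, 1)
  rate <- utt$lip$rate
  n <- length(utt$lip$samples)
  words <- utt$truth$words
  if (is.null(per_word_advances)) {
    if (is.null(advance_ms)) {
      advance_ms <- with_seed(seed, stats::runif(
        1, utt$profile$onset_advance_ms_range[1],
        utt$profile$onset_advance_ms_range[2]))
    }
    per_word_advances <- rep(advance_ms, nrow(words))
  }
  if (length(per_word_advances) != nrow(words)) {
    stop("`per_word_advances` must have one entry per word", call. = FALSE)
  }
  if (any(per_word_advances < 0)) stop("advances must be >= 0", call. = FALSE)
  if (any(per_word_advances / 1000 >= duration(utt$lip))) {
    stop("advance longer than the utterance", call. = FALSE)
  }
  # articulation envelope: sensor electrical noise (50 Hz pickup, white
  # noise) must not leak into the acoustic channel, so rectify the
  # low-passed lip signal
  clean <- if (rate > 45) lowpass(utt$lip, 20)$samples else utt$lip$samples
  env_full <- smooth_ma(abs(clean), max(1L, round(smooth_ms * rate / 1000)))
  snd <- numeric(n)
  for (k in seq_len(nrow(words))) {
    i0 <- round(words$start_s[k] * rate) + 1
    i1 <- round(words$end_s[k] * rate) + 1
    shift <- round(per_word_advances[k] * rate / 1000)
    keep <- round(duration_frac * (i1 - i0))
    src <- i0:min(i1, i0 + keep)
    dst <- src + shift
    ok <- dst <= n
    snd[dst[ok]] <- snd[dst[ok]] + env_full[src[ok]]
    # short fade-out so truncation does not leave a cliff
    nf <- min(length(dst[ok]), max(2L, round(0.01 * rate)))
    if (nf > 1) {
      tail_ix <- utils::tail(dst[ok], nf)
      snd[tail_ix] <- snd[tail_ix] * seq(1, 0, length.out = nf)
    }
  }
  if (max(snd) > 0) snd <- snd / max(snd)
  utt$sound <- waveform(snd, rate, units = "normalized", kind = "sound")
  utt$truth$advance_ms <- per_word_advances
  utt$truth$duration_frac <- duration_frac
  utt
}

# zero-phase moving average (centered window, edge-padded)
smooth_ma <- function(x, width) {
  if (width <= 1L) return(x)
  half <- floor(width / 2)
  xp <- c(rep(0, half), x, rep(0, half))
  cs <- cumsum(xp)
  w <- 2L * half + 1L
  (cs[(w):length(cs)] - c(0, cs[seq_len(length(cs) - w)])) [seq_along(x)] / w
}

#' Generate a labeled lip-motion dataset
#'
#' Seeded generator of the study-scale classification dataset: `n_classes`
#' word classes with `n_per_class` utterances each, every sample perturbed
#' by the speaker profile's amplitude, duration and speed jitters plus
#' measurement noise, and tagged with a stratified train/test split.
#'
#' @param n_classes Number of classes (>= 2); defaults to 20.
#' @param n_per_class Samples per class; defaults to 100.
#' @param templates Named list of [word_template()] objects, at least
#'   `n_classes` long; defaults to the built-in fruit vocabulary.
#' @param profile A [speaker_profile()].
#' @param base_seed Master seed; all per-sample seeds derive from it.
#' @param similarity Class-similarity knob in \[0, 1): blends the first two
#'   templates toward each other to create a deliberately confusable pair.
#' @param train_frac Fraction of each class tagged `train` (default 0.8).
#' @param rate Sampling rate in Hz.
#' @inheritParams synth_word
#' @return An object of class `lip_dataset`: list with `utterances` (list),
#'   `manifest` (data frame: `id`, `label`, `speaker`, `split`, `seed`) and
#'   `params`.
#' @export
make_dataset <- function(n_classes = 20, n_per_class = 100,
                         templates = builtin_templates("fruits"),
                         profile = speaker_profile(), base_seed = 1,
                         similarity = 0, train_frac = 0.8, rate = 1000,
                         powerline_amp = 0.10, white_amp = 0.02) {
  stop_if_not_scalar_num(n_classes, "n_classes", 2)
  stop_if_not_scalar_num(n_per_class, "n_per_class", 2)
  stop_if_not_scalar_num(similarity, "similarity", 0, 1 - 1e-9)
  if (length(templates) < n_classes) {
    stop("need at least `n_classes` templates", call. = FALSE)
  }
  templates <- templates[seq_len(n_classes)]
  labels <- vapply(templates, function(t) t$label, "")
  if (anyDuplicated(labels)) stop("duplicate class labels in templates", call. = FALSE)
  if (similarity > 0 && n_classes >= 2) {
    bl <- blend_templates(templates[[1]], templates[[2]], similarity)
    templates[[1]] <- bl[[1]]
    templates[[2]] <- bl[[2]]
  }
  n_total <- n_classes * n_per_class
  seeds <- derive_seeds(base_seed, n_total)
  n_test <- round((1 - train_frac) * n_per_class)
  split_tags <- with_seed(base_seed + 1L, {
    lapply(seq_len(n_classes), function(k) {
      tags <- rep("train", n_per_class)
      tags[sample.int(n_per_class, n_test)] <- "test"
      tags
    })
  })
  utterances <- vector("list", n_total)
  manifest <- data.frame(id = seq_len(n_total),
                         label = rep(labels, each = n_per_class),
                         speaker = profile$name,
                         split = unlist(split_tags),
                         seed = seeds)
  idx <- 0L
  for (k in seq_len(n_classes)) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      sd <- seeds[idx]
      prof_j <- profile
      prof_j$speed_factor <- with_seed(sd + 1L,
        profile$speed_factor * exp(stats::rnorm(1, 0, profile$speed_jitter_cv)))
      utterances[[idx]] <- synth_word(templates[[k]], prof_j, seed = sd,
                                      rate = rate, powerline_amp = powerline_amp,
                                      white_amp = white_amp)
    }
  }
  structure(list(utterances = utterances, manifest = manifest,
                 params = list(n_classes = n_classes, n_per_class = n_per_class,
                               base_seed = base_seed, similarity = similarity,
                               train_frac = train_frac, rate = rate,
                               labels = labels)),
            class = "lip_dataset")
}

#' @export
print.lip_dataset <- function(x, ...) {
  cat(sprintf("<lip_dataset> %d classes x %d samples (%d train / %d test), seed %d\n",
              x$params$n_classes, x$params$n_per_class,
              sum(x$manifest$split == "train"), sum(x$manifest$split == "test"),
              x$params$base_seed))
  invisible(x)
}
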