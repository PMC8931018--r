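still_profile <- function(...) {
  speaker_profile(amplitude_jitter_cv = 0, duration_jitter_cv = 0,
                  speed_jitter_cv = 0, ...)
}

test_that("word templates enforce the closed-open-close alternation", {
  seg <- data.frame(state = c("closed", "opening", "closing", "closed"),
                    duration_s = c(0.1, 0.2, 0.15, 0.1),
                    peak = c(NA, 0.8, 0.5, NA))
  expect_s3_class(word_template("ok", seg), "word_template")
  bad <- seg[c(2, 3, 4), ]
  expect_error(word_template("bad", bad), "closed")
  seg2 <- seg
  seg2$peak[2] <- 1.5
  expect_error(word_template("bad", seg2), "\\(0, 1\\]")
  seg3 <- seg
  seg3$duration_s[2] <- 0
  expect_error(word_template("bad", seg3), "positive")
})

test_that("word synthesis is seed-deterministic and amplitude-faithful", {
  tpl <- builtin_templates("fruits")$Apple
  u1 <- synth_word(tpl, speaker_profile(), seed = 7)
  u2 <- synth_word(tpl, speaker_profile(), seed = 7)
  expect_identical(u1$lip$samples, u2$lip$samples)
  u3 <- synth_word(tpl, speaker_profile(), seed = 8)
  expect_false(identical(u1$lip$samples, u3$lip$samples))
  # no jitter, no noise: waveform peak equals the template peak
  uc <- synth_word(tpl, still_profile(), seed = 1,
                   powerline_amp = 0, white_amp = 0)
  expect_equal(max(abs(uc$lip$samples)), max(tpl$segments$peak, na.rm = TRUE),
               tolerance = 1e-3)
  # doubling the speaking speed halves the duration to within one sample
  uf <- synth_word(tpl, still_profile(speed_factor = 2), seed = 1,
                   powerline_amp = 0, white_amp = 0)
  expect_lte(abs(length(uc$lip$samples) - 2 * length(uf$lip$samples)), 2)
})

test_that("initial-trough speaker habit dips below zero before the word", {
  tpl <- builtin_templates("fruits")$Date
  u <- synth_word(tpl, still_profile(initial_trough = TRUE, trough_depth = 0.1),
                  seed = 1, powerline_amp = 0, white_amp = 0)
  i_on <- round(u$truth$words$start_s[1] * 1000) + 1
  pre <- u$lip$samples[seq_len(i_on - 1)]
  expect_lt(min(pre), -0.05)
})

test_that("phrase compression reproduces the printed duration efficiencies", {
  tpl <- builtin_templates("fruits")[1:4]
  prof <- still_profile()
  sep <- vapply(tpl, function(t) {
    synth_word(t, prof, seed = 2, powerline_amp = 0, white_amp = 0)$truth$active_s
  }, 0)
  # compression chosen as for the four-word phrase read continuously:
  # 1.648 s continuous vs 2.398 s separate
  comp <- 1 - 1.648 / 2.398
  ph <- synth_phrase(tpl, comp, prof, seed = 2,
                     powerline_amp = 0, white_amp = 0)
  expect_equal(efficiency(sep, ph$truth$active_s), 31.3, tolerance = 0.02)
  # two-word phrase: 1.10 s continuous vs 1.286 s separate
  comp2 <- 1 - 1.10 / 1.286
  ph2 <- synth_phrase(tpl[1:2], comp2, prof, seed = 3,
                      powerline_amp = 0, white_amp = 0)
  expect_equal(efficiency(sep[1:2], ph2$truth$active_s), 14.5, tolerance = 0.03)
  # no compression: active duration equals the summed word durations
  ph0 <- synth_phrase(tpl, 0, prof, seed = 2, powerline_amp = 0, white_amp = 0)
  expect_equal(ph0$truth$active_s, sum(sep), tolerance = 5e-3)
  expect_lt(ph$truth$active_s, sum(sep))
  expect_error(synth_phrase(list(), 0.1), "non-empty")
})

test_that("sound envelopes lag the lip signal by the planted advance", {
  tpl <- builtin_templates("fruits")$Mango
  u <- synth_word(tpl, speaker_profile(), seed = 21)
  u0 <- synth_sound_envelope(u, advance_ms = 0)
  expect_lte(abs(onset_advance(lowpass(u0$lip), u0$sound)), 2)
  u100 <- synth_sound_envelope(u, advance_ms = 100)
  on0 <- detect_onsets(u0$sound)$start_s[1]
  on100 <- detect_onsets(u100$sound)$start_s[1]
  expect_lte(abs((on100 - on0) * 1000 - 100), 1)
  # lip onset precedes the sound onset whenever an advance is applied
  expect_lt(detect_onsets(lowpass(u100$lip))$start_s[1], on100)
  # drawn advances stay in the speaker's range and are seed-deterministic
  ud <- synth_sound_envelope(u, seed = 4)
  expect_identical(ud$truth$advance_ms,
                   synth_sound_envelope(u, seed = 4)$truth$advance_ms)
  expect_true(all(ud$truth$advance_ms >= 18 & ud$truth$advance_ms <= 417))
  expect_error(synth_sound_envelope(u, advance_ms = 1e6), "longer")
})

test_that("sound duration occupies the configured fraction of the lip duration", {
  tpl <- builtin_templates("fruits")$Guava
  u <- synth_sound_envelope(synth_word(tpl, speaker_profile(), seed = 31),
                            advance_ms = 50, duration_frac = 0.75)
  lip_seg <- detect_onsets(lowpass(u$lip))
  snd_seg <- detect_onsets(u$sound)
  frac <- duration_fraction(snd_seg$end_s[1] - snd_seg$start_s[1],
                            lip_seg$end_s[1] - lip_seg$start_s[1])
  expect_gt(frac, 60.8)
  expect_lt(frac, 85.4)
})

test_that("dataset generation is balanced, split-tagged and reproducible", {
  ds <- make_dataset(n_classes = 4, n_per_class = 10, base_seed = 3)
  expect_equal(nrow(ds$manifest), 40)
  counts <- table(ds$manifest$label, ds$manifest$split)
  expect_true(all(counts[, "train"] == 8))
  expect_true(all(counts[, "test"] == 2))
  ds2 <- make_dataset(n_classes = 4, n_per_class = 10, base_seed = 3)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$utterances[[17]]$lip$samples,
                   ds2$utterances[[17]]$lip$samples)
  # different base seed changes the waveforms
  ds3 <- make_dataset(n_classes = 4, n_per_class = 10, base_seed = 4)
  expect_false(identical(ds$utterances[[1]]$lip$samples,
                         ds3$utterances[[1]]$lip$samples))
  bad <- builtin_templates("fruits")[c(1, 1)]
  expect_error(make_dataset(2, 4, templates = bad), "duplicate")
})

test_that("classes are separated farther than the within-class jitter spread", {
  ds <- make_dataset(n_classes = 4, n_per_class = 8, base_seed = 9)
  X <- vapply(ds$utterances, function(u) {
    lipdecode:::condition_signal(u$lip, 20, 200)
  }, numeric(200))
  lab <- ds$manifest$label
  centroids <- vapply(unique(lab), function(l) {
    rowMeans(X[, lab == l, drop = FALSE])
  }, numeric(200))
  within <- mean(vapply(seq_along(lab), function(i) {
    sqrt(sum((X[, i] - centroids[, lab[i]])^2))
  }, 0))
  between <- min(dist(t(centroids)))
  expect_gt(between, within)
})
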