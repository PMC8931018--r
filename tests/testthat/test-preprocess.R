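test_that("default low-pass removes 50 Hz interference but keeps slow lobes", {
  rate <- 1000
  t <- (0:1999) / rate
  hum <- waveform(sin(2 * pi * 50 * t), rate)
  out <- lowpass(hum)
  expect_lt(max(abs(out$samples[200:1800])), 0.01)
  lobe <- waveform(sin(2 * pi * 2.5 * t), rate)
  kept <- lowpass(lobe)
  expect_lt(max(abs(kept$samples - lobe$samples)[200:1800]), 0.05)
  zero <- waveform(rep(0, 500), rate)
  expect_equal(lowpass(zero)$samples, rep(0, 500))
  expect_error(lowpass(waveform(rnorm(100), 30), cutoff_hz = 20), "Nyquist")
})

test_that("zero-phase filtering does not shift onsets", {
  u <- synth_word(builtin_templates("fruits")$Peach, speaker_profile(),
                  seed = 3, powerline_amp = 0.1, white_amp = 0)
  on_clean <- u$truth$onset_s
  on_filt <- detect_onsets(lowpass(u$lip))$start_s[1]
  expect_lte(abs(on_filt - on_clean) * u$lip$rate, 2)
})

test_that("normalization rescales to unit peak and preserves shape", {
  w <- waveform(c(0.1, 2.0, -0.5, 0.634), 100)
  n <- normalize(w)
  expect_equal(max(abs(n$samples)), 1)
  expect_equal(n$samples[2], 1)
  expect_equal(n$samples[4], 0.317)
  expect_equal(n$samples[3], -0.25)  # sign preserved
  expect_identical(normalize(n)$samples, n$samples)  # idempotent
  expect_error(normalize(waveform(rep(0, 5), 10)), "all-zero")
})

test_that("filtering then normalizing is invariant to input scaling", {
  u <- synth_word(builtin_templates("fruits")$Lime, speaker_profile(), seed = 4)
  a <- normalize(lowpass(u$lip))
  scaled <- waveform(3.7 * u$lip$samples, u$lip$rate)
  b <- normalize(lowpass(scaled))
  expect_equal(a$samples, b$samples, tolerance = 1e-10)
})

test_that("onset detection separates words at closed-state gaps", {
  rate <- 1000
  lobe <- sin(pi * (1:300) / 300)
  x <- c(rep(0, 200), lobe, rep(0, 300), lobe, rep(0, 200))
  w <- waveform(x, rate)
  seg <- detect_onsets(w)
  expect_equal(nrow(seg), 2)
  # gap below the closed-state minimum is bridged into a single word
  x2 <- c(rep(0, 200), lobe, rep(0, 100), lobe, rep(0, 200))
  expect_equal(nrow(detect_onsets(waveform(x2, rate))), 1)
  expect_equal(nrow(detect_onsets(w, threshold_frac = 2)), 0)
})

test_that("onset advance is recovered from planted lip-sound lags", {
  u <- synth_word(builtin_templates("fruits")$Cherry, speaker_profile(),
                  seed = 12)
  for (adv in c(18, 124, 417)) {
    ue <- synth_sound_envelope(u, advance_ms = adv)
    expect_lte(abs(onset_advance(lowpass(ue$lip), ue$sound) - adv), 2)
  }
  w <- normalize(lowpass(u$lip))
  expect_equal(onset_advance(w, w), 0)
  expect_error(onset_advance(w, waveform(rep(0, 10), w$rate)), "onset")
})

test_that("duration efficiency matches the worked examples exactly", {
  expect_equal(round(efficiency(2.398, 1.648), 1), 31.3)
  expect_equal(round(efficiency(1.286, 1.10), 1), 14.5)
  expect_equal(efficiency(c(1, 1), 2), 0)
  # scale-invariant under a common time-unit change
  expect_equal(efficiency(c(550, 736) , 900), efficiency(c(0.55, 0.736), 0.9))
  expect_error(efficiency(1.0, 1.5), "exceeds")
  expect_error(efficiency(c(1, -1), 0.5), "positive")
})

test_that("duration fraction and data volume ratio are plain ratios", {
  expect_equal(duration_fraction(1, 1), 100)
  expect_equal(duration_fraction(0.608, 1.0), 60.8)
  expect_equal(duration_fraction(0.854, 1.0), 85.4)
  expect_equal(duration_fraction(608, 1000), duration_fraction(0.608, 1))
  expect_error(duration_fraction(1, 0), "positive")
  expect_equal(data_volume_ratio(12, 576), 1 / 48)
  expect_equal(data_volume_ratio(7, 7), 1)
  expect_equal(data_volume_ratio(1, 4), 0.25)
  expect_error(data_volume_ratio(0, 10), "positive")
})

test_that("spectrogram locates tones and vanishes for silence", {
  rate <- 1000
  tone <- waveform(sin(2 * pi * 5 * (0:4095) / rate), rate)
  sg <- stft(tone, window_len = 512, hop = 128)
  peak_freq <- sg$freq_hz[apply(sg$magnitude, 2, which.max)]
  expect_true(all(abs(peak_freq - 5) <= rate / 512))
  expect_equal(dim(sg$magnitude), c(length(sg$freq_hz), length(sg$time_s)))
  zero <- stft(waveform(rep(0, 1024), rate), window_len = 256)
  expect_true(all(zero$magnitude == 0))
  expect_error(stft(tone, window_len = 8192), "length")
  expect_error(stft(tone, window_len = 256, hop = 0), "positive")
})

test_that("model input resampling and padding keep the signal centered", {
  w <- waveform(sin(2 * pi * 3 * (0:999) / 1000), 1000)
  expect_identical(to_model_input(w, 1000), w$samples)
  half <- to_model_input(w, 500)
  expect_length(half, 500)
  short <- waveform(rep(1, 10), 1000)
  padded <- to_model_input(short, 20)
  expect_length(padded, 20)
  expect_equal(sum(padded), 10)
  nz <- range(which(padded != 0))
  expect_lte(abs((nz[1] - 1) - (20 - nz[2])), 1)  # centered within one sample
  # decimation by two reads every other position (after anti-aliasing,
  # which leaves a slow in-band sine untouched)
  slow <- sin(2 * pi * 0.5 * (0:99) / 10)
  dec <- to_model_input(waveform(slow, 10), 50)
  expect_equal(dec, slow[seq(1, 99, by = 2)], tolerance = 0.05)
})

test_that("planted segment boundaries are recovered to within two samples", {
  tpls <- builtin_templates("fruits")
  worst <- 0
  for (i in 1:25) {
    u <- synth_word(tpls[[(i %% 20) + 1]], speaker_profile(), seed = 4000 + i)
    seg <- detect_onsets(lowpass(u$lip))
    expect_equal(nrow(seg), nrow(u$truth$words))
    err <- max(abs(c(seg$start_s - u$truth$words$start_s,
                     seg$end_s - u$truth$words$end_s))) * u$lip$rate
    worst <- max(worst, err)
  }
  expect_lte(worst, 2 + 1e-9)
})
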