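---
title: "Methods: simulating, conditioning and decoding triboelectric lip-motion signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, conditioning and decoding triboelectric lip-motion signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipdecode)
```

`lipdecode` models the computational side of a silent-speech interface built
on flexible triboelectric sensors worn at the corners of the mouth: a
calibrated simulator of the sensor's electrical output, a seeded generator
of synthetic lip-motion utterances, the signal-conditioning and
timing-analysis chain used on such recordings, and a dilated
gated-recurrent-unit (GRU) classifier with prototype learning. This
vignette documents the models, the tunable parameters, the numerical
choices and the limitations.

## 1. The sensor model

A contact-separation triboelectric sensor produces an alternating signal as
the mouth opens (presses the sensor) and closes (releases it). One
press-release cycle has four stages: closed mouth (no current), pressing
(current one way), full opening (current returns to zero), releasing
(current the opposite way). `cycle_shape()` represents this as a fixed
smooth template: a positive raised-cosine lobe over the pressing half-cycle
and a mirror-image negative lobe over the release half-cycle. The template
is zero at the stage boundaries, has unit amplitude, and integrates to zero
over a full cycle, so simulated short-circuit current conserves charge.

### Calibration

`default_calibration()` anchors the simulator to bench characterization of
the reference sensor (a 20 x 20 x 5 mm square driven at 5 N and 1 Hz):

* **Force.** Peak open-circuit voltage is linear in the pressing force with
  sensitivity 0.376 V/N; below the 1 N anchor the response continues
  linearly to zero at zero force.
* **Frequency.** Peak voltage is essentially frequency-independent; the
  observed 0.02 V fluctuation band across 1-5 Hz is carried as a small
  multiplicative ripple. Peak short-circuit current instead rises
  monotonically with pressing frequency, from 1.88 nA at 1 Hz to 9.66 nA at
  5 Hz (more charge transferred per unit time).
* **Area and thickness.** Larger plates transfer more charge: voltage and
  current scale by monotone factors anchored at the measured 1.10 to 3.08 V
  and 1.52 to 4.39 nA rises from D = 20 to D = 50 mm. The thickness
  response saturates at 2 mm (electrostatic induction decays with spacer
  gap), so T = 2 mm and T = 5 mm outputs differ by under 2%.
* **Durability.** Amplitude decays linearly from 1.00 at cycle 0 to
  1.38/1.40 at cycle 2000, clamped beyond.

The per-axis sweeps were measured one at a time, never jointly, so the
calibration composes them multiplicatively relative to the reference
condition. The published per-axis absolute scales are mutually
inconsistent (a 0.376 V/N slope over 1-5 N cannot coexist with a ~1 V
absolute output at 5 N), which is common when panels come from different
sensor builds; this package resolves it by letting the force axis carry
the absolute scale and treating the other axes as relative factors. The
printed area ratio (3.08/1.10 = 2.8) is preserved exactly; the printed
absolute area voltages are not reproduced and are documented as such.

Interpolation between anchors is piecewise linear, which preserves
monotonicity; inputs outside the anchored ranges raise an error unless
`extrapolate = TRUE` (clamped, or slope-extended for force).

`load_sweep()` models the sensor as a Thevenin source: delivered power
$P(R) = V_p^2 R/(R+R_i)^2$ peaks exactly at the matched load $R = R_i$
(97.1 M$\Omega$ and 3.50 nW for the characterized device), and
`combine_sensors()` applies ideal superposition: series chains add
voltages, parallel banks add currents, so series voltage amplitude exceeds
parallel for identical units.

## 2. The synthetic utterance generator

The study's raw lip-motion recordings are not available in machine-readable
form, so `synth_word()`, `synth_phrase()` and `make_dataset()` generate
utterances with the statistical structure those analyses assume.

A word template is an alternation of mouth states — `closed` (zero
signal), `opening` (positive lobe), `closing` (negative return lobe) —
with per-segment durations and normalized peaks. The built-in vocabulary
(20 fruit names, 4 directional commands) is hand-authored. Because the
conditioning chain normalizes every utterance to unit peak, absolute
amplitude carries no class information; class identity therefore lives in
normalization-invariant cues: the number of lobes (syllables), the
relative peaks within a word, segment durations, and the release asymmetry
(depth and duration of the closing lobe relative to the opening lobe).
Most words are deliberately distinct; Berry and Olive are deliberately
similar, mirroring the confusable pairs seen in real vocabularies, and
`make_dataset(similarity = )` can morph the first two templates together
to create harder confusions on demand.

Speaker style is a `speaker_profile()`: overall speed (durations scale by
`1/speed_factor`), an optional downward trough at each word start (a habit
some speakers show), amplitude jitter (log-normal, CV 0.10), duration
jitter (CV 0.05) and per-utterance speed jitter (CV 0.08). Measurement
noise is added as a 50 Hz power-line sinusoid (amplitude 10% of the clean
peak — the interference that motivates the 20 Hz low-pass) plus Gaussian
white noise whose amplitude parameter (default 2% of peak) specifies the
±3σ excursion, the same amplitude convention as the sinusoidal term.
All randomness derives from one seed; identical seeds give bit-identical
utterances.

Connected speech omits parts of the isolated pronunciations:
`synth_phrase()` drops the inter-word closed gaps and multiplies each
word's duration by `(1 - compression)`, so the phrase's active duration is
exactly `(1 - compression)` times the summed isolated durations. The sound
channel is represented as an envelope, not audio (every analysis that uses
sound needs only onsets and durations): `synth_sound_envelope()` rectifies
and smooths the low-passed lip waveform, delays it by the lip-to-sound
onset advance (drawn from the speaker's 18-417 ms range unless given), and
truncates it so the sound occupies a configurable fraction (default 0.75,
inside the observed 60.8-85.4% band) of the lip duration.

Each utterance carries ground-truth bookkeeping computed on the clean,
pre-noise waveform under the same 5%-of-peak crossing convention the
detector uses, which is what the closed-loop recovery tests compare
against.

The default dataset is the study-scale protocol: 20 classes x 100 samples,
stratified 80/20 train/test tags, per-sample seeds derived from one base
seed.

What the generator does **not** emulate: real articulator biomechanics and
phoneme-to-waveform mapping, inter-session sensor placement drift,
baseline wander, cross-speaker template variation beyond the profile knobs,
and real acoustics. Tests passing on this generator show the chain is
self-consistent and that the classifier separates waveform families of
this structure at these noise levels — not that any particular accuracy
would be attained on the authors' recordings.

## 3. Signal conditioning and timing analyses

* `lowpass()` — 4th-order Butterworth at 20 Hz applied forward-backward
  (`signal::filtfilt`), chosen because the double pass is zero-phase (no
  onset shift) and attenuates the 50 Hz interference by over 60 dB while
  keeping the sub-10 Hz passband within 0.1 dB.
* `normalize()` — division by the maximum absolute value, preserving signs
  and relative sub-peaks. Idempotent by construction.
* `detect_onsets()` — activity where the magnitude reaches 5% of the peak;
  active runs separated by less than the minimum closed-state gap
  (default 0.2 s) are bridged, so brief dips between lobes stay inside a
  word while genuine pauses split words. The threshold is a design
  default; the paper's own onset criterion is unspecified.
* `onset_advance()` — sound onset minus lip onset, in ms, both located by
  the same relative-threshold rule so rise-shape biases cancel; the
  closed-loop tests recover planted advances to ±2 ms at 1 kHz.
* `efficiency()` — `100 * (sum(separate) - continuous)/sum(separate)`, the
  only definition consistent with both worked duration pairs
  (2.398 s vs 1.648 s giving 31.3%, and 1.286 s vs 1.10 s giving 14.5%).
* `stft()` — Hanning-window magnitude spectrogram via `signal::specgram`.
* `to_model_input()` — fixed-length model input: longer signals are
  anti-alias filtered (0.45 x the output Nyquist) and linearly resampled at
  a constant stride; shorter ones are zero-padded symmetrically.

## 4. The classifier

The feature extractor is a 4-layer dilated GRU with 50 neurons per layer
and dilations 1, 2, 4, 8 (exponential, the standard schedule): layer $l$
updates its hidden state from the state $d_l$ steps back, which enlarges
the temporal receptive field without adding parameters (dilation changes
connectivity only — `drnn_n_params()` is dilation-independent). The cell
is the standard GRU,

$$z_t = \sigma(W_z x_t + U_z h_{prev} + b_z),\quad
  r_t = \sigma(W_r x_t + U_r h_{prev} + b_r),$$
$$\tilde h_t = \tanh(W_c x_t + U_c (r_t \odot h_{prev}) + b_c),\quad
  h_t = (1-z_t)\odot h_{prev} + z_t \odot \tilde h_t,$$

with $h_{prev} = h_{t-d_l}$ (zero before the first step of each chain).
The feature vector is a linear map of the top layer's final state(s): the
mean of its last $d_L$ hidden states, one per recurrence chain, so every
chain contributes (a single final state reads only one chain's endpoint).
The exported `gru_step()` is a plain-R reference implementation; the
batched extractor is compiled (RcppArmadillo) and is required by the test
suite to agree with compositions of `gru_step()` and to reproduce
finite-difference gradients to 1e-5.

Two classification heads share the extractor:

* **Prototype learning** — each class $k$ owns a prototype $m_k$ in
  feature space; $p(k\,|\,f) \propto \exp(-\gamma\,\|f - m_k\|^2)$, and the
  training loss is this distance-based cross-entropy plus a pull term
  $\lambda \|f - m_y\|^2$ ($\gamma = 1$, $\lambda = 0.01$ by default, one
  prototype per class). Prototypes are initialized to the class means of
  the untrained features (one forward pass) and then optimized jointly.
* **Softmax baseline** — a linear layer plus cross-entropy.

Training uses Adam (learning rate 1e-3 by default, batch 32) with an
optional cosine decay of the learning rate to 10% over the run; the
desk-scale experiments below use 3e-3 with decay, which converges
noticeably faster at these problem sizes. All initialization, shuffling
and subsampling derive from the config seed, so runs are bit-reproducible
at a fixed thread count. Ties in the argmax go to the lowest class index.

### Problem sizes used by the tests

The packaged experiments run the full study-scale dataset (20 x 100,
80/20) but condition each utterance to 64 samples and train for 100
epochs. Sixty-four samples correspond to an effective sampling rate of
roughly 45-60 Hz for word-length utterances — comfortably above twice the
20 Hz filter band, so the resampling loses no in-band structure — and the
100-epoch budget is where both heads' accuracy curves have flattened on
this data. The `to_model_input()` default of 1000 samples (one second at
the native rate) remains for users who want the unreduced representation.

### Open-set decisions

`predict()` optionally rejects inputs whose nearest-prototype distance
exceeds a threshold. `enroll_speaker()` builds the verification policy for
the identity-check application: the enrolled prototype is the mean
enrollment feature vector and the threshold is 1.5 x the 95th percentile
of the genuine enrollment distances — calibrated without impostor data,
with the margin covering held-out genuine attempts. Acceptance is monotone
in the threshold: 0 rejects everything, infinity accepts everything.

## 5. Evaluation harness

`confusion_report()` computes the row-normalized confusion matrix from
exact count ratios (rows sum to 1) plus the summary fractions of classes at
100%, above 90% and above 80% accuracy. `small_sample_sweep()` subsamples
the training split per class (seeded) to fixed fractions, retrains both
heads and evaluates on the untouched test split; the headline value per
cell is the median over 3 seeds. `feature_map_2d()` embeds samples with a
`feature_dim = 2` extractor and summarizes class structure as mean
between-class over mean within-class pairwise distance. On inputs that are
already class-clustered, even an untrained random extractor inherits a
ratio above 1; the class-blind null (permuted labels) sits at 1, and
training drives the ratio far higher — the tests check all three
behaviors.

## 6. Numerical choices and degenerate inputs

* All-zero waveforms cannot be normalized (error) and yield no onsets.
* The onset detector returns an empty segment set when the threshold
  exceeds the peak.
* Waveform CSVs must present a uniform, monotone time grid; the JSON
  sidecar carries units, rate and provenance, and every generated artifact
  records the parameters and seed needed to regenerate it.
* Boundary localization is noise-floor limited: after the 20 Hz low-pass,
  residual noise is band-limited like the signal itself, so a threshold
  crossing on a lobe with slope $s$ shifts by (noise amplitude)/$s$. At
  the default noise levels this keeps recovered boundaries within ±2
  samples at 1 kHz; substantially noisier generators would degrade the
  shallow release offsets first.
* Model checkpoints are JSON (weights as flat arrays plus shapes); layer
  lists are serialized as named objects so the structure survives the JSON
  round-trip unambiguously.

## 7. Known limitations

* The simulator is a calibration surface, not a physics solver: no
  electrostatic field computation, no material screening, no mechanical
  contact model.
* The generator's word templates are hand-authored, not phoneme-derived;
  cross-speaker generalization is only as rich as the profile knobs.
* The classifier is a whole-utterance classifier (as in the application it
  models): no sequence-to-sequence decoding, no data augmentation beyond
  the generator's jitter.
* Single prototype per class; multi-prototype variants are not
  implemented.
```
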