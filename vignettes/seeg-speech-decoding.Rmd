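---
title: "Decoding Mandarin articulatory features from cortical and subcortical sEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding Mandarin articulatory features from cortical and subcortical sEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

Speech neuroprostheses decode intended speech from intracranial
recordings. Most work uses electrocorticography, which samples only the
cortical surface. Stereotactic EEG (sEEG) depth electrodes, implanted
for epilepsy monitoring, additionally sample deep structures — the
thalamus, hippocampus, amygdala, insular and parahippocampal gyri — so
they can ask a question surface grids cannot: *what do subcortical
structures contribute to speech decoding?*

`seegspeech` implements an analysis chain for this question in the
setting of spoken Mandarin, where each syllable is characterized by
three articulatory label spaces:

* **place of articulation** of the initial consonant — 7 categories
  (bilabial, labiodental, dental, alveolar, post-alveolar, palatal,
  velar), chance level 1/7;
* **manner of articulation** — 8 categories (plosives and affricates,
  each unaspirated/aspirated; voiceless and voiced fricatives; nasal;
  lateral), chance level 1/8;
* **lexical tone** — 4 categories, chance level 1/4.

The 21 Mandarin initials occupy the cells of the standard
place-voice-manner chart (`consonantInventory()`); zero-initial
syllables such as "an" have a tone but no consonant, so they
participate only in the tone task. The neutral (fifth) tone is excluded:
the 4-class tone space fixes the 1/4 chance level, and syllables
annotated with tone 0/5 are rejected at labeling time.

## Signal path

Raw recordings are multichannel voltage series at 2000 Hz. The feature
extraction follows the standard intracranial band-power recipe:

1. per-channel least-squares **linear detrend** over the full session,
   then an **anti-alias low-pass at 500 Hz** (Butterworth order 4,
   forward-backward);
2. three band features: the **1–30 Hz** and **30–70 Hz** components via
   6-pole Butterworth band-passes, and the **70–150 Hz high-gamma
   envelope** via band-pass + Hilbert analytic-signal magnitude (the
   high-gamma envelope tracks local population firing and is the
   canonical speech-decoding feature);
3. decimation to a common **200 Hz** axis (every 10th sample, with a
   safety 100 Hz low-pass on the envelope so envelope ripple cannot
   alias);
4. a **running z-score** with a 30 s centered window per channel and
   band.

All filters are applied forward-backward (zero phase). This is a
deliberate reading of the requirement that the three band series be
*parallelly aligned*: zero-phase filtering leaves no relative group
delay between bands, so an impulse peaks at the same output index in
all three paths (tested to ±1 sample). The cost is that each filter's
effective magnitude response is squared (effective order doubles); the
test oracles therefore compare measured gains against the closed-form
bilinear-transform Butterworth magnitude *squared*
(`butterBandGain()`), and agree to 1%. "6th-order Butterworth
band-pass" is read as a 6-pole band-pass (prototype order 3), the usual
engineering convention.

Numerical choices worth knowing:

* the running z-score uses a centered window, shrunk symmetrically at
  session edges (offline analysis has no causality constraint), with a
  floored standard deviation `max(sd, 1e-8 * global sd, 1e-12)`;
  windows that are flat to numerical precision output exactly zero, so
  constant channels map to zeros rather than noise;
* decimation keeps every 10th sample starting at the first, so all
  band paths land on one shared time axis by construction;
* filter stability is asserted at design time (all poles strictly
  inside the unit circle).

## Dataset construction

Syllable events (onset, offset, pinyin, tone) cut the feature tensor
into segments padded with 100 ms of context on each side; context
missing at a session boundary is filled by edge replication (zeros
would be extreme values after z-scoring). The decoder consumes 200 ms
(40-sample) windows sliding sample by sample. With 20 pad samples per
side a segment of core length L yields L+1 stride-1 windows of length
40; to honor the contract that the decoded sequence has exactly the
length of the neural data, the last window is dropped — an off-by-one
forced by the even window length. Window *k* is then centered on core
sample *k*, which makes the "window target = label at the window
center" alignment an identity mapping (a right-edge alignment is also
implemented and config-exposed).

Train/test splits are **session-wise**: whole sessions are assigned to
one side, so no syllable (and no temporally adjacent data) is shared.
The printed train/test ratio in the source material is ambiguous, so
the train fraction defaults to 0.8 and is config-exposed. Channel order
is randomly permuted per repeat (seeded), implementing the stated
shuffling of electrode order fed to the decoder.

## The decoder

A stacked 3-layer bidirectional LSTM (100 hidden units per cell by
default) maps each 40-sample window to a score vector over the task's
categories, read out linearly from the concatenated forward/backward
hidden states at the window's center step. Training minimizes
**mean-squared error against one-hot targets** (per the stated
objective — not cross-entropy) with Adam (learning rate 0.001, beta1
0.9, beta2 0.999, epsilon 1e-8), 50% dropout, and early stopping when
validation loss stops decreasing; the best-validation checkpoint is
restored. Dropout is variational (one mask per unit and example,
shared across the 40 timesteps) on every layer's output. Validation
data are held out session-wise from the training sessions (10% of
sessions, at least one), mirroring the split discipline; patience
defaults to 5 epochs with an epoch cap of 100, both config-exposed
since they are not pinned by the protocol.

The network and full backpropagation-through-time are implemented in
RcppArmadillo (no deep-learning framework is used); gradients are
verified against finite differences to ~1e-10 relative error, and on
trivially separable synthetic data the decoder matches a multinomial
logistic oracle's predictions to ≥99%. Classification at the syllable
level takes a majority vote over per-timepoint argmaxes, with ties
broken by summed score. At inference dropout is disabled, so
prediction is a pure function of (weights, input).

## Evaluation designs

* `evaluateRegion()` — repeated seeded session-wise splits; per repeat
  it trains a fresh decoder on one region's channels (optionally
  restricted to single bands) and reports syllable-level test accuracy
  next to the exact chance level. Timepoint-level accuracy is logged
  as a secondary unit since the primary unit (the syllable) involves
  the majority-vote reduction.
* `evaluatePair()` — one channel from a cortical region plus one from
  a subcortical region, against the cortical channel alone under the
  *same* splits (paired design). The improvement ratio is
  `(pair − corticalAlone) / corticalAlone`. Channel selection
  defaults to `"best-val"`: one decoder per candidate channel is
  trained on training sessions only and the channel with the lowest
  best-checkpoint validation loss wins — validation loss stands in for
  validation accuracy because it is computed anyway, is monotonically
  related to fit quality under MSE, and touches no test data. The
  ranking may use a reduced epoch budget, but the selected channel's
  alone model and the pair model are always refit at the full budget so
  the improvement ratio is not biased by a weak baseline. `"random"`
  and `"all-pairs-mean"` policies are also provided.
* `bandComparison()` — per-band results under common splits, so band
  contrasts are paired.
* `chanceTest()` — exact two-sided binomial test of pooled correct
  counts against 1/K.

The cortical/subcortical designation follows the study convention:
ITG/MTG/STG are cortical; thalamus, insular gyrus, amygdala,
parahippocampal gyrus and hippocampus are treated as subcortical (the
parahippocampal gyrus is archicortex, but like the other deep
structures it is inaccessible to surface grids — the class labels are
data, not anatomy).

## The synthetic generator

Patient recordings are not redistributable, so every stage is exercised
on synthetic sEEG from `simulateRecordings()`:

* background: 1/f^a Gaussian noise (default exponent 1, amplitude
  20 µV sd) per channel, FFT-shaped, at 2000 Hz;
* sessions and events: several sessions (default 6 × 60 s) of
  syllables at 40/min with uniform 250–400 ms durations on a jittered
  non-overlapping grid, labels drawn iid from a configurable corpus
  (default: the full 21-initial × 4-tone inventory);
* class information: an event-locked **multiplicative gain on the
  band-passed background** under a Tukey window. Because the Hilbert
  envelope of `(1 + g·w(t)) · x_band` is exactly `(1 + g·w(t))`
  times the background envelope, a class with 0-based index k gets an
  envelope elevation of exactly `k · effectSize` baseline standard
  deviations at the window plateau. This makes the injected effect
  analytically controlled (and verifiable: `verifySpectrum()` recovers
  the spectral exponent and the standardized contrast), which an
  additive tone burst would not be, since envelopes do not add
  linearly. Class information deliberately rides on band *amplitude*:
  the pipeline's features are envelope/power-based, so phase coding
  would be invisible by design.
* regional structure: the default scenario places the effects the way
  the qualitative findings run — place → STG, manner → STG and
  thalamus, tone → thalamus, all in 70–150 Hz. Effects sharing a
  region occupy disjoint channel subsets (round-robin), emulating
  spatially segregated coding populations under different contacts of
  one electrode shaft; with shared channels the two multiplicative
  gains would act as mutual noise.

Two design points deserve emphasis:

* **Labels are iid, not balanced-without-replacement.** Cycling through
  a balanced pool would anticorrelate train and test class frequencies
  across a session-wise split, biasing a no-signal decoder *below*
  chance. Independent draws keep sessions exchangeable, so the null is
  centered at chance.
* **Task-balanced corpora for calibration.** Under the uniform
  21-initial corpus the marginal class frequencies are unequal (five
  initials are voiceless fricatives; one is a lateral), so a decoder
  that learns class priors can legitimately sit away from 1/K with
  zero signal. `taskBalancedCorpus(task)` repeats initials inversely
  to their class sizes so every category of one task is equiprobable —
  the design under which "chance = 1/K" is exact. The calibration and
  ordering studies in the test suite use these corpora; the package
  default remains the uniform inventory.

What the generator does **not** emulate: biophysical neural mass
dynamics, epileptiform activity, line noise, electrode drift,
cross-channel correlation structure, or any acoustic signal. Passing
tests therefore demonstrate that the machinery — labeling, signal
path, windowing, decoder, evaluation — recovers known injected
structure; they say nothing about decodability of real speech from
real brains.

## Scale choices in the tests

The shipped tests run on one CPU, so they use reduced problem sizes
chosen once as the package's desk scale: evaluation studies of 6
sessions × 36 s with 2 channels per region and a 10 s z-score window,
decoders with 8 hidden units, a training-window stride of 8, an epoch
cap of 22, and 20 split repeats per comparison; null-calibration
studies are smaller still (4 × 18 s, 1 channel per region, 6-unit
decoders). The null calibration checks each task × region cell's
pooled accuracy against a family-wise 95% binomial acceptance band
(Bonferroni-adjusted per cell): with 24 cells, testing each at an
unadjusted 95% would reject somewhere by construction. The
`scripts/acceptance.R` report uses the same designs with 12 repeats.

## Known limitations

* The package is an R library, not a shell tool: its users drive
  analyses from R, so the exported functions (plus
  `scripts/acceptance.R` for the end-to-end report) are the interface;
  no command-line subcommands are shipped.
* The decoder trains on CPU without minibatch parallelism; the
  full-scale protocol (100 hidden units, 1000 split repeats) is
  expressible but slow — the defaults are faithful, the tests scale
  down.
* Channel selection for pairs ranks by validation MSE, not validation
  accuracy; with very few validation syllables the ranking is noisy.
* The EDF writer quantizes to 16 bits over each channel's observed
  range, as the format requires; amplitudes are reconstructed to within
  one digital step.
* Accuracies on the uniform corpus mix class-prior information with
  signal; use the balanced corpora when comparing against 1/K.
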