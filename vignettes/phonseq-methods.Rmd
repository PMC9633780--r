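---
title: "Dynamic population codes for phoneme sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic population codes for phoneme sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phonseq)
```

## The problem this package models

Continuous speech delivers a phoneme roughly every 78 ms (SD 34 ms), while
the multichannel response evoked by each phoneme persists for about 300 ms.
At any instant the sensor array therefore superimposes the codes of roughly
three to four phonemes. Two families of solutions could keep those codes
apart: *position-specific* coding (a different topography per within-word
position) and *dynamic* coding (one position-invariant code whose
topography drifts lawfully with time since phoneme onset, so that content
and elapsed time — hence order — are jointly readable). `phonseq`
implements the analysis chain that distinguishes these hypotheses, along
with a synthetic generator that can plant either code.

## The annotation model

Each phoneme event carries 31 features. Binary features are coded ±1 and
continuous ones are z-scored within the annotated stream.

* **Phonetic (14)**: voicing; manner (fricative, nasal, plosive,
  approximant, vowel); place (central/low/mid/high vowel for vowels;
  coronal, glottal, labial, velar for consonants). Vowel place bits are
  structurally zero for consonants and vice versa.
* **Information-theoretic (3)**: with `C` the cohort of words consistent
  with the word-internal prefix heard so far and `f(w)` lexical frequency,
  the continuation probability is `P(p|C) = f(p) / Σ_{p'∈C} f(p')` with
  `f(p)` the summed frequency of cohort members continuing with `p`
  (this reading makes the continuation distribution sum to one);
  surprisal is `-log2 P(p|C)` — reported in bits, consistent with entropy
  — and cohort entropy is `-Σ_{w∈C} P(w|C) log2 P(w|C)`. Log sequence
  frequency is `log10` of the summed cohort frequency (base configurable;
  base-10 is the lexical-statistics convention). Cohorts restart at every
  word boundary; the empty prefix denotes the whole lexicon.
* **Boundary (8) and positional (6)**: word/syllable/morpheme onsets and
  offsets, sentence onset, and scaled positions within syllable, word and
  sentence. The exact split is configurable in principle; the default set
  totals 31 columns. Syllables come from a deliberately naive
  vowel-centred rule (each vowel is a nucleus; the single consonant before
  a nucleus joins its syllable) — adequate for the toy lexicon, replaceable
  by user-supplied columns for real corpora.

`lag_features()` appends the phonetic block of the `n` preceding phonemes
(`14·(n+1)` columns) for history decoding; missing history is padded with
0, the uninformative midpoint of the ±1 coding, rather than a fabricated
phantom phoneme.

## The synthetic generator

The generator is the package's test bed and defines its study conditions:

* **Streams**: words drawn by lexical frequency from a 40-word toy
  lexicon, phoneme durations from a truncated normal (mean 78 ms, SD
  34 ms, > 20 ms), word gaps uniform on [0, 20] ms and sentence gaps on
  [0, 1] s.
* **Codes**: each feature gets a random unit-norm channel pattern. A
  dynamic code drifts along a piecewise geodesic through random
  orthonormal directions at angular rate `2π·drift_rate` rad/s (a cascade
  of Givens rotations between successive waypoints), so the correlation
  between the onset pattern and the pattern at latency `t` falls as
  `cos(2π·drift_rate·t)` and is exactly zero beyond a quarter cycle. A
  training pattern is therefore informative over `1/(2·drift_rate)`
  seconds; the dynamic presets use `drift_rate = 6.25` (80 ms informative
  width, the regime where pattern lifetime matches the phoneme rate).
  `drift_rate = 0` gives the static control. Amplitude follows a
  half-cosine envelope over the 0–300 ms response window ("boxcar"
  available where a truly stationary pattern is required, e.g. the static
  control of latency decoding — a half-cosine static code still carries an
  amplitude cue to latency). An optional `"onset"` feature adds the
  generic evoked component every phoneme shares; without such a
  sign-consistent component, latency since onset is not linearly decodable
  from ±1-weighted patterns whose trial-mean is zero.
* **Superposition and noise**: responses of neighbouring phonemes add
  linearly; envelope/pitch confounds are injected through fixed random
  topographies with configurable gain; white sensor noise is scaled so
  `snr` is the signal-to-noise amplitude ratio (`0` = noise only, `Inf` =
  noise-free). The `"paper-like"` preset (`snr = 0.004`) was calibrated once so that
  single-feature AUC on the default 208-channel layout lands at ~51.5%,
  only a point or two above chance — the low-SNR regime the B2B method
  targets — while `"clean"` (`snr = 3`) recovers everything comfortably.
* **Audio branch**: a pseudo-spectrogram with a static code active only
  during each phoneme's acoustic extent, the stationary short-lived cue
  structure of a spectrogram; `mel_branch()` provides the real
  mel filterbank front end (2048-sample Hamming window, 128 samples shared
  between frames, 208 triangular filters on the mel scale from 1 Hz to
  11.25 kHz, resampled to 250 Hz).

What the generator does **not** emulate: realistic forward fields or
sensor cross-talk, 1/f noise spectra (an AR(1) flag is the only coloured
option), coarticulation between neighbouring phonemes, and listener-level
variability. Passing tests on this bed therefore demonstrate the
correctness and calibration of the estimators under their own model
assumptions, not performance on real recordings.

## Preprocessing

The TRF confound model predicts each channel from the preceding 200 ms of
envelope and pitch, both standardised, with ridge regularisation chosen
from ten log-spaced values in `[1e-6, 1e+6]` by mean predictive
correlation across channels over three contiguous folds. Residualisation
subtracts held-out predictions (fold k predicted by models fit on the
other folds), transformed back to original units; an in-sample mode (one
fit on all data) exists for diagnostics, where residuals are orthogonal to
predictions by construction. Epoching band-passes 0.1–50 Hz with a
zero-phase frequency-domain filter (raised-cosine transitions; robust for
sub-hertz cutoffs at arbitrary recording lengths), decimates 1000→250 Hz,
and cuts −200…600 ms windows (201 samples). No baseline correction is
applied anywhere, so slow shifts remain visible to the decoders rather
than being aliased into the baseline.

## Back-to-back decoding

Per timepoint and per random 50/50 split: decoders `G` (one per feature)
are fit on the training half with per-feature regularisation chosen from
20 log-spaced values in `[1e-5, 1e+5]` by closed-form leave-one-out CV;
channel standardisation always uses training-half statistics. On the held
half, each decoded feature is regressed on **all** true features (the
direction stated in the method's prose; the transposed variant is
available via `direction`), and `β_f = H_ff` is averaged over splits —
averaging is what stabilises coefficients of correlated regressors. The
noise ceiling `max_t Σ_f β_f(t)` turns betas into variance shares that sum
to one at the ceiling timepoint. Per-timepoint seeds are derived from the
master seed by counter, so any timepoint is reproducible in isolation and
results are independent of execution order or parallelisation.

The SVD-based ridge solver underlying all of this evaluates the whole
alpha grid from one decomposition and selects per-target alphas from
closed-form leave-one-out residuals — the same selection rule as the
reference RidgeCV implementations, without refitting.

## Temporal generalisation and its diagnostics

`tg_fit_eval()` trains at every latency and evaluates the encoder betas at
every other latency (the diagonal reproduces the timecourse analysis under
shared splits — an invariant in the test suite). Group-level inference
uses a one-sample t map across subjects with the conventional `t > 4`
contour (the Bonferroni-across-201-samples equivalent); single runs can
threshold on the score scale instead.

* `diag_vs_rows()` measures "how long information is present" (longest
  contiguous suprathreshold run on the diagonal) versus "how long one
  trained pattern stays informative" (mean of per-row longest runs). The
  accompanying statistic is a paired t across the train-time axis
  (df = 200 on the canonical 201-sample grid). Durations are longest runs,
  not suprathreshold counts, because a code can be noisily suprathreshold
  in scattered cells without being stably present.
* `align_to_word_clock()` shifts position `Pk` forward by `(k−1)·80` ms
  from word onset and `P−k` backwards from word offset.
  `overlap_fraction()` then reports the percentage of a position's
  suprathreshold cells shared with at least one temporally adjacent
  position — near 100% for middle positions of a static code, near zero
  for a dynamic code whose 80 ms bands tile the word clock without
  touching.
* `ridge_angle()` fits the first principal axis to the suprathreshold
  (test, train) cell coordinates; `atan2(|train component|, |test
  component|)` in degrees is 45° when test dynamics run at training speed,
  `atan(1/2) ≈ 26.6°` when twice as fast. Cells are equally weighted by
  default (a score-weighted variant exists); the angle is invariant to
  time-axis translation, and single-row/column regions are flagged
  degenerate rather than silently returning 0 or 90.
* `subset_compare()` trains on the full training split and evaluates per
  bin (duration quartiles, surprisal/entropy bins, word length), so bin
  differences reflect evaluation data only, never training-set size.
  Duration-scaled drift (the drift clock running in units of phoneme
  duration) reproduces longer generalisation for longer phonemes.

## Trajectories, latency, sequences

Unregularised (OLS) decoding coefficients — fit on all trials with no
cross-validation, since the goal is interpretable weights rather than
prediction — are RMS-combined across subjects, rectified (topography signs
are ambiguous after RMS), and projected against unit-norm binary
anterior/posterior and left/right masks. The structure metric `(m/s)·v`
(range over mean absolute step, times SD, averaged over the two axes) is 0
for constant trajectories, large for smooth far-ranging drifts, and is
tested against trajectories re-estimated under shuffled labels (default
100 shuffles, p floor 1/100). Structure is only detectable over the
response window; including signal-free epochs dilutes the path with
estimation jitter, so the analysis crops to the window where decoding is
present.

The latency decoder crops 100–400 ms, keeps 16 equally spaced samples (an
effective 53.3 Hz grid; one fewer sample is a plotting convention
elsewhere, the grid is configurable), collapses trials × latencies into
observations, standardises inputs and targets, and fits ridge (penalty 1,
the reference default) under shuffled 5-fold CV. On noise it predicts the
250 ms mean latency; on drifting codes the held-out Pearson r rises with
drift rate until pattern overlap between adjacent latency samples is
exhausted — the monotonicity test uses the rising part of that curve
(drift 0–2.5 cycles/s at SNR 0.4).

The anagram simulation enumerates the 24 orderings of {b, p, s, z},
synthesises 10 response streams per ordering by shifting each phoneme's
voicing/plosive coefficient template 100 ms per position and summing, with
a multiplicative Gaussian noise factor (mean 1, SD 0.1 by default; the
smallest assumption matching a "noise factor" on coefficients, with SD 0
for the ideal-conditions result). Sequence order is freshly shuffled per
stream, so far history is genuinely unpredictable rather than leaking
through a fixed presentation cycle. Ridge reconstruction (fixed small
penalty 1e-6, shuffled 5-fold CV) predicts the feature vector `lag−1`
phonemes back; lag 1 denotes the current phoneme, whose zero-noise
similarity is exactly 1 — the convention that anchors the lag axis.
Cosine similarity is computed once per lag over all concatenated epochs;
the permutation null shuffles phoneme labels (default 10,000, floor
1/n_perm).

## Group statistics

The sign-flip cluster test exploits that squares are flip-invariant: all
permuted t timecourses come from one matrix product, and the max-cluster
sum-t across time provides multiplicity correction. The cluster-forming
threshold defaults to the two-tailed p = 0.05 critical t at
`df = n_subjects − 1` (the convention of the reference implementation);
the statistic is max *sum* of t, not run length. Ties between the observed
cluster and its exact mirror flip are counted into the null tail
(numerically tolerant comparison), making small-n p values match
exhaustive enumeration. Empirical type-I error at 21 subjects × 201
timepoints sits in the low single digits of percent, within the accepted
[0.02, 0.09] band at nominal 0.05.

## Numerical and design choices

* Ridge solutions come from one SVD per design; `alpha = 0` falls back to
  the minimum-norm OLS solution with rank-deficient directions dropped.
* The regularisation grid readings (`1e-6…1e+6` for the TRF,
  `1e-5…1e+5` for B2B) are the only interpretations under which a
  log-spaced grid exists.
* The mel short-time transform takes "128-sample overlap" literally
  (hop = 2048 − 128); the alternative (hop = 128) costs 16× more frames
  for no analytical difference at the 250 Hz output rate.
* On-disk interchange is plain text throughout (TSV for tables, YAML for
  configs, JSON for cluster reports); epoch tensors live as in-memory
  arrays inside `epoch_set` objects.
* Desk-scale defaults: the orchestration layer (`run_pipeline()`) runs all
  stages on tens of words, 32 channels and a 50 Hz analysis grid — sizes
  chosen so a full run takes a couple of minutes — while every underlying
  function defaults to the canonical 250 Hz / 201-sample grid. The test
  suite follows the same philosophy: group-level TG fixtures use 6
  simulated subjects, 120 trials and 24 channels.
* `run_pipeline()`/`make_report()` are the orchestration interface; the
  package is a library, not a shell tool, so no command-line wrapper is
  shipped.

## Known limitations

* The toy lexicon has 40 words; cohort statistics are illustrative, not
  corpus-calibrated.
* The naive syllabifier and the sparse morphology annotations limit the
  boundary features' realism.
* The generator's linear superposition omits adaptation and co-articulatory
  interactions; static/dynamic dissociations shown here are therefore
  cleaner than real data would allow.
* Real-data effect sizes (variance shares, overlap percentages, latency
  correlations reported for ~50,000-phoneme recordings across 21
  listeners) are not reproduced at desk scale; the suite asserts the
  qualitative dissociations and the self-contained calibration anchors
  instead.
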