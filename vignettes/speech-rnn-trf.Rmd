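---
title: "From spoken-word recognition networks to neural encoding models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spoken-word recognition networks to neural encoding models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`wordtrf` implements, end to end on synthetic data, a computational chain that
links spoken-word recognition by recurrent networks to continuous neural
population responses:

1. a **lexicon generator** that produces phoneme-coded words with controlled
   cohort (onset-overlap) structure and multi-talker spectrogram tokens;
2. a **stream builder** that concatenates tokens and silence into continuous
   training input with time-aligned targets and calibrated noise;
3. **LSTM word recognizers** with three output-space codings and two loss
   functions, including a competition-friendly variant;
4. **lexical decoding**: word error rate, relative target activation, and
   onset-locked cohort-competition profiles;
5. a **linking hypothesis** that reduces hidden-unit activity to population
   predictors;
6. **multivariate temporal response function (mTRF)** estimation by boosting
   with validation-based kernel freezing, cross-validated variance explained,
   model comparison, and unique-variance attribution on simulated
   multi-subject responses.

Everything is seeded: one master seed derives every stage seed, and repeated
runs are bit-identical.

# The word recognition model

The recognizer is a stacked LSTM (standard variant: no peepholes, one bias
vector per gate set, forget-gate bias initialized to 1) that reads a 64-band
spectrogram frame by frame at 100 Hz and is trained to output, for the entire
duration of each word, a word-specific target vector — a zero vector during
silence. Each layer with input width $n_{in}$ and $h$ hidden units has
$4\,[(n_{in} + h)\,h + h]$ trainable parameters; `count_parameters()`
reproduces the depth-matched family used throughout (1×512, 2×320, 3×256,
4×192 units, all within a few percent of 1.2 M core parameters). This
parameter convention is the one under which those counts hold.

Three output codings are available: **localist** (one-hot; sigmoid head,
binary cross-entropy), **sparse random vectors** (10 active elements in a long
binary vector; sigmoid head), and **semantic** (dense unit-norm Gaussian
vectors standing in for corpus-derived embeddings; linear head, mean squared
error). The synthetic semantic space deliberately has no phonetic
organization, which is the property the analyses need.

## The competition-friendly loss

With binary targets $y_i$ and sigmoid outputs $\hat y_i$, the standard
per-frame loss is

$$L_{bce} = -\frac{1}{N}\sum_i^N y_i \log \hat y_i + (1 - y_i)\log(1 - \hat y_i).$$

Because wrongly activating a single non-target is penalized as much as the
target is rewarded, a recognizer has a strong incentive to commit to one word
as early as possible, suppressing cohort competitors. The modified loss
divides the non-target terms by a constant $c \ge 1$ on frames from word onset
until 100 ms before word end:

$$L_{lill} = -\frac{1}{N}\sum_i^N y_i \log \hat y_i + \frac{1}{c}(1 - y_i)\log(1 - \hat y_i),$$

with the standard weighting on the final 100 ms of each word (so the model
must still resolve the competition before the recognition point) and during
silence. At $c = 1$ the two losses are identical to numerical precision; the
gradient of the discounted terms is exactly $1/c$ times the standard gradient.
Words no longer than the 100 ms guard get no discounted frames. The loss is
averaged over output elements *and* frames (the per-frame form only fixes the
per-element average; averaging over frames makes batches of different lengths
comparable).

## Training procedure and its tunable parameters

Training streams mimic connected speech: pick a talker; emit a phrase whose
length is geometric with continuation probability 0.5 (mean 2 tokens); insert
silence drawn uniformly from 200–500 ms; after two phrases re-pick the talker.
Gaussian noise is added per frequency band at 20 dB SNR, defined on variances
(noise SD = signal SD × $10^{-\mathrm{SNR}/20}$, computed per band over the
whole stream; bands with zero variance get no noise, as the ratio is undefined
there). Streams are processed in consecutive segments with LSTM state carried
across segment boundaries, so the time axis is fully continuous and words may
straddle segments.

Parameters that matter, with defaults:

* `lr` (Adam learning rate): package default $10^{-3}$; the desk-scale
  analyses in `analysis/` use $5 \times 10^{-3}$, which converges in ~35
  epochs on the 50-word lexicon.
* `batch_size`, `segments_per_stream`, `segment_frames`: one epoch processes
  `batch_size` independent streams of `segments_per_stream` segments
  (`segment_frames` frames each, 10 s = 1000 by default). One optimizer update
  is taken per segment, so updates per epoch equal `segments_per_stream`; the
  desk-scale runs use 4 × 10 × 500 frames (20 s of speech × 4 streams per
  epoch).
* patience: when the epoch loss has not improved on its minimum for 20
  epochs, weights are restored to that minimum; after 200 evaluations without
  improvement training stops. Training loss (not held-out loss) is the
  monitored quantity. Optimizer moments are kept across a restore.
* gradient clipping at global norm 5; log clipping at $\varepsilon = 10^{-7}$.
* the sigmoid output bias is initialized at −4 (a low-activation prior), so
  early training is not spent learning the rare-positive base rate of
  multi-label targets. This is a pure initialization choice; it does not
  change what the trained model can express.

Fresh streams are generated every epoch from seeds derived from the master
training seed, so "epoch" means a fixed budget of newly sampled speech rather
than a fixed dataset pass.

# What the synthetic generators emulate — and what they do not

**Lexicon/tokens.** Phonemes are smooth random 64-band spectral templates
(2–3 Gaussian bumps plus a floor), 80 ms nominal duration; talkers differ by a
smooth template shift, a duration rate factor (0.85–1.2), and a token-jitter
scale; each token additionally receives smooth low-pass-filtered noise so that
token-specific acoustic details exist for a model to exploit. A fraction
`neighborhood_density` of words are single-phoneme edits of existing words,
which yields onset-sharing cohorts at several depths; homophones are discarded
and regenerated. Word lengths default to 3–7 phonemes, giving word durations
(~240–560 ms at the reference rate) comparable to natural spoken words.

This captures the *structural* properties the analyses depend on — onset
overlap, talker variability, token idiosyncrasy — and nothing phonetic:
there is no articulatory realism, no coarticulation across word boundaries,
no prosody, and the band spacing is arbitrary. Passing tests therefore show
that the pipeline's inferences are correct *given* a lexicon with cohort
structure; they cannot certify behavior on real speech.

**Responses.** Simulated multi-channel responses are linear convolutions of
predictors with smooth random kernels (1–2 Gaussian bumps with peaks confined
to 20–450 ms, well inside the −100…1000 ms estimation window) plus white
Gaussian noise at a requested SNR; subjects share a group-mean kernel plus a
smooth subject-level perturbation, and channels differ by gains (in-ROI gains
uniform on 0.5–1.5, out-of-ROI gains zero, noise only). Defaults are desk
scale: 10 subjects, 20 channels. Real MEG departures — correlated sensor
noise, nonlinearity, non-stationarity — are deliberately out of scope, so
recovery results bound estimator correctness, not real-data effect sizes.

# Linking hypothesis

Hidden units are pooled into groups — by layer, or by K-means over per-unit
activation time courses (z-scored per unit; constant units map to zero;
squared-Euclidean objective with 10 seeded restarts; layer labels are ignored
so deep models are clustered blind). Each group contributes two predictors:
the summed absolute activation (magnitude) and the half-wave-rectified
backward difference of absolute activation (change; first frame 0). Pooling
reflects how M/EEG signals physiologically average over populations, and
avoids the high-dimensional regression regime in which individual units can
resemble brain responses by chance. Predictors are resampled from 100 Hz to
the 50 Hz analysis rate by polyphase FIR decimation (`signal::decimate`); the
resampling method is a pipeline choice, not a claim about any particular
preprocessing chain.

# mTRF estimation by boosting

The encoding model is
$$\hat y_t = \sum_i^N \sum_\tau^T h_{i,\tau}\, x_{i,t-\tau},$$
with delays $\tau$ from −100 to 1000 ms (56 one-sample impulse-basis
coefficients at 50 Hz). Estimation is greedy coordinate descent: predictors
and response are mean-centered and scaled to unit variance on the training
segments; at each step the single element $h_{i,\tau}$ whose change by
$\pm\Delta$ (default $\Delta = 0.005$ in standardized units) most reduces the
training squared error is selected — ties broken by lowest predictor, then
lowest delay, then $+\Delta$, for determinism — and tested on the validation
segment: if validation error would increase, the change is reverted and
predictor $i$'s entire kernel is frozen. Fitting stops when all kernels are
frozen, no step strictly improves training error, or a step cap is reached.
The implementation maintains exact incremental cross-correlations (including
segment-edge corrections), and the test suite pins it step-for-step to a
brute-force reference that re-evaluates every candidate directly.

Cross-validation uses 4 contiguous segments: for each test segment the other 3
yield 3 fits (each serving once as validation), whose kernels are averaged to
predict the test segment; concatenated test predictions give
% variance explained $= 100\,(1 - SS_{resid}/SS_{total})$ per channel.
Channels are fit independently (mass-univariate), but share the predictor
cross-correlation tables, which is what makes the desk-scale fits fast. A
constant response yields a zero kernel by contract.

Model comparison reports the raw difference and
$100\,(ve_{full} - ve_{base})/ve_{base}$; channels with non-positive baseline
fit are flagged rather than divided by. Unique variance of a named predictor
part is $(ve_{full} - ve_{-part})/(ve_{full} - ve_{base})$.

# Group statistics

ROI-mean quantities are compared with paired t tests ($df = n - 1$;
zero-variance differences flagged as degenerate), and repeated-measures error
bars use the within-subject SE (per-subject offsets removed by centering each
subject's row on the grand mean). Full factorial repeated-measures ANOVA is
not implemented: at desk scale (defaults: 10 simulated subjects) planned
paired contrasts answer the questions the pipeline poses.

# Numerical choices and degenerate inputs

* Argmax ties in recognition go to the lowest word id (determinism).
* Relative target activation guards totals below $10^{-12}$ by emitting the
  uninformative prior $1/|lexicon|$; for semantic models (activations can be
  negative) a softmax transform is available.
* Recognition averages activation over the final min(10, duration) frames and
  is therefore invariant to positive affine — but not general monotone —
  transforms of the activations.
* Semantic lexical activation uses negative Euclidean distance by default
  (cosine switchable); output-mapping distances are Euclidean between the
  dense layer's per-word weight vectors.
* The 8-band baseline spectrogram averages adjacent groups of 8 of the 64
  bands and log-transforms as $\log(x + 10^{-3})$; the onset spectrogram is
  the per-band half-wave-rectified temporal difference of the log spectrogram
  — a simple, documented acoustic-edge stand-in that is config-swappable; the
  word-onset predictor is rebinned (not filtered) so impulses stay unit
  impulses.
* `sample`-scale pitfalls, RNG hygiene: every seeded helper saves and restores
  the caller's RNG state (`with_seed`), and stage seeds come from a
  multiplicative mixing function bounded below $2^{31}$.

# Design choices where the design was open

* **Token partition.** Per talker, ≈ a holdout fraction of word tokens go to
  test, with pinned tokens forced into training. Sampling is
  constraint-aware: a word is eligible for a talker's test set only while it
  keeps a training token elsewhere, so small lexicons cannot strand a word,
  and a fully pinned talker simply contributes no test tokens.
* **Epoch semantics.** One optimizer update per 10 s segment, loss evaluated
  per epoch; "no improvement for 200 evaluations" is interpreted at epoch
  granularity, consistent with the 20-epoch restore rule.
* **Boosting step.** $\Delta$ is defined in standardized units (data scaled to
  unit variance per training fold), making one default work across predictor
  scales; validation is checked after every accepted step.
* **Serialization.** Run-time containers use RDS with text manifests;
  lexicons and annotations use delimited text (annotations as a BED-like
  0-based half-open table).

# Problem sizes used in the shipped analyses

The `analysis/` drivers and the acceptance script run at desk scale, chosen so
a complete run takes minutes on one CPU: a 50-word, 4-talker lexicon with
neighborhood density 0.6; 64-unit localist recognizers trained 35 epochs
(4 streams × 10 × 5 s segments per epoch); 100 s stimulus streams for
predictors; 10 simulated subjects × 20 (recovery) or 4 (comparison) channels
at 10 dB SNR with $T = 10^4$ samples at 50 Hz. The same code scales to larger
lexicons and models by changing the configuration.

# Known limitations

* The recognizer is trained and evaluated on synthetic tokens; word error
  rates are not comparable to real-speech benchmarks.
* Boosting with an impulse basis yields sparse kernels; kernel-recovery
  correlations benefit from averaging the 12 cross-validation fits and would
  drop for very narrow true kernels near the delay-window edges.
* The improvement metric divides by the baseline's variance explained and is
  undefined when that baseline fails; flagged, not extrapolated.
* Stacked LSTMs allow no feedback from later to earlier layers; effects that
  depend on long-range top-down revision are outside the model family.
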