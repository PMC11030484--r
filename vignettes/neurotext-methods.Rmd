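---
title: "Decoding attempted speech from simulated intracortical activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attempted speech from simulated intracortical activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotext)
```

# Overview

`neurotext` implements a complete brain-to-text decoding pipeline on
simulated data: a generative model of multi-channel intracortical activity
during attempted speech, a frame-level phoneme classifier, a
lexicon-constrained beam search with n-gram language models, neural speech
onset/offset detection for self-paced conversation, decoder recalibration
against day-to-day nonstationarity, and the error-rate / bootstrap
methodology used to evaluate such systems. This vignette describes the
models, their assumptions, the parameters that matter, and the design
decisions behind them.

# The synthetic cortex

## Generative model

A recording session is a sequence of 80 ms feature frames over `n_channels`
channels (default 256, in four named 64-channel groups: `v6v`, `55b`, `4`,
`d6v` — labels for the implanted-array areas, with no anatomical claim).
Each frame carries one phoneme label from the 39-symbol ARPAbet alphabet
plus a silence token `SIL`. Given a tuning model with per-channel baseline
$b_c$ and gain matrix $g_{cp}$, a frame labelled $p$ with attempt amplitude
$a \in (0,1]$ is

$$x_{tc} = \max\!\big(0,\; b_c + a\, g_{c,p(t)} + \varepsilon_{tc}\big),
\qquad \varepsilon_{tc} \sim \mathcal N(0, \sigma^2).$$

Baselines are drawn uniformly on $[5, 15]$ (arbitrary rate units); gains are
standard normal scaled by the channel group's *informativeness* multiplier,
default $\{v6v{:}\,1,\ 55b{:}\,0.6,\ 4{:}\,0.5,\ d6v{:}\,0.2\}$, realizing
the empirical ordering of array informativeness for speech decoding. The
`SIL` column of the gain matrix is zero: silence is baseline activity. The
amplitude factor scales the tuning modulation only, never the baseline —
modelling quiet or non-vocalized attempts as attenuated modulation.

The noise scale defaults to $\sigma = 1.5$. This is the package's designed
operating point: with all 256 channels the frame classifier works close to
ceiling (copy-task word error rates of a few percent with half an hour of
training data), while any single 64-channel group in isolation is degraded
in proportion to its informativeness, so the ablation analysis has dynamic
range. The reduced 64-channel geometry used in the unit tests uses
$\sigma = 1$ for the same reason.

## Timing

Attempted speech has no acoustic record, so timing is modelled directly:
each phoneme occupies $1 + \mathrm{Geom}(1/m)$ frames with mean
$m = 4$ frames (320 ms), minimum one frame; `sil_frames = 3` silence frames
surround sentences and separate words. The 4-frame mean gives speaking
rates of a few tens of words per minute (about 45 with the short words of
the packaged 50-word vocabulary), matching self-paced attempted speech.
A `jitter_durations = FALSE` switch makes durations deterministic for exact
tests.

## Drift

Day-to-day nonstationarity is a per-channel random walk: multiplicative
log-gain steps ($\mathrm{sd} = 0.05$/day), additive baseline steps
($\mathrm{sd} = 0.2$/day), and a small per-day probability
($0.005$) that a channel drops out permanently (gain zero). Day 1 is always
the unperturbed tuning. The magnitudes are the package's own choice of
"moderate" drift — roughly a 20% gain dispersion, a 10%-of-noise baseline
shift per day, and ten percent channel loss over three weeks — chosen once
so that a frozen decoder degrades measurably over 21 days while daily
20-sentence recalibration recovers it. The log-gain ratios at day $d$ are
exactly $\mathcal N(0, (d-1)\,\mathrm{sd}^2)$, which the tests verify by
Kolmogorov–Smirnov.

## What the simulator does not model

Real intracortical features (threshold crossings, spike-band power) have
Poisson-like count statistics, correlated noise, within-day nonstationarity
and electrode-specific artifacts; phoneme tuning is context-dependent
(coarticulation) and speech timing autocorrelated. The simulator's Gaussian
noise, frame-independence, and context-free tuning are deliberate
simplifications: they preserve exactly the structure the pipeline's
contracts rely on (linearly separable frame classes, informativeness
ordering, silence = baseline, smooth drift), so green tests certify the
pipeline's machinery, not fidelity to any participant's recordings.
Headline accuracies reported from human intracortical studies are not
reproducible at desk scale and are not targeted.

# Lexicon and language models

Pronunciations are read from CMUdict-dialect text (stress digits stripped,
`WORD(2)` variants kept, case folded); a 50-word communication vocabulary
ships with the package, and a synthetic generator builds configurable-size
vocabularies of CV-patterned pseudo-words with rule-based pronunciations to
stand in for a large open vocabulary at desk scale (the 125,000-word regime
is represented by scaling, not replicated).

Language models are backoff n-grams (orders 1–3) with Witten–Bell
discounting by default:
$$P(w \mid h) = \frac{c(h,w)}{c(h) + T(h)} \ \ \text{if seen}, \qquad
\mathrm{bow}(h) = \frac{1 - \sum_{\text{seen}} P(w|h)}
                        {1 - \sum_{\text{seen}} P_{\text{lower}}(w|h')},$$
with an interpolated-to-uniform unigram so every event in
vocabulary ∪ {end, unknown} has positive probability; every context sums to
one within $10^{-9}$ (a property test). Unsmoothed maximum likelihood is
available (`smoothing = "none"`, unseen events floored at $10^{-99}$).
Witten–Bell was chosen because it is parameter-free and robust on the small
corpora used here; Kneser–Ney offers little at these sizes. Models
round-trip losslessly (to $10^{-6}$) through standard ARPA text. One
caveat found by property testing: adding a sentence to the corpus can
*decrease* that sentence's own likelihood under Witten–Bell (a new
continuation type raises $T(h)$), although pure MLE is provably monotone;
the test asserts the invariant under MLE.

# The phoneme decoder

Frames are z-scored per channel with statistics from their own session —
per-day normalization is the first line of defense against offset drift —
then stacked with ±2 context frames (edge-replicated) and classified by
multinomial logistic regression into the 40 classes. Training is full-batch
gradient descent with heavy-ball momentum and an automatic step-size
backoff (a step that increases the loss is undone and retried at half the
rate), which makes training deterministic given the seed and monotone in
loss; the objective is convex. Frame-wise supervision (labels from the
simulator) was chosen over CTC: it is the simplest contract that exercises
the full pipeline, and a sequence objective can be slotted in behind the
same interface. A small linear-softmax classifier suffices because the
generative classes are linearly separable by construction; on noiseless
data held-out frame accuracy exceeds 99%.

Recalibration (`fine_tune`) takes a new day's session, refits the
normalizer on the calibration sentences (default 20), and continues
gradient descent from the current weights for a few epochs. Pseudo-label
mode replaces ground-truth frame labels with labels obtained by decoding
each calibration sentence with the full sentence decoder and force-aligning
the decoded pronunciation back to the frames (best-path alignment) —
recalibration without ground truth. Zero-epoch fine-tuning returns the
input model unchanged.

# The sentence decoder

Decoding is time-synchronous Viterbi beam search over a pronunciation
prefix tree. A hypothesis occupies a tree node (or the silence state),
carries its word history and its combined score

$$\text{total} = \underbrace{\textstyle\sum_t \log
P(\text{phoneme}_t)}_{\text{acoustic}}
 + \alpha \cdot \log P_{\text{LM}}(\text{words}, \langle/s\rangle)
 + \beta \cdot \#\text{words},$$

and per frame may stay in its phoneme (self-loop), advance along the tree,
or — at a word-end node — emit the word (paying the weighted LM cost plus
the insertion bonus β) and either pass through optional inter-word silence
or begin the next word directly. Hypotheses are merged by (tree position,
word history) keeping the best alignment, and pruned to `beam_width`. Ties
are broken lexicographically by word sequence everywhere, which makes tests
exact. Silence is an optional between-word state, matching the simulator's
segmental frame labelling (explicit per-frame phoneme states with
self-loops, not CTC blank semantics). An exhaustive oracle
(`exhaustive_decode`) enumerates all word sequences up to a length cap,
force-aligns each by dynamic programming, and provably equals the beam
search when the beam saturates — the central correctness test. N-best lists
can be re-ranked by a second, higher-order language model
(`rescore_nbest`, stable on ties), mirroring the cascade of an in-beam
n-gram plus rescoring models.

One caveat surfaced by property testing: the best score is *not* strictly
non-decreasing in `beam_width` — pruned hypothesis sets are not nested
across widths, so rare inversions at very small beams are inherent to beam
pruning. The saturating beam does dominate every narrower run (it attains
the exhaustive optimum), and adjacent-width monotonicity holds in the large
majority of steps; the tests assert exactly that.

# Conversation mode

Self-paced use requires detecting speech from neural activity alone.
Because attempted speech modulates channels in both directions around
baseline, raw rates are not linearly separable; the detector therefore uses
deviation *energy*: per frame, the squared normalized deviation averaged
over channels with non-negative weights learned from the speech/silence
contrast, smoothed by a 5-frame (400 ms) causal moving average, and mapped
to a probability through a logistic link on its z-score relative to
silence ($z = 4$ at $p = 0.5$, so the default onset threshold 0.8 sits
about 5.4 silence standard deviations above the silence mean). Two
estimation details matter and were found the hard way:

* **Cross-fitting.** The contrast weights and the silence mean/sd are
  estimated on disjoint frame halves. Estimating both on the same frames
  biases the silence baseline low (weight selection favors channels whose
  training silence was coincidentally quiet), which inflates false
  detections on genuinely silent streams.
* **Window purity.** Short inter-word gaps always contain speech inside a
  smoothing window; any calibration fit on such frames learns that
  "silence" carries speech-level energy. Anchoring the calibration to
  silence statistics (rather than a discriminative fit over all frames)
  avoids this.

Segmentation is a hysteresis state machine: onset when the smoothed
probability reaches θ\_on (default 0.8), offset candidate below θ\_off
(default 0.4), and finalization after 75 consecutive sub-threshold frames —
exactly 6 s of speech inactivity at the 80 ms frame rate. A still-open
segment at stream end is finalized as if by the user's manual button. The
causal smoothing delays onsets by a few frames, so decoded segments are
padded by 8 frames of context on both sides. Simulated conversations mark
a sentence "correct" iff the decoded text equals the reference, with a
configurable no-report probability, enabling confirmed-fraction reporting
with no-report sentences excluded from the self-report breakdown.

# Evaluation methodology

Phoneme and word error rates are minimal edit distances (insertions,
deletions, substitutions at unit cost) divided by the reference length,
pooled over sentences before dividing (micro-average); rates above one are
possible and preserved, and a zero-length reference yields an explicit
undefined marker rather than 0 or ∞. The alignment backtrace uses a fixed
tie order (match, substitution, deletion, insertion). The implementation is
verified exhaustively against the C edit distance on all 1.19 million
ordered pairs of sequences up to length 6 over a 3-symbol alphabet and
against a recursive reference on random longer pairs.

Confidence intervals are percentile bootstrap over sentences: resample
sentences with replacement, recompute the pooled rate, take the empirical
quantiles; 10,000 resamples and 95% intervals by default, deterministic
given the seed. Percentile (not BCa) is the simplest method consistent
with sentence-level resampling; a Monte-Carlo study in the tests confirms
92–98% empirical coverage of a known 5% per-word error probability. No
multiplicity adjustment is applied anywhere, deliberately.

Substitution structure is summarized in a phoneme confusion matrix with an
articulatory ratio: the probability that a substituted pair shares manner
or place of articulation, divided by the chance level under independent
marginal shuffling. Word-level accuracy is related to training-data
frequency by Spearman rank correlation, with novel words in the zero-count
bin. Channel-group ablation retrains the decoder on each 64-channel group
alone and reports per-group word error rates, recovering the simulated
informativeness ordering. Conversation reports flag, but do not correct,
the selection effect of restricting to sentences with known ground truth.

# Study harnesses and problem sizes

Three end-to-end studies reproduce the experimental designs at desk scale,
fully deterministic from a master seed (child seeds come from a Lehmer
stream, and every stochastic function takes an explicit seed):

* **Copy task** (`run_copy_task_study`): 290 training sentences (about 30
  minutes of simulated attempted speech), 40 evaluation sentences from the
  50-word vocabulary; bigram in-beam LM and trigram rescoring trained on a
  600-sentence text corpus; evaluation word error rates run a few percent.
  A Zipf exponent of 0.6 in the corpus generator gives the word-frequency
  analysis its dynamic range. The zero-noise variant decodes perfectly.
* **Stability** (`run_stability_study`): 21 drifting days, 10 seeds; day 1
  trains the decoder (60 sentences), later days provide 20
  calibration sentences each. Three strategies are compared — frozen after
  day 1, pooled over the first days then frozen, and recalibrated daily —
  with word error rate evaluated on checkpoint days. Uniform word
  frequencies isolate the drift effect. The frozen decoder's error rate
  roughly doubles or worse by day 21 while daily recalibration holds it
  near the day-1 level.
* **Conversation** (`run_conversation_study`): a continuous stream of
  sentences separated by 85–140-frame pauses (always beyond the 75-frame
  timeout), detector-segmented, decoded, and self-reported; plus an hour of
  pure silence for the false-detection rate (< 2 events/hour at the default
  thresholds, typically 0).

These sizes were chosen as the smallest that make the qualitative
phenomena (near-ceiling small-vocabulary decoding, drift-induced
degradation, recalibration recovery, informativeness ordering) statistically
stable across seeds.

# Numerical choices and degenerate inputs

Log-probabilities are natural logs internally; ARPA files use log10 with
7 decimals (round-trip error below $10^{-6}$). Softmax rows are normalized
by log-sum-exp with max-subtraction. The unsmoothed-LM floor is the ARPA
convention $10^{-99}$. Normalizer standard deviations are floored at
$10^{-8}$ with a warning for constant channels. Empty frame matrices
decode to the empty result with score zero; a beam from which no
completable hypothesis survives falls back to the empty sequence scored on
the all-silence path. `exhaustive_decode` guards its enumeration at
$|V|^{\text{max\_words}} \le 10^5$.

# Known limitations

* The simulator's independence assumptions make frame classification easier
  than on real neural data at matched signal-to-noise ratios; absolute
  error rates here say nothing about any real participant.
* The detector's onset latency (a few frames, from causal smoothing) is
  compensated by segment padding rather than modelled; at desk scale the
  detected-versus-oracle segmentation WER gap is a few points, dominated by
  boundary frames of short sentences.
* Sessions are persisted in a documented plain-text container (JSON header
  plus TSV matrices) and decoder models as JSON; both are small at desk
  scale, and the formats favor portability and inspectability over
  compactness.
* Homophones are resolved only by the language model; with a uniform LM the
  lexicographically first spelling wins by the tie-break contract.
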