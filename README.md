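# neurotext

Brain-to-text speech neuroprostheses decode the cortical activity of
attempted speech into text: every 80 ms, multi-electrode intracortical
recordings are classified into the most likely English phoneme, and a
lexicon-constrained search with n-gram language models assembles phoneme
probabilities into sentences. `neurotext` implements that pipeline
end-to-end in R on **simulated** neural data, for researchers and students
who want to study, test, and extend the decoding machinery itself — the
classifier, the search, the onset detection, the recalibration strategy,
the statistics — without access to (or before committing to) human
recordings.

The package provides:

* **A synthetic cortex** — 256-channel binned rate features in four named
  64-channel groups with phoneme-tuned gains, attempt-amplitude scaling,
  silence structure, and day-to-day drift (gain random walk, baseline
  offsets, channel dropout).
* **A frame-level phoneme decoder** — multinomial logistic regression on
  context-stacked, per-session-normalized frames, with supervised and
  pseudo-label fine-tuning for rapid recalibration from 20 sentences.
* **A sentence decoder** — time-synchronous Viterbi beam search over a
  pronunciation prefix tree with an in-beam n-gram LM, n-best rescoring by
  a higher-order LM, and a provably equivalent exhaustive oracle. Scores
  are log-linear: acoustic + α·LM + β·words.
* **Conversation mode** — an energy-based neural speech detector with a
  hysteresis state machine that finalizes a sentence after 6 s (75 frames)
  of inactivity, plus false-detection-rate measurement.
* **Evaluation** — phoneme/word error rates from unit-cost edit-distance
  alignment, micro-averaged over sentences, with 10,000-resample
  percentile-bootstrap confidence intervals; confusion matrices with an
  articulatory-similarity ratio; word-frequency effects; channel-group
  ablation.
* **Study harnesses** — copy-task, 21-day stability, and conversation
  studies, deterministic from one master seed.

Readers and writers for CMUdict-dialect lexicons and ARPA-format language
models are included, along with a packaged 50-word communication
vocabulary.

## A worked example

Simulate a day of prompted-sentence (copy task) use with the 50-word
vocabulary, train the decoder, and decode held-out sentences:

```r
library(neurotext)

cfg <- study_config(master_seed = 7L, sentences_per_day = 60L,
                    n_eval_sentences = 10L,
                    training = training_config(epochs = 30L),
                    beam = beam_config(beam_width = 16L))
study <- run_copy_task_study(cfg)
print(study$report)
#> Session: 10 sentences, 57 words; WER 3.51% [0.00%, 9.62%]
#>   raw PER 13.48% [8.67%, 19.26%]
#>   48.6 words per minute

head(study$results[, c("reference", "hypothesis")], 3)
#>                           reference                        hypothesis
#> 1 not you faith are hungry yes that not you faith are hungry yes that
#> 2         music have computer are i         music have computer are i
#> 3                   hope what bring                   hope tell bring
```

The report gives the session's micro-averaged word error rate (3.51%: two
word errors among 57 reference words, pooled before dividing) with a 95%
percentile-bootstrap confidence interval over sentences, the *raw* phoneme
error rate of the frame classifier alone (13.48% — before the language
model fixes most of it), and the speaking rate implied by the simulated
frame spans. The third sentence shows a typical residual error: a
substitution between two short words. `study$word_frequency` relates
per-word accuracy to training-data frequency (Spearman ρ = −0.30 here:
frequent words err less).

The pieces compose à la carte: `build_tuning()` / `synthesize_session()`
for data, `train_decoder()` / `decode_frames()` for phoneme probabilities,
`beam_search()` / `rescore_nbest()` for sentences, `fine_tune()` for
recalibration, `train_detector()` / `detect_segments()` for conversation
mode, and `align_sequences()` / `error_rate()` / `bootstrap_ci()` /
`session_report()` for measurement. A thin command-line front end lives in
`inst/cli/neurotext.R` (`study-copy`, `study-stability`,
`study-conversation`, `simulate`).

## Scope

All neural data are synthetic. The generative model preserves the
structure the pipeline assumes (phoneme-tuned channels, informativeness
ordering across arrays, silence as baseline, smooth multi-day drift) but
deliberately simplifies real intracortical statistics; results on it
validate the machinery, not clinical performance. See the methods vignette
(`vignettes/neurotext-methods.Rmd`) for models, assumptions, parameter
choices, and known limitations.
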