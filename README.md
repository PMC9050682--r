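# attnmvpa

Time-resolved EEG decoding of feature-based attention, as a fully
simulatable R pipeline.

## The problem

When two stimuli occupy the same location at the same time — here, overlaid
blue and orange line gratings — selective attention determines which one the
brain prioritises. Multivariate pattern analysis (MVPA) of EEG can track
this prioritisation millisecond by millisecond: a classifier is trained to
decode the orientation shown in the attended colour (the *cued* orientation)
and, separately, the orientation shown in the ignored colour (*uncued*),
at every timepoint of the peristimulus epoch. The scientific questions are
*when* the attended and ignored features are coded equally, *when*
preferential coding of the attended feature emerges, and whether temporal
expectation (predictable vs jittered stimulus onsets) changes any of this.

`attnmvpa` implements the complete analysis chain for rapid-serial designs
of this kind, together with a synthetic-EEG generator with a known
ground-truth attention effect, so that the whole pipeline can be validated
by parameter recovery without any data download. It is aimed at
cognitive-neuroscience methodologists who want a tested, reproducible
reference implementation of:

- **Design generation** — 64 counterbalanced sequences of 104 analysable
  presentations each (plus targets, foils and padding), stimulus types built
  from orientations {22.5°, 67.5°, 112.5°, 157.5°} with the two colours
  always 45° apart, and constant (200 ms) or varied (100–300 ms, 60 Hz frame
  grid) inter-stimulus intervals.
- **Synthetic EEG** — orientation-selective evoked responses (unit-norm
  spatial patterns, raised-cosine temporal kernel on 80–400 ms) superposed
  linearly across overlapping presentations at 1000 Hz, an attention gain
  that diverges at a configurable latency τ (default 230 ms), and
  spatially/temporally correlated noise (rank-8 factor covariance, AR(1)).
- **Preprocessing** — zero-phase Hamming-windowed FIR band-pass 0.1–100 Hz,
  average re-reference, anti-aliased downsampling to 250 Hz, epoching from
  −100 to 800 ms.
- **Decoding** — per-timepoint regularised LDA
  (`S_r = S + 0.01·mean(diag(S))·I`) under leave-one-sequence-out
  cross-validation, within two orthogonal analysis groups
  (22.5° vs 112.5° and 67.5° vs 157.5°) whose pair-averaging yields a 50%
  chance level and guarantees the non-decoded colour's orientation is
  uninformative.
- **Group inference** — per-timepoint Bayes factors from one-sample t
  statistics under an interval-null Cauchy prior (scale 0.707, effect sizes
  |d| < 0.5 excluded; half-Cauchy for directional contrasts, whole Cauchy
  for the attention × expectation interaction), percentile bootstrap CIs
  (10,000 samples), and onset latencies defined as the second consecutive
  timepoint with BF₁₀ > 10.

## Worked example

```r
library(attnmvpa)

# a small simulated group: 6 participants x 8 sequences, 32 channels,
# ground-truth attention gain divergence at tau = 230 ms
cfg <- run_config(seed = 17, n_participants = 6, n_sequences = 8,
                  n_channels = 32, isi_filters = "all")
res <- run_pipeline(cfg, contrasts = c("cued_vs_chance", "uncued_vs_chance",
                                       "attention_effect"))
res$onsets
#> $cued_vs_chance
#> [1] 124
#>
#> $uncued_vs_chance
#> [1] 132
#>
#> $attention_effect
#> [1] 236
```

Reading: the cued and uncued orientations become decodable at ~120–130 ms
(both well before τ — the early coding is equal), and sustained strong
evidence for *stronger* coding of the cued orientation emerges at 236 ms,
recovering the simulated 230 ms divergence. At the full study size
(20 participants × 16 sequences) the recovered onset is 232 ms. Each
`bf_timecourse` has `autoplot()`, `tidy()` and `glance()` methods;
`glance()` reports the onset, peak evidence and prior settings in one row.

Lower-level entry points mirror the analysis stages:
`generate_session()`, `simulate_recording()`, `preprocess_recording()`,
`decode_task()`, `run_all_conditions()`, `bf_timecourse()`, `onset_time()`,
`bootstrap_ci()`. Designs round-trip through BIDS-style events TSVs via
`write_events_tsv()` / `read_events_tsv()`.

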