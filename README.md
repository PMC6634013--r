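# afrr

Atrial fibrillation (AF) detection from RR-interval heterogeneity.

Consumer chest-strap heart-rate monitors stream beat-to-beat RR
intervals in milliseconds. The ventricular response in AF is
*irregularly irregular* — RR intervals are both highly variable and
serially unpredictable — and that signature alone, without any ECG
waveform, supports automated AF screening over long monitoring
periods. `afrr` is a complete implementation of such a detector, for
researchers developing or validating RR-only arrhythmia monitors:

* **Per-beat classifier** — from the trailing window of `window_n`
  (default 32) prior intervals, each beat gets a heterogeneity index

  `index = w_v · v + w_r · rn ∈ [0, 1]`,

  where `v` is normalized RMSSD saturated to [0,1] and `rn` is the
  first-order entropy rate of the ternary delta-RR symbolization
  (decrease / steady / increase about a ±δ band). Two thresholds cut
  the index into three classes: **probable AF** (red), **normal
  rhythm** (blue), and **unclassified non-AF arrhythmia** (yellow).
  Regularly irregular rhythms such as atrial flutter with patterned AV
  conduction have entropy rate exactly 0 and cannot reach the AF
  class, however variable their RR stream.
* **Recording-level decision** — AF burden is the fraction of
  classified duration labeled probable AF; a recording is called AF
  when burden ≥ 90% (inclusive).
* **Simulators** — seeded generators for sinus rhythm (respiratory
  modulation), AF (i.i.d. Gamma intervals), atrial flutter (fixed or
  patterned conduction), ectopic beats and sensor artifacts, plus
  `simulate_study()`, which emulates a paired pre/post-cardioversion
  validation cohort (95 patients, 190 ten-minute recordings) with
  exact, deterministic design counts.
* **Evaluation** — contingency tables against a reference diagnosis,
  sensitivity/specificity under explicit flutter handling (excluded or
  as-negative), Cohen's kappa, exact (Clopper–Pearson) and Wilson
  binomial confidence intervals.

## Worked example

```r
library(afrr)

af   <- simulate_af(duration_s = 600, seed = 42)   # 10 min of synthetic AF
labs <- classify_stream(af)                        # one label per beat
table(labs$label)
#> probable_af      warmup
#>         972          31
aggregate_recording(labs)
#> <recording_decision: AF, AF burden 1.000 (threshold 0.90, duration-weighted)>
#>   classified 581.3 s, warm-up 18.9 s, 1003 beats
```

All 972 classified beats of the AF series exceed the AF cutoff, the
burden is 1.0 ≥ 0.90, and the recording is called AF. The first 31
beats are the classifier's warm-up (the window is 32 beats) and are
excluded from the burden.

Evaluating a validation study from its published contingency counts
(truth in rows: AF 96/3, flutter 0/8, sinus 4/79 against the app's
binary call):

```r
tbl <- contingency_from_counts(af = c(96, 3), flutter = c(0, 8), sr = c(4, 79))
diagnostic_metrics(tbl)
#> <diagnostic_metrics: 190 pairs>
#>   sensitivity: 97.0%   (flutter excluded and as-negative agree)
#>   specificity: 95.2% flutter-excluded / 95.6% flutter-as-negative
#>   kappa: 0.926 (as_negative)
#>   AF prevalence (flutter excluded): 54.4%
```

`tidy()` and `glance()` methods return these as tibbles, and
`autoplot()` methods draw the labeled RR stream (the familiar colored
dot plot of RR against time), contingency tables, and metric estimates
with their CIs.

A command-line front end is installed at `exec/afrr` with subcommands
`simulate`, `simulate-study`, `classify`, `evaluate`, and
`metrics-from-table`; logs go to stderr, results to files/stdout, and
every JSON result embeds the resolved parameter set.

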