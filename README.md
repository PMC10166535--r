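# drowsival

Convergent-validity analysis of video-based **observer rating of drowsiness
(ORD)** against the other accepted driver-drowsiness measures, for
within-subject simulated-driving designs.

Driver-monitoring research leans on ORD — trained raters scoring a driver's
face video on a D1–D5 (+S) scale — as its ground truth. Whether that is
justified is an empirical question: ORD should co-vary, within drivers, with
self-reported sleepiness (KSS), lane keeping (SDLP), eye closure (PERCLOS),
slow eye movements from EOG (%SEM), and EEG alpha/theta power. `drowsival`
implements the whole chain needed to ask that question:

* **Measure extraction** from raw channels, per five-minute trial:
  * %SEM — EOG calibrated to visual angle (least-squares slope against
    target angles `atan(offset/distance)`), 15-Hz zero-phase low-pass, and a
    two-criterion detector (speed < 30°/s, net displacement > 5°);
  * EEG alpha (8–12 Hz) and theta (4–7.9 Hz) power — 0.53-Hz/30-Hz
    zero-phase filtering, artifact-screened 15-s segments, Welch PSD
    (2-s Hann, 50% overlap), exact-bandwidth integration;
  * PERCLOS — pupil diameter ≤ 20% of a modal baseline maximum for > 400 ms,
    with an explicit tracking-loss policy;
  * SDLP — sample standard deviation of lateral lane position;
  * ORD — D1–D5/S labels to points, grand mean over three raters × 60
    segments, pairwise concordance gate ≥ 0.7.
* **The statistical battery** as an S3 model fit, `ord_validity()`:
  per-participant Pearson correlations across trials for all 21 measure
  pairs, Fisher z = atanh(r), one-sample t-tests with 95% CIs across
  participants, one-way repeated-measures ANOVA per measure over the
  24-level trial factor (df (23, 368) at the 17 × 8 × 3 design), and
  per-trial time-course summaries — with `print`, `summary`, `coef` and
  `plot` methods.
* **A synthetic cohort generator** in which one latent drowsiness process
  (intercept + session build-up with a lunch-break reset + within-session
  drift + AR(1) noise) jointly drives all seven measures through a logistic
  link, at the study's native sampling rates (1-kHz EOG/EEG, 60-Hz pupil,
  10-Hz lane position). It makes the whole pipeline testable without any
  human data.

## Worked example

```r
library(drowsival)

tab <- extract_cohort(sim_config(), seed = 1)   # ~4 min: 408 trials of waveforms
fit <- ord_validity(tab, kss_filter = FALSE)
summary(fit)
```

which prints (abridged):

```
Convergent-validity summary (17 participants, 408 trial rows)

Pairwise mean Fisher z:
 pair                              mean_z ci           t     df p        sig
 ord_mean ~ kss                    1.17   (1.06, 1.27) 23.60 16 7.36e-14 ***
 ord_mean ~ sdlp_cm                0.76   (0.64, 0.88) 13.18 16 5.21e-10 ***
 ord_mean ~ perclos_pct            0.78   (0.67, 0.89) 14.98 16 7.79e-11 ***
 ...
 Trial effect (one-way repeated-measures ANOVA):
 measure         F      df        p      sig
 kss              35.40 (23, 368) <2e-16 ***
 sdlp_cm          11.51 (23, 368) <2e-16 ***
 ...
```

Every row answers one validity question: `mean_z` is the average
Fisher-transformed within-participant correlation between the two measures
(positive = the measures rise and fall together within drivers), the CI and
t/p test it against zero across the 17 participants, and the ANOVA block
confirms each measure actually changed over the 24 trials of the day. On
synthetic cohorts with the default coupling, all 21 pairs are positive and
significant — the structural analogue of the convergent-validity finding —
and with coupling gains set to zero the battery flags only ~5% of pairs.

Individual stages are exported too: `calibrate_eog()`, `eog_to_angle()`,
`detect_sem()`, `percent_sem()`, `preprocess_eeg()`, `segment_trial_eeg()`,
`trial_bandpower()`, `baseline_pupil_max()`, `perclos()`, `sdlp()`,
`labels_to_points()`, `trial_ord_score()`, `concordance_rate()`,
`slice_trials()`, `assemble_measure_table()`,
`filter_participants_by_kss_range()`, plus text readers/writers for trial
tables (`read_trial_table()` accepts spreadsheet-style column labels),
channels and rater label files.

See the vignette
(`vignettes/validating-observer-rated-drowsiness.Rmd`) for the model, every
tunable constant, and the design decisions.

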