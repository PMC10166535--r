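---
title: "Validating observer-rated driver drowsiness against physiological and behavioural measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating observer-rated driver drowsiness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsival)
```

## The problem

Observer rating of drowsiness (ORD) — trained raters watching a driver's
face video and scoring drowsiness on a discrete scale — is the de-facto
ground truth in much of the driver-monitoring literature. Its *convergent
validity* rests on whether ORD co-varies with the other accepted drowsiness
measures: self-reported sleepiness (the 9-level Karolinska sleepiness scale,
KSS), lane-keeping performance (the standard deviation of lateral position,
SDLP), eye closure (PERCLOS), slow eye movements from the
electrooculogram (%SEM), and EEG alpha and theta band power.

`drowsival` implements that validation end to end for a within-subject
simulated-driving design: each participant performs eight sessions (three
before and five after a lunch break) of three five-minute driving trials,
each trial ending at a KSS voice prompt, giving 24 trials per participant.
The package covers three layers:

1. **extraction** — per-trial computation of the seven measures from the raw
   channels (1-kHz horizontal EOG and C3 EEG, 60-Hz pupil diameter, 10-Hz
   lateral lane position, per-rater 5-s ORD labels, KSS responses);
2. **statistics** — the convergent-validity battery around `ord_validity()`;
3. **synthesis** — a latent-state cohort generator, so the full pipeline is
   testable without access to human recordings.

## The statistical model

For a participant $i$ and an unordered pair of measures $(a, b)$, Pearson's
$r_{i}^{(a,b)}$ is computed across that participant's 24 trials. Each
correlation is Fisher-transformed, $z = \operatorname{atanh}(r)$, and the
per-participant $z$ values are tested against zero with a one-sample
$t$-test:

$$ t = \frac{\bar z}{s_z / \sqrt{n}}, \qquad \mathrm{df} = n - 1, $$

with the matching 95% interval $\bar z \pm t_{0.975,\,n-1}\, s_z/\sqrt n$.
Seven measures give $\binom{7}{2} = 21$ pairs. Convergent validity of ORD is
supported when the ORD rows (and, more broadly, all pairs) show positive
mean $z$ at $p < 0.05$. No multiplicity adjustment is applied, matching the
unadjusted design this replicates; a Bonferroni flag would be a one-line
extension for users who want it.

Whether drowsiness changed at all over the day is checked per measure with a
one-way repeated-measures ANOVA over the 24-level trial factor:
$SS_\text{total} = SS_\text{subject} + SS_\text{trial} + SS_\text{error}$,
$F = MS_\text{trial}/MS_\text{error}$ with df $(T-1,\,(T-1)(n-1))$ — for 17
participants and 24 trials, $(23, 368)$. No sphericity correction is
applied, deliberately matching the uncorrected degrees of freedom of the
design being emulated.

## Measure definitions and the constants that matter

All extraction constants live in `analysis_config()` and default to the
study protocol values:

* **ORD** — three raters label every 5-s video segment D1–D5 (1–5 points; a
  separate "sleeping" label S also counts 5). The trial score is the grand
  mean over raters and segments. Rater qualification demands a pairwise
  concordance rate ≥ 0.7; since the originating regulation's concordance
  formula is not public in detail, we implement it as the fraction of
  segments agreeing within ±1 level, with the tolerance exposed (0 = exact
  agreement) so the plausible readings are all available.
* **%SEM** — the EOG is converted to visual angle using a per-participant
  calibration constant (least-squares slope of median voltage against target
  angle $\theta = \arctan(\text{offset}/\text{distance})$; the pre-session-1
  block applies to sessions 1–3 and the pre-session-4 block to sessions
  4–8), low-passed at 15 Hz with a zero-phase 4th-order Butterworth. A slow
  eye movement is a velocity run below 30°/s whose net displacement exceeds
  5°. Velocity is a 50-ms-smoothed first difference, and runs are split
  where the velocity sign reverses for more than 100 ms. We use *net
  endpoint displacement* rather than path length because the path length of
  a megasample noisy trace grows without bound under measurement noise,
  while net displacement captures the physiological notion of a slow drift;
  a `sem_distance_mode = "path"` switch preserves the alternative reading.
* **PERCLOS** — the baseline "maximum" pupil diameter is the mode (0.1-mm
  bins, ties to the larger diameter) over an alert reference window; a
  sample is closed when diameter ≤ 20% of baseline, and closed runs longer
  than 400 ms count. Tracking loss contiguous with sub-threshold samples is
  treated as closed (closure is itself the usual cause of loss); isolated
  dropouts under 100 ms are bridged linearly; longer unexplained dropouts
  are removed from the denominator rather than guessed.
* **EEG band power** — first-order high-pass with a 0.3-s time constant
  (≈0.53 Hz), 30-Hz low-pass, zero phase; trials tile into 15-s segments and
  segments with any sample above 100 µV are discarded as artifacts. A trial
  with zero clean segments yields a *missing* power, never zero, since a
  zero would bias correlations. Welch PSD uses 2-s Hann windows with 50%
  overlap (0.5-Hz resolution, ≥9 averages per segment). Band integration
  treats the PSD as piecewise constant and integrates over exactly
  [4, 7.9] Hz (theta) and [8, 12] Hz (alpha), with fractional edge bins:
  this keeps adjacent bands additive and makes a flat spectrum integrate in
  proportion to exact bandwidth.
* **SDLP** — the sample (n−1) standard deviation of lateral position over
  the full trial window; with ~3000 samples per trial the denominator choice
  is immaterial. No lane-departure clipping is applied.
* **KSS** — the verbal 1–9 response at the prompt ending each trial.

Participant selection mirrors the study rule: a participant enters the
analysis only if they gave at least three KSS responses ≥ 8 *and* at least
three ≤ 7 ("greater than two" read strictly); `kss_min_count` makes the
threshold configurable.

## The synthetic cohort

The generator (`sim_config()`, `simulate_latent()`, `simulate_recording()`,
`simulate_raters()`) is a stand-in for human data, not a biophysical model.
Its single structural commitment is the one the analysis assumes: a latent
drowsiness state $d$ that jointly drives all seven measures. Per
participant, $d(t)$ at 1 Hz is

intercept + between-session build-up (0.5/session, reset to 0.3 by the
lunch break) + within-session drift (0.3/trial) + stationary AR(1) noise
(sd 0.3, lag-one 0.9 at 1 Hz),

with intercepts drawn from N(−1.0, 0.4²) so the logistic $\sigma(d)$ spans
roughly 0.2–0.9 over a day — a participant who starts alert and becomes
markedly drowsy, the population the selection rule targets. Measures couple
through $\sigma(d)$: SEM and closure episode *rates* grow linearly in it,
EEG burst *amplitudes* (10-Hz alpha, 6-Hz theta over an autoregressive
background) grow with it, the lane-position innovation scale grows with it,
and KSS/ORD are clamped, rounded logistic responses with rater bias and
noise. Saccades (400°/s, 2–15°) and SEM kinematics (5–25°/s, 6–20°) are
chosen to straddle the detector's 30°/s and 5° thresholds so both the
acceptance and the rejection paths of the detector are exercised; the
volts-per-degree constant is randomised per participant (8–20 µV/°) so the
calibration stage genuinely matters; half of the pupil samples during a
closure are flagged invalid to exercise the PERCLOS tracking-loss contract.

What the generator does *not* emulate: realistic EEG microstructure beyond
band-limited bursts, facial video (raters are simulated), road geometry,
vigilance-task reaction times, and any particular numeric level of the
published correlations. A passing end-to-end run therefore shows that the
pipeline *recovers jointly-driven structure when it exists* and stays quiet
when it does not — it does not show that the effect sizes match human data.

The generator has two layers. The waveform layer is the default and is what
`extract_cohort()` consumes. `simulate_measure_table()` draws the per-trial
measures directly from the same latent process and coupling model, skipping
waveform synthesis; it exists for statistical checks that need many
replicate cohorts (for example the type-I-error calibration below), where
synthesising hundreds of gigasamples would add runtime without adding
information about the statistics stage.

## A worked example

```{r example, eval = FALSE}
library(drowsival)

## full waveform pipeline at the study scale (a few minutes of CPU)
tab <- extract_cohort(sim_config(), seed = 1)
nrow(tab)            # 408 trial rows: 17 participants x 8 sessions x 3

fit <- ord_validity(tab, kss_filter = FALSE)
summary(fit)
coef(fit)["ord_mean", "kss"]   # mean Fisher z, ORD ~ KSS
plot(fit)                      # drowsiness time course per measure
plot(fit, which = "pairs")     # pairwise mean z with 95% CIs
```

On a default cohort (seed 1) all 21 measure pairs come out positive and
significant — the synthetic analogue of the convergent-validity claim —
with, for example, mean z(ORD, KSS) ≈ 1.17 and trial-effect
F(23, 368) ≈ 35 for KSS. With every coupling gain set to zero the same
battery flags about 5% of pairs at $p < .05$, as it should.

## Numerical and design choices

* Zero-phase (forward–backward) IIR filtering everywhere a filter touches
  episode timing, so detected episodes align with trial windows. The filter
  runs with steady-state initial conditions and reflective padding; a
  constant input passes through exactly.
* Trial windows are closed-open `[start, end)` in seconds from session
  start; channels may start at different times and are sliced individually.
* The global trial order `3*(session-1)+trial` is derived, never stored.
* Welch window length/taper/overlap are not dictated by the emulated
  protocol (only "Welch" is); 2-s Hann at 50% is the conventional choice at
  1 kHz and is config-exposed, as is the 100-µV artifact rule behind the
  protocol's bare "without artifacts".
* Degenerate inputs fail loudly and specifically: overlapping SEM episodes
  (detector contract), zero-variance z samples (undefined t), zero error
  sum of squares (undefined F), calibration slopes below 1 µV/° (implausible
  gain). Missing data stay missing — assembly never imputes, correlations
  are pairwise-complete with a ≥3-trial floor, and ANOVA drops incomplete
  participants with a message.
* Determinism: every simulation entry point takes `(config, seed)` and
  derives independent sub-streams per participant, stage and session, so a
  single session can be regenerated bit-identically without generating the
  cohort.

## Problem sizes used in the shipped checks

The package's own test battery runs the waveform pipeline end to end at the
full 17 × 8 × 3 design once, verifies the episode detectors against
brute-force sample-wise oracles on 240 randomised short traces, checks the
ANOVA against an independent `aov()` decomposition to 10⁻⁹ relative error,
and calibrates the battery's type-I error on 50 zero-coupling cohorts at the
measure level. Smaller configurations (2 × 2 × 3) are used where only
plumbing is under test.

## Known limitations

* The raters, and hence ORD itself, are simulated; nothing here validates
  human rating behaviour.
* The concordance formula is a documented stand-in (tolerance-based
  agreement fraction) for a regulation formula that the emulated protocol
  does not reproduce.
* The reproduction of the published trial-level statistics requires the
  journal-deposited 408-trial table, which is not redistributable inside
  the package; the corresponding check fails with an informative message
  until a copy is supplied (see `tests/testthat/test-acceptance.R`).
* Band power is reported as absolute band-integrated power (µV²); any fixed
  positive rescaling (e.g. per-Hz normalisation) leaves every correlation
  and F statistic unchanged.
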