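---
title: "Serial cystometry reliability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial cystometry reliability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystokit)
```

This vignette is the package's account of its science: what the generative
model emulates, how the feature-extraction pipeline operationalizes the
standard urodynamic measurements, how the reliability statistics are
defined, which parameters matter, and where we made genuinely open design
choices.

## 1. The measurement problem

During continuous-infusion cystometry in an anesthetized rat, the bladder
fills at the pump rate (default 0.088 ml/min) and voids rhythmically. Each
micturition cycle shows a slow filling ramp, an active contraction starting
at the *threshold pressure*, a *peak pressure* during voiding accompanied
by phasic bursting of the external urethral sphincter (EUS) EMG, and a
decay back to the post-void *minimum pressure*. The intercontraction
interval (ICI) times the infusion rate gives the *volume threshold*; the
EMG contributes the *burst duration* (first quiet-period onset to last
quiet-period end) and the *burst count* (EMG peaks above baseline mean +
2 SD). Session values are averages of five successive events per animal.

Reliability of these six features is assessed two ways: within a session by
ICC(3,k) across the five events (animals as subjects, events as
measurements), and across sessions by a one-way repeated-measures ANOVA on
per-animal session means.

## 2. The generative model

`sim_config()` + `simulate_recording()` synthesize one recording;
`simulate_cohort()` / `cohort_study()` extend this to an
animals-by-sessions design.

**Pressure channel.** Each cycle is piecewise smooth: a linear filling ramp
from the previous minimum to the threshold; a raised-cosine rise from
threshold to raw peak over `contraction_rise_time` (default 15 s); a
linearly declining voiding plateau spanning the bursting window; an
exponential decay (rate constant 5 per decay duration, default 10 s) back
to the minimum. A constant `catheter_offset` (default 5 mmHg) is added to
the whole trace and Gaussian noise (`pressure_noise_sd`, default 0.5 mmHg)
on top. The recording opens with a `leadin_s` (30 s) empty-bladder segment
at zero corrected pressure — the "beginning of infusion" baseline that the
offset correction uses. The waveform shapes are not dictated by any data
source; they were chosen for smoothness and an unambiguous slope change at
contraction onset, and all shape parameters are config-exposed.

**EMG channel.** The raw EMG is a deterministic nonnegative amplitude
envelope multiplied by a sinusoidal carrier (default 250 Hz, chosen inside
a typical 10 Hz–1 kHz EMG passband and such that decimation blocks contain
whole half-periods), plus additive Gaussian noise. The envelope is: tonic
activity (`tonic_amplitude`, 0.05 mV) during filling; elevated guarding
activity (`guard_amplitude`, 0.15 mV) from shortly before contraction
onset to the peak and again from the end of bursting through the early
filling phase (sustained post-void tonic activity is a recognized feature
of these recordings); and during the voiding plateau an alternating
burst/quiet pattern: `B` raised-cosine bursts separated — and flanked — by
`B + 1` quiet gaps occupying `quiet_fraction` (default 0.4) of the window.
Because the bursting window opens and closes with a quiet gap, the
first-quiet-onset-to-last-quiet-end span equals the ground-truth burst
duration by construction. A carrier (rather than modulated noise) keeps
bursts present and countable even in fully noise-free configurations,
which the exactness tests exploit.

**Variance components.** All six features are strictly positive, so
per-animal means and per-event values are drawn from lognormal
distributions parameterized by arithmetic mean and fractional CV. The
defaults are calibrated analytically from the package's reference table
(`stuc_feature_reference()`): the reference SDs describe per-animal
five-event means and the reference ICC(3,k=5) splits that variance, giving
`sigma_between = sqrt(ICC) * SD` and
`sigma_within = sqrt(5 * (1 - ICC)) * SD`. Draws violating the cycle
geometry (minimum < threshold < raw peak; ICI long enough to hold rise +
bursting + decay + `min_fill_s`) are redrawn, a mild truncation of the
tails. The ICI is derived from the drawn volume threshold, so
`volume = ICI × infusion rate` holds to machine precision in the truth
table. Features are drawn independently of each other; real features
correlate (e.g. long ICIs tend to accompany larger voids), which the model
does not emulate — recovery tests are therefore about marginal means and
variance structure, not cross-feature covariance.

**What passing tests show — and what they do not.** The simulator shares
the pipeline's *definitions* of the features but not its *mechanisms*
(detection is done on the signals, not the truth table), so recovery tests
validate the measurement chain against known answers under realistic noise
and variance. They cannot certify behavior on real recordings, whose
non-stationarities (drifting baselines, non-voiding contractions, movement
artifacts, electrode repositioning between sessions) are out of the
generative model's scope.

## 3. The extraction pipeline

`extract_session_features()` runs five stages; `extract_params()` holds
every tunable with its default.

1. **Conditioning** (`condition_recording()`): the EMG is rectified
   (absolute value) and block-mean resampled from the acquisition rate
   (2 kHz) to an effective 0.1 kHz; the pressure is decimated identically
   for consistency and offset-corrected by subtracting its mean over
   `baseline_window` (default the first 10 s — the record's
   beginning-of-infusion segment). Block means were chosen over polyphase
   filtering because they are exactly testable and match the "smoothed by
   software resampling" character of the measurement; resampling at the
   original rate is the identity, and the ratio must be an integer.
2. **Measurement smoothing**: a light boxcar (`measure_smooth`, 0.5 s) is
   applied before any value is read off the trace. An extremum taken over
   hundreds of noisy samples is biased by extreme-value statistics (at the
   default noise level the post-void minimum would read ~0.3 mmHg low);
   smoothing suppresses this at the cost of a small deterministic rounding
   of the peak (≈ 0.1 mmHg at default geometry). Setting it to 0 restores
   exact noise-free recovery, which is how the exactness tests run.
3. **Void detection** (`detect_voids()`): voiding peaks are local maxima
   with topographic prominence ≥ `peak_prominence` (10 mmHg) separated by
   ≥ `min_separation` (60 s) — both an order of magnitude below typical
   peak heights (~21 mmHg above baseline... i.e. prominence ~20 mmHg) and
   ICIs (~330 s). Candidates are located on a coarse 2 Hz block-mean trace
   and refined at the effective rate. The post-void minimum is the trace
   minimum between a peak and the next, bounded at `max_post_void` (60 s)
   after the peak: without the bound, an animal whose filling ramp is
   nearly flat (low threshold, high minimum — possible under independent
   draws) lets noise place the "minimum" hundreds of seconds into filling.
4. **Threshold detection** (`find_threshold_pressure()`): the smoothed
   derivative (boxcar `deriv_smooth` = 1 s, central difference with
   half-gap `deriv_gap` = 1 s) is compared with a criterion of
   filling-slope mean + `slope_k` (3) SDs estimated over a
   `filling_window` (60 s) ending `rise_margin` (30 s) before the peak.
   The onset is the latest upward crossing that stays above the criterion
   through the point of steepest rise. Anchoring the "sustained" condition
   at the steepest rise rather than the peak matters: any smooth
   contraction has derivative returning to zero at its peak, so a
   crossing could never be "sustained until the peak" literally. Events
   where the derivative never exceeds the criterion (e.g. a pure linear
   ramp) are flagged and excluded from averages rather than imputed.
5. **EUS quantification**: the EMG baseline (mean, SD) comes from the
   longest filling-phase stretch at least `guard_s` (30 s) from every
   detected void, truncated to `baseline_len` (60 s). Within each void
   window (onset − `pre_void` to the post-void minimum), burst events are
   local maxima above baseline mean + 2 SD with ≥ `min_peak_sep` (0.05 s)
   separation **and** a prominence of at least `min_peak_prom_sd` (10)
   baseline SDs and `min_peak_prom_frac` (0.5) of their own elevation —
   the amplitude criterion alone cannot distinguish bursts from sustained
   guarding activity whose noise also crosses mean + 2 SD. The 2 SD
   criterion is read as mean + 2·SD of the *rectified* baseline: the
   rectified baseline has a nonzero mean, and all analysis operates on
   rectified records. Quiet periods are maximal sub-(mean + `quiet_k`·SD)
   intervals of at least `min_quiet` (0.02 s), searched within the
   bursting episode delimited by the detected burst peaks ± one median
   inter-burst interval; confining the search keeps unrelated low tonic
   activity elsewhere in the window from reading as quiescence. Burst
   duration is last quiet end − first quiet onset (0 without quiet
   periods).

Finally `select_stable_events()` picks the `n_events` (5) successive events
whose ICIs have the smallest coefficient of variation (ties: earliest
window; a user-supplied start time overrides). The ICI itself is measured
onset-to-onset: threshold onset is a defined fiducial of the method,
whereas peak-to-peak would mix contraction kinetics into the interval; a
`ici_fiducial = "peak"` switch is provided. The "minimum pressure" feature
is the same post-void minimum used inside the peak-pressure difference;
the definitions give no second minimum fiducial.

## 4. Reliability statistics

`icc3k()` implements the consistency-definition, average-measures ICC:
`(MS_rows − MS_err)/MS_rows`, `F = MS_rows/MS_err` with
`(n−1, (n−1)(k−1))` df, CI bounds `1 − 1/(F/F_{0.975})` and
`1 − 1/(F·F'_{0.975})`. The tests hold it to an explicit double-loop
sums-of-squares oracle at 1e−10. Degenerate inputs (missing cells, zero
between-subject variance) are errors; zero error variance (duplicated
columns) yields exactly 1. Bands: poor < 0.5 ≤ moderate < 0.75 ≤ good ≤
0.9 < excellent — the customary wording is ambiguous exactly at 0.9, and
we close the "good" band there.

`rm_anova()` is the one-way within-subject ANOVA with subjects as blocks;
it matches both the sums-of-squares oracle and base R's
`aov(y ~ session + Error(subject/session))` to machine precision. No
sphericity correction is applied to the headline p-value (the plain
`aov`-style result); a Greenhouse–Geisser-corrected p is computed and
reported alongside, clearly labelled. A matrix with zero residual variance
(e.g. sessions identical within every subject) is a degenerate-input error
rather than an F of 0/0.

`stuc_reliability()` assembles the cohort report: per feature, ICC(3,k)
over the first session's five events and the across-session ANOVA on
per-animal session means (the across-session analysis uses n×s per-animal
means, not all events, matching the session-mean definition of the
features). Animals with fewer than five events are excluded for that
feature with a warning — no imputation — and fewer than two remaining
animals is an error.

## 5. Numerical choices and degenerate inputs

* Block-mean resampling requires an integer rate ratio and drops a
  trailing partial block; resampling at the same rate is the identity.
* Offset correction subtracts a window mean (the definition leaves open
  whether a single sample or a window is meant; a 10 s window mean is
  robust to noise and makes the corrected baseline exactly zero-mean).
* Noise-free slope criteria add a 1e−12 epsilon so a zero-variance filling
  ramp does not trigger on floating-point ripple; the "latest sustained
  crossing" rule makes isolated numerical crossings harmless.
* The greedy minimum-separation rules (void peaks, burst peaks) keep the
  taller peak on conflict.
* Lognormal draws are truncated by redraw (up to 1000 rounds) to satisfy
  cycle-geometry constraints; configurations whose mean geometry is
  infeasible are rejected at construction.
* Monte-Carlo problem sizes in the tests: the cohort recovery check runs
  12 animals × 1 session at full 2 kHz scale (about a minute); the
  type-I-error calibration uses 500 replicates of the 12 × 3 feature-truth
  model, which exercises the statistics without resynthesizing signals —
  these sizes give stable checks while keeping the suite quick to run.

## 6. Known limitations

* No non-voiding contractions, pressure-volume compliance mechanics, or
  anesthetic pharmacology in the generator; residual volume and voiding
  efficiency are out of scope (a continuous-flow protocol cannot measure
  them).
* Features are generated mutually independent within an event.
* The EMG model is post-rectification-equivalent (envelope × carrier);
  it does not emulate motor-unit statistics or electrode-placement
  variability across sessions.
* Tonic EMG is modelled only as far as needed to make burst detection
  honest (guarding and post-void activity); it is not itself quantified.
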