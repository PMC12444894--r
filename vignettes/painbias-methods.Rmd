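---
title: "Methods: simulating and analysing attention and interpretation bias toward pain cues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing attention and interpretation bias toward pain cues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(painbias)
library(dplyr)
```

## The paradigm

`painbias` implements the complete data pathway of a fear-conditioning
generalization experiment in which participants perform a 2-back
working-memory task on a virtual tablet while a colour-graded ball floats
through the room and signals possible painful stimulation on hand contact.
Seven cues span a single blue gradient: two conditioned pain cues (CS+,
reinforced), two safety cues (CS-, never reinforced) at the opposite end,
and three ambiguous intermediate shades (CSA, never reinforced).  Which end
of the gradient carries pain is counterbalanced.

The session has four phases:

1. **Practice** - 32 letters of 2-back (500 ms letter, 1500 ms blank);
   repeated until accuracy reaches 70% (inclusive).
2. **Acquisition** - 8 trials: each conditioned cue twice, pain cues
   reinforced on every trial.  Afterwards each conditioned cue is rated
   once more (the post-acquisition manipulation check).
3. **Test** - a booster (1 reinforced CS+, 1 CS-) followed by 56 trials in
   pseudo-random order: every cue once with each of 8 trajectories whose
   durations run from 16 s to 58 s in 6-s steps.  CS+ reinforcement drops
   to 50%: 8 of 16 CS+ trials, 4 per CS+ cue, exactly 2 pain deliveries in
   every block of 14 trials.  The ball appears 4 s after the 2-back task
   starts; each trial ends with pain-expectancy and pain-related-fear
   ratings on 11-point numerical rating scales (NRS, 0-10).
4. **Colour discrimination** - all 21 unordered cue pairs plus 21
   self-pair fillers (each cue against itself 3 times), 42 trials.

Because raw data from such experiments are typically not shareable, the
package pairs the analysis pathway with a first-class synthetic-data
generator so that the entire pipeline is testable end to end.

## The unit of analysis: seven difference indices

Per participant, every metric is averaged over valid test trials within
each cue category and the analysis uses the ambiguous-minus-safe (CSA -
CS-) differences:

| index | metric | units | interpretation when positive |
|---|---|---|---|
| `ab_cue_dwell` | cue-AOI dwell time per second | ms/s | attention drawn to ambiguous cues |
| `ab_tablet_dwell` | tablet-AOI dwell per second | ms/s | (negative = attention drawn away from the task) |
| `ab_cue_fix` | cue fixations per second | 1/s | attention drawn to ambiguous cues |
| `ib_threat` | rated pain threat = (expectancy + fear)/2 | NRS points | ambiguous cues construed as threatening |
| `ib_pdr` | 2-s epoch pupil dilation | mm | arousal to ambiguous cues |
| `ti_latency` | 2-back mean reaction time | ms | task interference |
| `ti_error` | 2-back error rate | proportion | task interference |

CS+ category means feed the manipulation checks and omnibus tests but
never the indices.

## Schedule generation

Two details of the published design are under-determined and were fixed
once as package conventions:

* **Trajectory durations.** Only the range (16-58 s) and the 6-s interval
  are given; trajectory `k` is assigned `16 + 6(k-1)` s.
* **Letters per trial.** The 2-back runs for the whole trial with one
  letter every 2 s and the ball appearing at 4 s, so a trial of duration
  `d` seconds contains `floor((d + 4) / 2)` letters; the first two letters
  precede ball onset and have no 2-back reference, leaving the scoreable
  letters exactly co-extensive with the cue-present window.

Pseudo-randomization is rejection sampling under the seed: a candidate
order is a random permutation locally repaired so that no cue appears on
two consecutive trials (an added spacing convention - plain rejection
would accept only ~e^-7 of permutations), and a reinforcement assignment
is then drawn per 14-trial block until the 2-per-block and 4-per-CS+-cue
constraints hold.  Whether reinforced CS+ trials balance across
trajectories is not constrained (the design does not require it).  An
impossible configuration fails with a schedule-constraint error after a
bounded number of attempts.  Booster trials are flagged and excluded from
all downstream metrics; they exist only to refresh learning.

## The generative model of a participant

The simulator emulates exactly the data structures the preprocessing
consumes.  All defaults are the observed study conditions: the implied
category means and index means equal the reported values (safe-cue dwell
1.25 ms/s, tablet dwell 955.5 ms/s, threat 1.44 with +1.39 for ambiguous
and +4.48 for pain cues, 582-ms median latency with +3.17/+8.63 ms
slowing, a -3.2e-3 mm epoch-pupil effect, 95% colour accuracy).

* **Gaze** is emitted as categorical AOI labels, not gaze vectors: the
  derived metrics depend only on AOI membership, and this sidesteps
  unmodelled 3-D geometry.  Labels are generated as dwell *episodes* of
  250 ms whose AOI is drawn independently with
  `P(CUE) = base + ab_effect[category]` and
  `P(OTHER) = base + search_effect[category]`, remainder tablet.
  Episode-level (rather than per-sample) drawing is what makes >=100-ms
  fixations exist at realistic occupancies; with per-sample draws at 120 Hz
  virtually no run would reach 12 samples.  Setting the episode length to
  one sample period recovers the iid special case, which the tests use to
  verify the injected probabilities binomially.  Expected indices follow in
  closed form (`implied_indices()`): dwell indices are `1000 * dP(CUE)`
  ms/s and the fixation-rate index `dP(1-P)/0.25` per second.
* **Pupil** traces are baseline + slow sinusoidal drift + sensor noise,
  with a rectangular category-dependent bump over the 2-s post-onset
  epoch, sampled per eye at 120 Hz (configurable).  Blinks are
  Poisson-placed (0.2 Hz, 100-400 ms), hit both eyes and the gaze stream
  simultaneously; longer tracker losses (600-1500 ms) hit gaze only.
  The pupil light reflex to the approaching ball is deliberately not
  modelled - it is the stated confound that motivated restricting analysis
  to the 2-s epoch, and the full-trial dilation response is therefore not
  computed anywhere in the package.
* **2-back** responses are correct with probability
  `1 - (base_error_rate + error_effect[category])`, omitted with small
  probability, with log-normal latencies shifted by the category slowing;
  presses later than the 1500-ms response window become omissions, so a
  recorded press always has `rt <= 1500`.
* **Ratings** are the category mean plus Gaussian noise (SD 1.0), rounded
  and clipped to the 11-point NRS.  The noise SD matters: with much larger
  noise the floor at 0 would bias the safe-cue mean upward and shrink the
  interpretation-bias index.
* **Between-subject dispersion** (`cohort_params()`) multiplies gaze
  occupancies by unit-mean log-normal factors - keeping probabilities
  positive and cohort-mean indices unbiased - and adds normal deviations
  to the additive effects, with SDs chosen so per-participant index SDs
  match the reported ones (e.g. 1.1 NRS points for threat bias, 18 ms for
  latency interference).  Demographics follow the study sample (age ~21,
  85% female, ~5% screened out for chronic pain); sex is plumbing for the
  regressions only, coded 0 = female / 1 = male.
* The **calibration staircase** uses a linear latent rating
  `80 * I / threshold` plus noise, rated 0-100, stepping 0.5 mA from
  0.5 mA until a rating reaches 80; three runs, the maximum stop current
  is used, and a configurable safety ceiling turns a degenerate threshold
  into an error.

What the generator does *not* emulate - saccade kinematics, luminance
responses, smooth pursuit of the moving ball, structured (non-Poisson)
missingness, rating drift over time - bounds what passing tests show:
parameter recovery demonstrates that the pipeline is an unbiased,
correctly-calibrated estimator of effects *under this generative model*,
not that the model is a faithful account of real eye-tracking data.

## Preprocessing rules and numerical choices

All constants live in `pipeline_config()` and are echoed into every
report: fixation >= 100 ms, reconstructable gap <= 500 ms, median-filter
window 11 samples, blink margin 100 ms, blink ceiling 500 ms, baseline
100 ms before onset, epoch 2000 ms, validity cutoffs at 50%, RT outliers
at 3 SD, response window 1500 ms.

* Run durations are `n_samples * period`; thresholds compare inclusively
  (`>=` for fixations, `<=` for gaps/blinks) at sample resolution, with a
  1e-6-ms tolerance so that, e.g., 60 samples at 120 Hz count as exactly
  500 ms despite floating-point representation.
* Gap reconstruction precedes fixation detection, so a fixation may bridge
  a reconstructed gap; this is a convention (the alternative - detecting
  on raw runs - would make dwell depend on blink placement).
* The pupil chain per eye is median filter, then blink margining and
  linear interpolation, then binocular fusion, baseline, epoch.  The
  median filter leaves missing samples missing so blink extents survive to
  the deblink stage intact.  Margins of adjacent blinks merge into one
  interpolated span; spans missing a valid anchor on either side stay
  missing, as do runs longer than the blink ceiling even where a
  neighbouring blink's margin overlaps them.
* Trial validity is `missing fraction <= 50%` (inclusive keep) plus, for
  pupil, a non-empty baseline window; participant exclusion is strictly
  more than 50% invalid trials.  A trial invalid on either the gaze or the
  pupil criterion counts as invalid for the participant rule (the source
  design is ambiguous; this is the conservative reading).
* RT cleaning removes incorrect and omitted responses, then applies one
  non-iterative >= 3 SD cut around the participant's pooled mean; if the
  pooled SD is zero nothing is removed (guarding the degenerate reading
  under which identical latencies would all be "outliers").  Error rates
  are computed before RT cleaning and are unaffected by it.  Scoreable
  letters are positions 3 onward; omissions count as errors.
* One boundary convention required a choice: a 12-sample run at 120 Hz
  spans exactly 100 ms under the `n * period` rule and therefore *is* a
  fixation; the sub-threshold case is 11 samples (91.7 ms).

## Statistical battery

Engines are the standard R fits - `aov()` for the within-subject ANOVA,
`friedman.test()` (tie-corrected), `t.test()`, `cor.test()`, `lm()` with
`anova()` for nested-model increments - with the quantities of interest
computed on top: Greenhouse-Geisser epsilon from the sample covariance of
the conditions (bounded to `[1/(k-1), 1]`; the corrected p uses
epsilon-scaled degrees of freedom), `dz = t/sqrt(n)`, partial eta squared
`F df1 / (F df1 + df2)` (invariant under epsilon scaling), Wilcoxon
signed-rank Z with zero differences dropped, mid-ranks, tie-corrected
variance and no continuity correction, and Fisher-z confidence intervals.
The gaze metrics are analysed nonparametrically (Friedman + Wilcoxon), the
rating, pupil and 2-back metrics with GG-corrected repeated-measures
ANOVAs - mirroring the normality diagnostics of the original analysis
plan.  No multiple-comparison correction is applied anywhere, matching
that plan.

The hierarchical regressions enter age and sex, then one attention-bias
index with the threat-rating interpretation-bias index, then their
interaction built from mean-centered indices; standardized betas come from
fully z-scored refits (binary sex standardized like the rest for
reporting).  Simple slopes of the attention index are evaluated at +/-1 SD
of the moderator with standard errors from the coefficient covariance.
The pupil-based interpretation index is excluded from the regressions, as
in the analysis plan, because its own manipulation check fails.

Sample-size planning for correlations uses the *exact* sampling density of
r under bivariate normality (hypergeometric-series form, evaluated in log
space with a direct 2F1 series that converges quickly because its third
parameter grows with n), integrating the density over the rejection region
of the null t-based critical values.  This matters: the Fisher-z
approximation yields 85 for a medium effect (rho = 0.30, alpha = 0.05,
power = 0.80) where the exact computation yields 84.

## Test design and problem sizes

The suite verifies every operation against independent oracles: fixation
detection against an exhaustive run scan, the median filter against a
sort-based per-window oracle, signed-rank Z against exhaustive enumeration
of all 2^n sign assignments, the rmANOVA (including epsilon and corrected
p) against the multivariate-model route in `car`, and exact power against
a 10^5-draw Monte-Carlo estimate.

Simulation-based checks use these sizes, chosen to keep the default suite
fast while leaving the study conditions untouched: parameter recovery on
one 85-participant cohort at 120 Hz (every index mean within 3 standard
errors of its model-implied value); type-I calibration on 200 null-effect
cohorts of 8 participants at 60 Hz.  For the calibration, the pooled
rejection rate over the seven indices must lie within 2 percentage points
of 5%; per-index rates are checked against the exact binomial range
[3/200, 20/200] that a truly calibrated 5% process stays in with
probability above 0.999, because at 200 replicates the per-index
Monte-Carlo standard error (1.5 points) makes a per-index +/-2-point band
reject a perfectly calibrated pipeline roughly one time in five.

## Known limitations

* The gaze model has no spatial structure; metrics that would need it
  (first-fixation latency, saccade measures) are out of scope - the
  first-fixation latency was in any case dropped from the source analysis
  plan as confounded.
* Ratings are conditionally independent across trials; real raters drift
  and anchor.
* The 2-back letter stream places targets independently with probability
  0.3 from position 3; real sequences control lure structure.
* Exact-power integration is specific to the bivariate-normal correlation
  test; other designs would need their own power routines.
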