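---
title: "Quantifying anticipatory postural adjustments with fmsapa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anticipatory postural adjustments with fmsapa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmsapa)
```

## The measurement problem

Before any voluntary leg movement, the nervous system loads the support
leg to counteract the perturbation the movement will cause.  This
anticipatory postural adjustment (APA) is a standard behavioral index of
gait-initiation control, and it is reduced or abolished when the body is
externally supported.  Two task geometries carry the same APA signature:

* **Upright step initiation** on a force platform: before the stepping
  foot leaves the ground, the medio-lateral force `F_ml` deflects toward
  the support side.  A marker on the stepping-foot malleolus records the
  step itself.
* **Supine leg raise** inside an MRI scanner, where standing is
  impossible: raising one leg straight from the hip forces the opposite
  heel into its sensor before the lift.  An MRI-compatible force
  measurement system (FMS) — one thin-film force sensor under each heel,
  a touch bar limiting foot travel, all sampled at 32 Hz — records this
  supine analogue of the step APA.

`fmsapa` implements the computational chain around these recordings:
the event-related stimulus schedule, a trial simulator with ground
truth, the online force-drop trigger of the acquisition box, the APA
onset/amplitude/magnitude quantification, head-motion quality control,
and the exact small-sample statistics used to validate the supine task
against upright stepping.

## Paradigm generation

Each trial shows a cross (relax), a preparation circle, and a go circle.
Durations are drawn on 0.5 s grids — preparation on [1, 3] s, the
inter-stimulus cross on [5.5, 8.5] s — to jitter stimulus timing for
event-related fMRI.  "Poisson-distributed durations on a bounded grid"
is formally ill-posed, so the package resolves it as a truncated
Poisson draw over grid *indices*: duration = `min + step * j` with
`j ~ Poisson(lambda)` renormalized to the admissible indices
(`sample_grid_duration()`, default `lambda = 1.5`, configurable).  As
`lambda` tends to zero all mass collapses onto the grid minimum; any
`lambda` reproduces the printed grids exactly, which is the property the
tests pin down.

The go stimulus is *scheduled* at its 5 s maximum; its realized duration
is an acquisition-time outcome (it ends when the force under the moving
leg drops).  Cue assignment (which circle means "prepare") and condition
order are counterbalanced across subjects by an even random split
(`counterbalance()`).

## The trial simulator

No public recordings exist for this instrument, so the simulator is the
package's test bed: it generates trials with known ground truth, and
every detector is validated by parameter recovery against that truth.

**Supine trials** (`simulate_supine_trial()`): both heel forces rest at
10 N — heels press only lightly on the thin-film sensors when lying
supine.  From the true APA onset (go cue plus a uniform 150–400 ms
reaction latency) the support-foot force rises by `apa_amplitude`
(default 10 N) along a saturating-exponential ramp with a 60 ms time
constant; the onset is a slope discontinuity, matching the abrupt
force inflections seen in real records.  The moving foot loses 80 % of
its force from the lift onset, `apa_lead` = 250 ms after the APA onset.
The touch channel switches on when the foot reaches the restraint bar
(120 ms after lift).  Gaussian sensor noise (0.2 N SD) is added to the
force channels.

**Step trials** (`simulate_step_trial()`): `F_ml` follows a
piecewise-linear biphasic deflection (toward the support side to a 20 N
peak, then reversal past zero to −0.5 of the peak, then back), again
with an abrupt onset.  Force is synthesized at 1000 Hz and band-limited
with a zero-phase 4th-order Butterworth at 100 Hz to emulate the
platform's internal analog filter; the plateau at the peak is long
enough (80 ms) that the filter leaves the peak value intact.  The marker
excursion is a 300 mm smooth sigmoid over 300 ms starting at the step
onset (`apa_lead` = 350 ms after the APA), sampled at 200 Hz with 1 mm
noise.

In the supported condition (knee pad supine, walker upright) the
anticipatory component is scaled by `1 - suppression_factor`
(default 0.5, i.e. the roughly two-fold suppression reported for
externally supported movement).  Within a matched pair the same seed
drives both conditions, so suppression contrasts are matched on noise
and latency.

What the generator does *not* emulate: drifting sensor baselines,
non-Gaussian or correlated sensor noise beyond the analog filter,
trial-to-trial variation in APA shape, failed or hesitant movements,
and any scanner-related artifact.  Passing recovery tests therefore
show that the detectors are correct for clean but noisy geometry, not
that they are robust to every pathology of real recordings.

## The online trigger

The acquisition box watches the moving-leg force after the go cue and
triggers when a sample falls below `mean - 20 * SD` of a calibration
window recorded before the cue; the relax instruction follows exactly
500 ms later.  `run_acquisition_loop()` replays this rule sample by
sample, and the tests require the online trigger time to equal an
offline full-scan threshold search on every simulated trial.  With a
noise-free sensor the SD would be zero and the threshold unreachable;
the SD is floored at 0.5 % of the calibration mean, which documents the
degenerate case rather than hiding it.  The rule operates on raw
samples; whether the original hardware smoothed first is unknowable
from the outside, and raw is the stricter choice.

## APA quantification

Both tasks use the same primitive, `detect_crossing()`: the first time
the signal stays beyond `baseline mean ± 2 SD` for a debounce hold.
Two numerical choices matter:

* **Baseline window.** The instructed relax period (cross display to
  preparation cue) is the only quiescent epoch the paradigm defines, so
  it is the default baseline; it is configurable.
* **Debounce hold.** Band-limited noise crosses a 2 SD threshold in
  excursions lasting tens of milliseconds whatever the sampling rate,
  so a hold counted in samples cannot debounce — the default hold is
  about 100 ms of *sustained* crossing at each trace's rate (3 samples
  at 32 Hz, 20 at 200 Hz, 100 at 1000 Hz).  The onset reported is the
  first sample of the sustained run, so the hold adds no detection lag.
* **Search window.** The end-to-end analyzers search for onsets from
  the go cue only (an APA cannot precede its imperative stimulus), and
  the step-onset search additionally starts at the detected APA onset.
  Without these restrictions, chance 2 SD crossings during the 1–3 s
  preparation period dominate the false-onset rate.

**Step task** (`compute_step_apa()`): APA onset on `F_ml` (2 SD above
baseline), step onset on the 10 Hz-filtered marker displacement (2 SD
above baseline).  The amplitude is the peak absolute deviation of
`F_ml` from its baseline mean inside the APA interval — the standard
APA amplitude convention — divided by the subject's foot length
(N/cm).  Trials with undetectable onsets, or a step that does not
follow the APA, are flagged invalid with a reason, never dropped
silently.

**Supine task** (`compute_scanner_apa()`): APA onset on the support
(left) foot force, leg-lift onset on the moving (right) foot force 2 SD
*below* baseline — the moving foot is the one whose force drops, which
is why it also drives the online trigger.  The force magnitude is

```
100 * ∫ left force over [APA onset, lift onset]
      / ∫ left force over [prepare onset, relax display]
```

with trapezoidal integration of the *raw* force (the instrument
measures the force applied on the sensor; baseline subtraction is not
part of the definition) in both integrals.  The denominator epoch is
the cue-bounded trial, the only bounded window the paradigm defines.
Integration windows are closed (`[start, end]`, both endpoint samples
included), unlike the half-open slicing used everywhere else: with the
closed convention a sub-window covering a tenth of a constant trace
yields exactly 10 %, and the ratio stays in [0, 100] and is invariant
under positive rescaling.  The supplementary peak estimate (`apa_peak`)
is read from a 3-sample moving average, because the raw maximum of a
noisy trace is biased upward by the expected extreme of the noise.

`lowpass_filter()` wraps a zero-phase (forward-backward) Butterworth
filter with odd-reflection padding; without padding, finite records
carry start/end transients that corrupt baseline statistics.

## Head-motion quality control

`mean_displacement()` reduces 6-parameter rigid-body motion estimates
to a per-volume displacement: the Euclidean norm of the three
translations relative to a reference volume (first by default, middle
optional).  This is the "combined medio-lateral, antero-posterior and
superior-inferior" displacement; rotations are carried but excluded
from the criterion.  A run passes when its maximum displacement stays
below 1 mm, the conventional limit for a 3 mm EPI voxel.
`qc_report()` aggregates runs into the mean/SE/range summary a results
section reports.  Both reference-based conventions are exposed because
summary figures in the literature rarely say which was used.

## Exact small-sample statistics

With 8–10 subjects per group, normal approximations are not
trustworthy, so the validation battery uses exact tests implemented by
full enumeration:

* `wilcoxon_exact()`: signed-rank W with midranks; the null
  distribution enumerates all `2^m` sign assignments (zero differences
  dropped by Wilcoxon's original rule; an all-zero sample is degenerate
  with p = 1).  A tie-corrected normal z is reported alongside.
* `mannwhitney_exact()`: U from midranks; the null distribution
  enumerates all `choose(nA+nB, nA)` group assignments of the observed
  ranks, which is the exact permutation distribution with or without
  ties.
* `spearman_rank()`: midrank correlation; exact permutation p by
  enumeration of all `n!` orderings for n ≤ 8, seeded permutation
  sampling or a t approximation beyond.

Two-sided p-values double the smaller tail and cap at 1, the usual
convention for asymmetric exact distributions.  The test suite checks
every one of these implementations against independent brute-force
enumerations (and against the base-R references where those are exact),
exhaustively for n ≤ 10.

`validation_analysis()` assembles the battery: per-subject
unsupported-minus-supported difference scores in each task, the
cross-task Spearman correlation, paired Wilcoxon contrasts per task,
and correlations with a clinical score when one is supplied.

## The simulated cohort

`simulate_cohort()` emulates the study design end to end: each
synthetic subject performs both tasks in both conditions.  A
subject-level APA scale (log-normal, SD 0.3 on the log — roughly ±35 %
between subjects, a realistic spread for APA amplitudes) multiplies the
APA of *both* tasks; this shared trait is what makes the supine task a
valid index of upright stepping, and it is the mechanism behind the
cross-task correlation the battery recovers.  Because condition means
average 10 trials, measurement noise on the difference scores is a few
percent, and the between-task correlation of the difference scores is
high by construction; recovering a strong cross-task Spearman
correlation at n = 10 therefore tests the pipeline, not the power of
the Spearman test against weak bivariate-normal effects.  A synthetic
UPDRS motor score decreases with the APA scale, emulating stronger
parkinsonian impairment producing smaller adjustments.

## Problem sizes

The default verification sizes, chosen to make sampling error
negligible relative to the tolerances they are checked against: 200
simulated trials per task and condition for parameter recovery (median
onset error under 2 sample periods, mean amplitude bias within 5 %);
200 matched pairs for the suppression direction of effect (at least
95 % strict ordering); 1000 trials for online/offline trigger
equivalence (exact); exhaustive enumeration up to n = 10 for the exact
tests; 10^4 random traces for the magnitude bounds and 10^4 schedules
for grid compliance; a 10-subject, 10-trial-per-cell cohort for the
validation battery.  `scripts/acceptance.R` recomputes all of these
from scratch under a caller-supplied seed.

## Known limitations

* The FMS log format is a clean-room definition (the original control
  box format was never published); it is versioned and self-describing,
  but not a reverse-engineering.
* APA waveforms are minimal shapes (ramp-plateau, piecewise-linear
  biphasic) reproducing the geometry detectors rely on, not
  biomechanical models.
* Threshold-crossing onsets are systematically late by the time the
  signal needs to clear the 2 SD band; with the simulator's abrupt
  onsets this lag is below two sample periods, but slow real ramps
  would push it higher.
* The magnitude denominator depends on the cue-bounded epoch; run-level
  alternatives (e.g. whole-run integrals) would change its scale.
* Exact enumeration is limited to 25 non-zero differences (Wilcoxon)
  and 40 observations (Mann-Whitney); beyond that the normal
  approximations are the intended tool.
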