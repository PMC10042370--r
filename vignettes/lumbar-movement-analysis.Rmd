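---
title: "Quantifying variability and local dynamic stability of repetitive lumbar movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying variability and local dynamic stability of repetitive lumbar movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumovar)
```

## The measurement problem

Repetitive trunk movement — here, seated reaching performed 45 times at a
self-selected pace of roughly 0.38 repetitions/s — is never performed twice
the same way. How *much* it varies, and how quickly small deviations grow,
are read as signatures of how the nervous system controls the lumbar spine,
and both change under experimental manipulations such as postural threat
(the expectation of a mechanical perturbation) and in people with low back
pain (LBP). `lumovar` implements the full measurement chain from raw
motion-capture marker trajectories to those signatures, together with the
factorial statistics used to compare them across threat condition, LBP group
and task-specific pain expectation (Expected Back Strain, EBS), and a
synthetic-data generator that makes every stage testable against known
ground truth.

The movement patterns are summarised per trial by:

* **MeanSD** (deg, per axis): spatial variability — the between-cycle
  standard deviation of a lumbar angle at each normalized time point,
  averaged over the cycle;
* **CyclSD** (s): temporal variability — the standard deviation of cycle
  durations;
* **amplitude** (deg, per axis): mean per-cycle maximum minus mean
  per-cycle minimum;
* **velocity** (repetitions/s): repetitions divided by the time they span;
* **LDE** (log divergence per cycle): the local divergence exponent, the
  mean logarithmic rate at which initially neighboring trajectories in a
  delay-embedded state space move apart. Higher LDE means lower local
  dynamic stability.

## Kinematic chain

Two clusters of three reflective markers sit on the spinous processes of T8
(thorax) and S1 (pelvis). Recordings arrive at a nominally constant but
actually fluctuating 102/103 Hz, so every marker coordinate is first cubic
spline interpolated onto a uniform 100 Hz grid; dropouts up to 0.1 s are
bridged by the spline, anything longer is refused (`resample_to_rate()`) —
spline extrapolation across longer gaps is not trustworthy and silent
interpolation there would corrupt the variability measures downstream.

Each cluster defines an orthonormal frame (`cluster_orientation()`): axis 1
along marker 1 to marker 2, axis 3 along the normal of the marker plane,
axis 2 completing the right-handed triad. This two-vector construction is
deterministic and needs exactly the three markers available; a least-squares
rigid-body fit would need a redundant cluster and is deliberately out of
scope. The thorax frame is then expressed in the pelvis frame
(`relative_rotation()`) and decomposed (`euler_decompose()`) in the fixed
anatomical order **flexion-extension, then lateral-bending, then
axial-rotation**, the standard sequence for lumbar kinematics. Sign
conventions are not universal in the field; here the pelvis frame is assumed
to coincide with the global anatomical axes in the upright start posture
(x mediolateral, y anteroposterior, z vertical) and flexion is positive
forward — both documented rather than configurable-by-guesswork, and a
calibration rotation can be supplied to `markers_to_angles()` when marker
placement does not align cluster and segment frames. The decomposition is
singular at ±90° lateral bending; a 1° guard band raises an error there,
which the seated reaching task never approaches.

## Cycle segmentation and the linear metrics

Cycles are delimited by the most-forward sagittal orientation of the thorax
in each reach. The detector (`detect_cycles()`) takes local maxima of the
flexion-extension trace that (i) rise above the signal median, (ii) have
topographic prominence of at least 25% of the signal's interquartile range,
and (iii) are separated by at least half the dominant period (first
autocorrelation peak). Detection runs on a zero-phase low-pass filtered copy
(cutoff four times the movement frequency) and each detected peak is then
snapped to the raw-signal maximum within ±5 samples: near the flat top of a
reaching cycle, measurement noise displaces the raw argmax far more than it
perturbs the movement itself, and the filter removes exactly that jitter.
None of these thresholds is sacred; all are arguments with the defaults
above, chosen for smooth quasi-periodic traces.

The first five of the 45 repetitions are discarded as transients and the
final 40 cycles analyzed (`select_analysis_cycles()`). CyclSD is the n−1
standard deviation of the 40 peak-to-peak durations. For MeanSD, each cycle
is spline-resampled to 101 points (0–100% phase), cycles are aligned by
maximizing the circular cross-correlation of their flexion-extension trace
with the ensemble mean (integer shifts, bounded at ±10 phase samples, one
refinement pass against the updated mean), and the shift found on
flexion-extension is applied to all three axes so that coupling between axes
is preserved. Maximizing circular cross-correlation with the mean is the
same as minimizing each cycle's squared deviation from it, and the zero
shift is always admissible, so alignment cannot inflate the variability it
precedes. Velocity uses the time spanned by the analyzed cycles; whether
the discarded transients should count toward "total trial time" is
ambiguous, and using the analyzed span keeps velocity consistent with every
other metric computed on the same 40 cycles.

## Local dynamic stability

Because the divergence exponent is sensitive to series length, the angle
series covering the analyzed cycles is first spline-resampled to exactly
300 samples per cycle (12 000 points for 40 cycles). The state space is
6-dimensional: the three lumbar angles plus one 30-sample delayed copy of
each (10% of a cycle). For every state, the 15 nearest neighbors by
Euclidean distance are found, excluding neighbors within a Theiler window
of 150 samples (half a cycle) in time — temporally adjacent states are
trivially close and would fake convergence; the window value is standard
practice for periodic movement data and configurable. Log distances between
the forward images of each state–neighbor pair are averaged over neighbors,
then over states, for lags 0..300 (one cycle); pairs whose images run past
the series end are dropped at that lag, and distances are floored at 1e-12
before the log so coincident states cannot produce −∞. The LDE is the
unweighted ordinary-least-squares slope of this curve over lags 0–75
inclusive (the first 0.25 cycle, the simplest reading of "best fitting
line", with lag 0 included), multiplied by 300 to express log divergence
per cycle; the per-sample slope is also attached. The neighbor search is
exact brute force in compiled code — at this problem size an approximate
index buys nothing and exactness lets the search be verified against a
direct distance-matrix oracle.

## What the synthetic generator emulates — and what it does not

`generate_angle_trial()` builds the flexion-extension channel as an
asymmetric raised cosine (default peak at 45% of the cycle: the reach is
slightly faster than the return) from upright to 20° peak flexion, with
phase-locked 8° sinusoids on the secondary axes, at 100 Hz. Three noise
sources are controlled independently, and this separation is the point:

* **temporal jitter** — per-cycle durations drawn as 2.6 s + N(0, σ). The
  drawn durations are anchored peak-to-peak, because peak-to-peak intervals
  are what segmentation measures; anchoring them at cycle starts instead
  would mix adjacent draws and make the generator's own ground truth
  unrecoverable by construction.
* **process noise** — multiplicative white noise on the instantaneous phase
  velocity. This produces genuine trajectory divergence, which is what the
  LDE measures; purely additive noise does not.
* **spatial noise** — additive per-axis noise, low-pass filtered at 10 Hz
  (kinematic noise is smooth, unlike white measurement noise) and rescaled
  so its marginal SD equals the requested value exactly, which is what makes
  MeanSD recovery quantitative.

Defaults (45 cycles, 2.6 s period, amplitudes 20/8/8°, jitter 0.10 s,
spatial noise 1.0°, process noise 0.02) match the task's reported scales.
The generator does *not* emulate soft-tissue artifact, marker occlusion
patterns, inter-axis amplitude correlations, or the richer harmonic content
of real reaching; passing recovery tests therefore demonstrates the
pipeline's correctness, not that real recordings are this benign.

`generate_cohort()` works at the summary level: 60 participants in a
2 (LBP/healthy) × 2 (EBS low/high) between-subject design, each measured in
reference and threat conditions. Skewed metrics are drawn log-normally with
participant-level baselines; the LDE is drawn on its natural scale
(3.86 ± 0.2). A single `threat_effect` factor (default 1.22, a 22% MeanSD
flexion-extension increase) drives all condition responses — CyclSD
×(1+0.5(f−1)), LDE +0.45(f−1), amplitude ×(1+0.25(f−1)), velocity
×(1−0.15(f−1)) — with relative weights fixed once from the magnitudes this
paradigm reports; tying them to one factor keeps `threat_effect = 1` an
exact global null, which the type-I-error calibration relies on. An
`interaction_effect` (default 1.25) inflates secondary-axis MeanSD in the
LBP-and-high-EBS cell only. Between/within dispersions are sized so that
the planted 22% effect yields F ratios around 20 at N = 60, the magnitude
observed for this task. EBS scores are integers 0–10 drawn to respect the
fixed dichotomization (≤3 low, ≥4 high), with the pre-threat score higher
on average than the pre-reference score and the two positively correlated.

## The statistics stage

Skewed metrics (MeanSD, CyclSD, amplitudes, velocity) are natural-log
transformed before modelling; the LDE, already near-symmetric, is not. The
base of the logarithm is immaterial for F and η² — natural log is simply a
fixed choice. EBS is dichotomized on the score assessed before the first
(threat) trial.

The three-way mixed MANOVA exploits that a two-level within factor reduces
exactly to two between-subject multivariate models: per-participant
condition *differences* carry the within-subject effects (the threat main
effect is the test of the intercept) and condition *means* carry the
between-subject effects. Both models are fitted with effect coding and
Type III hypotheses — the conventional unweighted-means analysis for
(possibly mildly unbalanced) factorial designs, matching what the major
statistics packages report; with balanced cells all SS types coincide.
Wilks' Λ = det(E)/det(E+H) is converted with Rao's F, exact for the 1-df
effects here: for N = 60 and 4 between cells the error df is 56, so the
within-effect F carries (5, 52) df with five dependent variables
(MeanSD ×3, CyclSD, LDE) and (4, 53) with four (amplitudes ×3, velocity).
Univariate follow-ups report F(1, 56) and partial
η² = SS_effect/(SS_effect+SS_error), which for 1-df effects equals
F/(F+56). The implementation is independent linear algebra and is verified
in the test suite against `car::Anova` on random cohorts. Alongside the
MANOVAs, the descriptive suite runs Mann-Whitney U tests between groups for
ordinal scores, a Wilcoxon signed-rank test of EBS across conditions
(all-zero differences reported as p = 1), independent t-tests for height
and weight, and the Spearman correlation between the two EBS scores.
Significance is α = 0.05 throughout with no multiple-testing correction,
mirroring common practice for this design.

## Numerical choices and degenerate inputs

* Cubic splines are `stats::splinefun(method = "fmm")` everywhere —
  reproducing cubics exactly and preserving endpoints.
* Rotation matrices are validated (orthogonality within 1e-6, det +1)
  before decomposition; collinear marker triplets are refused.
* Constant signals, too-few peaks, a peak count different from the
  protocol's 45, cycles shorter than 4 samples, fewer than 2 cycles, and
  non-positive values under the log transform all raise errors naming the
  offending trial, marker or column rather than propagating garbage.
* Determinism: generators draw from a seed and restore the caller's RNG
  state; the analysis pipeline itself is deterministic, so identical input
  and configuration give byte-identical metric files.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the study's trial
geometry throughout (45 cycles, 40 analyzed, 100 Hz, 12 000-point state
spaces, 60-participant cohorts). Replicate counts are sized for stable
Monte-Carlo estimates at interactive runtimes: 50 seeds for the MeanSD and
CyclSD recovery brackets, 20 seeds per process-noise level for LDE
monotonicity (10 in the acceptance script), 1000 null cohorts for type-I
error (500 in the script), and 100 cohorts for power. Divergence tracking
in bulk simulations uses an 80-sample horizon — the fitted range (75 lags)
is unaffected; the default 300-sample horizon is kept for single-trial
diagnostics.

## Known limitations

* C3D recordings are not read directly; convert to the documented marker
  CSV dialect first. The marker-to-axis correspondence of a real protocol
  must be established by the user (or a calibration rotation supplied).
* The cycle detector assumes one dominant quasi-periodic component; it is
  not a general-purpose event detector.
* The LDE per-cycle scaling (slope × 300) reproduces the magnitudes
  reported for this task; other conventions (per second, per stride) exist
  in the literature, so compare exponents only under a common convention —
  the per-sample slope is attached for that purpose.
* The cohort generator draws metrics directly at the summary level; it
  cannot answer questions about how trial-level noise propagates into
  cohort-level effect sizes. Chain `generate_angle_trial()` through
  `run_trial_pipeline()` when that is the question.
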