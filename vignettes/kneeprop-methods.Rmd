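---
title: "Methods: knee-proprioception exergame analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knee-proprioception exergame analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeprop)
```

## What this package computes

`kneeprop` implements the analysis pipeline of a two-game knee
proprioception training study: two inertial sensors (thigh, at the
biceps femoris site, and midshank) stream unit orientation quaternions
at 74 Hz; a two-stage calibration removes mounting bias; the knee angle
drives two exergames (a squat game for closed-kinetic-chain training
and a stretch game for open-kinetic-chain training) with optional
auditory feedback; pre/post angle-reproduction tests quantify joint
position sense; EMG from seven leg muscles is decomposed into muscle
synergies; and a small-sample exact rank test compares the improvement
of the feedback group against controls.

Because raw trial data are not public, the package ships a first-class
synthetic cohort generator that emulates the study design end to end.
Every analysis stage is exercised and tested against that generator's
retained ground truth.

## Sensor model and calibration

Orientations are unit quaternions $q = (w, x, y, z)$, scalar-first,
Hamilton products. All rotation-level code is invariant to the global
sign flip $q \equiv -q$; averaging first aligns every buffer sample to
the hemisphere of the first sample, then takes the component-wise mean
and renormalizes.

Calibration has two stages:

1. **Flat surface.** Both sensors lie parallel on a desk; 14 s at
   74 Hz yields just over 1000 samples, and the trailing 1000-sample
   buffer is averaged into the shared baseline $q_0$.
2. **Upright stance.** After attachment, a second 14 s recording per
   sensor gives the upright mean $q_{\mathrm{ref}}$.

The per-sensor correction is $q_T = \bar{q}_{\mathrm{ref}} \otimes q_0$
(conjugate times baseline) and every in-task sample is corrected as
$q_{\mathrm{cal}} = q_R \otimes q_T$. The study protocol fixes only
the *contract* of these equations — the measured upright pose must map
back onto the flat-surface baseline, so both calibrated sensors
coincide at stance — and any composition convention satisfying that
contract produces identical angles. We fixed the convention above and
test the contract directly: for arbitrary random $(q_0,
q_{\mathrm{ref}})$, `apply_calibration(q_ref, q_T)` reproduces $q_0$
to below $10^{-6}$ degrees, and the upright knee angle is always 180°
included.

The knee rotation is the relative rotation between calibrated frames,
$q_{\mathrm{knee}} = \bar{q}_{\mathrm{shank}} \otimes
q_{\mathrm{thigh}}$, and the reported angle is its Y (sagittal-plane)
Euler component under the intrinsic Y–X–Z order. The extraction order
is not fixed by the study protocol (the original game engine has its own
convention); on (near-)pure-Y rotations — the movement plane of both
exercises — all common orders agree, which is what the tests pin down.
Near the gimbal singularity ($|$pitch$| \to 90°$) the code falls back
deterministically to the axis–angle magnitude projected on Y rather
than raising an error. Angles are reported on two conventions:
*included* (180° = straight leg, the internal canonical form, always
in $[0°, 180°]$) and *flexion* ($180° - $ included), because the
study's squat targets (90°/130°) are flexion angles while its stretch
targets (135°/180°) are included angles.

Thigh and shank samples are paired by nearest neighbour within half
the nominal sample period, with no interpolation — mirroring a live
system that pairs most recent frames — and unpaired samples are
dropped.

## Protocols, mappings, sonification

The squat game presents 12 groups of 9 carrots; each group requires
holding a half squat (flexion 90°) or deep squat (flexion 130°) for
2.5 s and is followed by a 20 s stand-up rest, so one round spans
$12 \times 22.5 = 270$ s. The stretch game spawns 12 fish on four
trails at included angles 90°/120°/150°/180°; a fish is caught after a
2 s hold on its trail and escapes after 10 s. Spawn spacing is not
part of the stated protocol; the generator spaces spawns `escape + 2` s apart
so windows never overlap (configurable). Pre/post tests prompt 10
squats and 10 seated stretches, held about 5 s, with the two targets
of each family in randomized order.

Screen position is a linear function of angle (squat game: rises with
flexion; stretch game: rises with included angle, the four trails
landing exactly on positions 0, 1/3, 2/3, 1). Sonification maps
position to one short percussive stimulus: amplitude exactly linear
from silence (0) to maximum non-clipping volume (1), pitch ascending a
monotone semitone ladder. The ladder size (25 steps, two chromatic
octaves) and the fixed 0.15 s stimulus duration inside the stated
0.1–0.2 s band are package choices, both configurable; the protocol
fixes only monotonicity and the duration band. Both pitch and
amplitude are modulated (the methods description; the more terse
abstract mentions loudness only). For the control group the
sonification function returns a silence marker.

## Joint-position-sense metrics

Per prompted movement, the actual knee angle (AKA) is the mean over
the central 60 % of the hold window — the study segmented with video
assistance, which is unavailable here, so the central-window mean
excludes transitions instead. The signed error is
$\mathrm{AE} = \mathrm{AKA} - \mathrm{TKA}$; per test and movement
family the average mean error is $\mathrm{AME} = |\sum \mathrm{AE} /
n|$ and the improvement is $\mathrm{IE} = \mathrm{AME}_{\mathrm{pre}}
- \mathrm{AME}_{\mathrm{post}}$ (positive = improvement). The
"absolute mean" reading of AME is the default; since it can cancel
bias-free errors to zero (errors $\{+5, -5\}$ give 0), the
mean-of-absolutes variant is available behind an explicit flag.

Outliers are screened in a single pass on the pooled IE values of each
movement family across both study groups: z-scores on the full list
(sample SD), drop $|z| > 2.5$, with a zero-variance guard. The scope
(pooled vs per group) is configurable because the protocol leaves it
open; a single pass is deliberate (no re-screening after removal),
so idempotence is not claimed.

## Exact rank inference

The group comparison is a Mann-Whitney U test. For the study's sample
sizes the null distribution is computed exactly by the classic
recurrence (conditioning on whether the largest pooled observation
belongs to the first sample), validated in the tests against
brute-force enumeration of all $\binom{n_1+n_2}{n_1}$ rank assignments
up to $n_1 = n_2 = 8$ and against the base-R Wilcoxon distribution.
One-sided p is $P(U \ge U_{\mathrm{obs}})$; two-sided is twice the
smaller tail, capped at 1. With ties (midranks) or $n_1 + n_2 > 25$
the normal approximation with tie and continuity correction is used
and labelled as such.

Both sidednesses are always reported. The study design calls for a one-sided
test, but the reported p-values (.04 for U = 41, .03 for U = 42 at
$n = 7 + 7$) are exactly the two-sided enumeration values
(130/3432 = .0379 and 90/3432 = .0262); the one-sided values would
print as .02 and .01. Which was actually computed cannot be determined
from the reported values alone, so the package computes both and
leaves the choice explicit in the configuration.

Quartiles use inclusive linear interpolation (`quantile` type 7); the
protocol does not fix the method.

The a-priori power calculator implements the between-factor
noncentral-F model for a two-group repeated-measures design:
$\lambda = f^2 N m / (1 + (m - 1)\rho)$ on $(k - 1, N - k)$ degrees of
freedom, with the repeated-measures correlation $\rho$ exposed
(default 0.5). The study's G*Power panel settings are not printed, so
the package makes no claim that any default set reproduces its N = 10;
the calculator is validated against numerical integration of the
noncentral-F density instead.

## Muscle synergies

EMG segments are event-locked: stretch-game segments run from 2 s
before each catch to the catch; squat-game segments span the first to
the ninth carrot of a *complete* group (incomplete groups and missed
fish yield nothing). Preprocessing per channel, in order: fifth-order
Butterworth low-pass at 30 Hz, fifth-order high-pass at 4 Hz, mean
subtraction, full-wave rectification, division by the channel maximum,
division by the channel SD (unit variance). Filtering is zero-phase
(forward–backward) by default — appropriate for offline analysis and
the package's choice where the protocol is silent — with a single-pass
causal mode behind a flag; for LTI filters the LP→HP order equals a
4–30 Hz band-pass either way. The filter stage is tested against the
analytic Butterworth magnitude response (a 50 Hz probe must be
attenuated below $1/\sqrt{1 + (50/30)^{10}} \approx 0.078$ single-pass).

Synergies are extracted with non-negative matrix factorization
(multiplicative updates, Frobenius loss, at most 1000 iterations,
relative tolerance $10^{-6}$), best of 10 seeded restarts, W columns
normalized to unit norm with scale pushed into H. VAF is
$1 - \|E - WH\|_F^2 / \|E\|_F^2$ with the *uncentered* total sum of
squares, the standard choice in the synergy literature. The selected synergy count is the smallest $k$ with
VAF $\ge$ threshold (90/85/80 %, default 85 %) — the reading under
which a minimum synergy count exists. Model
selection reuses each best fit, padded by one random component, as a
warm start for $k + 1$, which makes the VAF sequence non-decreasing
in $k$. Cross-group weight comparison matches columns by exhaustive
assignment maximizing total cosine similarity (exact for $k \le 7$).

## The synthetic cohort: what it emulates, what it does not

Generator defaults are the study conditions: 7 + 7 participants,
pre/post tests of 10 + 10 movements, 74 Hz sensors, 14 s calibration
recordings, random sensor mounting offsets up to 30° and 0.25°
per-sample orientation noise.

The proprioceptive error model is additive Gaussian with a
per-participant bias: movement error $= b_i + \varepsilon$,
$b_i \sim N(0, 10°)$, $\varepsilon \sim N(0, 3°)$. These defaults put
pre-test AME on the 5–10° scale the study reports. Training
attenuates errors multiplicatively — post-test errors are scaled by
$1 - g$ with learning gain $g = 0.8$ for the feedback group and 0 for
controls — the simplest mechanism consistent with a positive IE. With
these settings the median IE separation between groups is about
5–6.5°, and the full pipeline detects the one-sided difference in
well over 80 % of seeded replicates. On the stretch family the bias
enters as systematic under-extension ($-|b_i|$ on the included scale):
end-range reproduction errors are physically one-sided at the 180°
boundary (a knee cannot over-straighten into the sensor model, and the
relative-rotation magnitude folds any overshoot back), and without
this choice boundary clamping would silently halve the simulated
training effect for half the cohort. A lognormal error-magnitude
option exists for sensitivity analysis; Gaussian is the default.

Trajectories are minimum-jerk transitions (1 s) into noisy holds and
back to rest (stance for squats, a mid-range seated posture for
stretches). The IMU model measures the thigh as the world-frame Y
rotation of the ground-truth flexion composed with the sensor's fixed
mounting offset, plus per-sample random small rotations; the shank
sensor is static. This retains exactly the geometry the calibration
contract removes and none it does not.

EMG is generated as a non-negative synergy mixture $E = W H +
\varepsilon$ clipped at zero: three synergies with disjoint muscle
supports, task-locked Gaussian activation bursts around each game
event, and noise set by SNR (20 dB in the recovery checks). The
default EMG sampling rate for full-protocol simulation is 1111 Hz,
typical for the study's sensor family;
the pipeline's simulated synergy stage defaults to a shortened session
(3 squat groups, 4 fish, 250 Hz) so that the event-locked structure —
not the sheer record length — is what the tests exercise.

What the generator deliberately does **not** emulate: biomechanically
realistic muscle activation dynamics, ground-reaction forces, balance,
electromechanical delay, skin-motion artefacts, or non-stationary
sensor drift. Passing tests therefore demonstrate that the *analysis*
is correct and well-calibrated under the study's assumed data model,
not that the hardware would achieve these error levels in vivo.

## Numerical choices and degenerate inputs

* Quaternion normalization rejects near-zero norms; averaging guards
  against antipodal cancellation.
* Every emitted included angle is clamped to $[0°, 180°]$ (the
  relative-rotation magnitude cannot leave it, but noise at the
  boundary could).
* Segments with fewer than 3 samples are dropped with a warning;
  schedule windows outside the series raise an error naming the
  problem.
* All-zero or constant EMG channels abort preprocessing with the
  channel name.
* Zero-variance lists pass the outlier screen untouched.
* Trail quantization breaks exact midpoint ties toward the lower
  trail.
* All simulation randomness flows from explicit seeds through one
  seed-scoping helper that restores the caller's RNG state;
  regenerating any dataset from its manifest seed is byte-identical.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations to
make the Monte-Carlo properties sharp but cheap: 20 seeded
participants for angle-recovery RMSE, 20 seeds for synergy recovery at
SNR 20 dB, 2000 replicate pairs for the exact test's null calibration,
and 100 simulated cohorts (plus 100 null cohorts) for the end-to-end
power and size of the full pipeline. A full-protocol single run
(`study_config()` defaults) takes a couple of seconds on one core.

## Known limitations

* The Euler extraction order is only contract-tested on sagittal
  rotations; markedly out-of-plane motion would need the engine's
  exact convention.
* NMF multiplicative updates find local optima; restarts mitigate but
  do not guarantee the global factorization, which is why model
  selection uses warm-started nesting and tests use generous restart
  counts.
* The exact rank test is limited to $n_1 + n_2 \le 25$; beyond that
  the corrected normal approximation is used automatically.
* AME's absolute-mean default can mask dispersion without bias; read
  it together with the mean-of-absolutes variant when errors are
  two-sided.
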