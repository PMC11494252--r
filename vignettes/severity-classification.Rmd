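---
title: "Classifying residual stroke severity from robotic therapy kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying residual stroke severity from robotic therapy kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`rehabsev` turns raw in-home therapy kinematics — joint angle and
assistance pressure sampled at 30 Hz while a patient plays therapeutic
video games with a pneumatic wrist or ankle device — into a three-class
residual-severity prediction (`no`, `low`, `high` range of motion, encoded
0/1/2). The pipeline has six stages: simulation of raw session streams,
per-activity feature extraction, dataset assembly with leakage-safe
normalization, redundancy/dimensionality diagnostics, model training with
cross-validation, and holdout evaluation. This vignette records the
modeling assumptions, the defaults and why they were chosen, and the
numerical corner cases, at the level of detail a maintainer or reviewer
needs.

## The synthetic cohort generator

No dataset of this kind is publicly deposited, so the generator is the
package's source of study material. It emulates the *statistical shape* of
a real device cohort, not the device physics.

**Within one activity.** The angle channel is

```
angle(t) = A * (0.85 sin(2 pi f t + phi1) + 0.15 sin(2 pi (pi f) t + phi2))
           + N(0, noise_sd) + spikes
```

a slow task-following sinusoid plus a faster jitter sinusoid, Gaussian
sensor noise, and rare outlier spikes. Design points:

* `A` is the half peak-to-peak amplitude in degrees around the 0° rest
  midpoint (flexion negative, extension positive). The jitter frequency is
  `pi * f` — an *irrational* multiple of the base frequency — so the two
  components drift through all relative phases within an activity and the
  empirical peak-to-peak range converges to `2A` for any phase draw. A
  rational ratio (say 3:1) would make the attained range depend on the
  phase offset, breaking the closed-form range the tests verify.
* The jitter amplitude fraction (0.15) is small enough that the jitter
  never creates additional direction changes (its slope contribution
  `0.15 * pi` stays below the main component's `0.85`), so the expected
  direction-change rate is `2f` per second and `f` is set to half the
  profile's `movement_rate_hz`.
* Spikes replace a sample by `±spike_scale × max(A, 1)` with per-sample
  probability `spike_prob` (default 0.002, scale 4): transient sensor
  faults, the phenomenon that motivates winsorization downstream.
* Pressure is an activity-level assistance draw modulated in antiphase
  with the movement (the device pushes hardest at the bottom of the
  stroke) plus N(0, 0.15) sensor noise, which can dip slightly below zero
  as real gauge readings do.
* Score events arrive as a sparse Poisson process (0.15 events/s) with a
  per-game scale `exp(U(0, 4))` — scores are deliberately not comparable
  across games; about 30% of games can also lose points, so cumulative
  scores are only sometimes monotone.

**Across the cohort.** Class profiles give the hand-scale means and SDs:

| class | volitional amplitude (°) | assist pressure (PSI) | movement rate (Hz) |
|-------|--------------------------|-----------------------|--------------------|
| no    | 3 ± 1.5                  | 8 ± 2                 | 0.40               |
| low   | 14 ± 5                   | 5 ± 1.5               | 0.50               |
| high  | 34 ± 10                  | 2.5 ± 1.5             | 0.60               |

Patients with less residual function get more assistance and move slightly
more slowly. Three cohort-level mechanisms are deliberate:

1. **Between-patient heterogeneity exceeds within-patient variability.**
   Each patient draws their own amplitude, assistance and pace from the
   wide class distributions above; activities of one patient then vary
   tightly around those (within-patient amplitude SD = 8% of the patient
   mean + 0.3°). Patient clusters from different classes interleave in
   feature space. This is what real kinematics cohorts look like, and it
   is the mechanism behind the qualitative model ordering (see below).
2. **The low-ROM class is a mixture.** The labeling protocol pools
   patients who did and did not tolerate the assisted assessment into one
   "low" class. The generator mirrors this: 60% are a *passive* subtype
   (amplitude × 0.75, assistance ≈ 3 PSI), 40% an *assisted* subtype whose
   slow, device-driven excursion (amplitude × 3.2, pace × 0.75, assistance
   ≈ 6.5 PSI) exceeds even the high class's volitional range — consistent
   with assisted assessments reaching the largest total ROM in clinician
   tables. The low class therefore flanks the high class in ROM while
   overlapping the no class in pressure: mean ROM stays ordered
   no < low < high, but no hyperplane cleanly separates the classes.
3. **Peripheral scaling.** Ankle ROM is roughly half of wrist ROM, so foot
   streams (35% of patients) scale amplitudes by 0.5, adding an
   h-by-amplitude interaction to the class boundary.

**Sessions.** Session lengths are uniform over 5–60 minutes with 1–10
activities per session (an exponential-weights split of the session time,
so activity durations are realistically uneven), 9–15 sessions per
patient, and 33 patients by default — about 2,000–2,300 activities per
cohort, a desk-scale stand-in for a full device corpus.

**Seeding.** One master seed drives a deterministic cohort plan; each
stream gets a derived seed (`master*1009 + counter mod 2^31-1`) so any
single activity can be regenerated without replaying the cohort, and the
streaming path (`simulate_features`) agrees exactly with the materialized
path (`simulate_cohort` + `cohort_features`).

**Assessments.** Clinician-style records draw max/min angles as
class-conditional stretch gains times the patient's volitional amplitude
(passive stretching moves a no-ROM patient far beyond their own movement;
an assisted high-ROM patient reaches roughly half of it), with noise
proportional to the profile's sensor noise. The emitted label always
equals the generating truth label: the clinician's judgment itself —
weighing tone, spasticity, and context — is out of scope; the simulator's
assessments exist to carry ground truth in the protocol's shape (high →
assisted, low → either, no → passive).

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: labeling noise and inter-rater
disagreement; non-stationarity within a session (fatigue); game-specific
movement patterns; device recalibration drift; missing samples and
irregular timestamps; recovery over time (each patient is stationary
across sessions). Results on synthetic cohorts demonstrate that the
pipeline's machinery is correct and that its qualitative behavior matches
the intended regime, not that its absolute accuracy transfers to device
data.

## Feature extraction

Cleaning order is winsorize → smooth, per activity:

* **Winsorization** at the 1st/99th percentiles (linear-interpolation
  percentiles, the R/numpy default type 7). Because interpolated
  percentiles sit between order statistics, re-winsorizing can move values
  already at a clip boundary within the tie-induced gap; interior values
  are exactly fixed. The suite tests this bounded form of idempotence.
  Percentiles are computed per activity, not globally: a sensor fault in
  one game should not influence another's cleaning.
* **Smoothing**: centered moving average, window 5 samples (~0.17 s at
  30 Hz) — the simplest method consistent with removing sample-level
  noise, with edge shrinkage (the window truncates at the ends) so no
  padding values are invented and length is preserved. Window 1 is the
  identity.
* **Movement count** `N_mov`: direction changes of the smoothed angle,
  counted only after the signal has moved `movement_hysteresis_deg`
  (default 2°) from the last counted extremum. The default blocks the
  residual noise left after smoothing (SD ≈ 0.8/√5 ≈ 0.36°, so 2° is
  >5 SDs) while passing any therapeutic movement. The counter is
  implemented in C++ for throughput (a 60-minute stream has 108,000
  samples); an independent pure-R extremum-enumeration oracle cross-checks
  it in the tests. Zero hysteresis still requires a strictly positive
  excursion, so constant series count 0.
* **Directional forces**: angular velocity ω by central differences at the
  sampling rate (degrees → radians before squaring), force `F = c ω²` with
  `c = 1 N·s²/rad²` by default. The true mass-lever constant of a limb is
  unknowable here and irrelevant downstream: features are z-scored before
  modeling, so only relative magnitudes matter. `F_ext` is the maximum
  over upward-moving samples; `F_flex` the maximum over downward-moving
  samples, *stored negative* to keep the two directions visually and
  numerically distinct in the data dictionary. Central differencing at
  30 Hz underestimates a 0.5 Hz sinusoid's peak velocity by the sinc
  factor ≈ 0.4%, well inside the 1% tolerance the tests use.
* **Other features**: `t_game` is the total recording time (last minus
  first timestamp plus one sample period, so a 15 s activity reports
  exactly 15); `Score` is the maximum cumulative score (0 if no events);
  `h` is 1 for hand, 0 for foot. `R_mean` is computed and carried but is
  not in the default model feature set — the data dictionary's 11 features
  are `F_flex, F_ext, N_mov, R_min, R_max, t_game, P_min, P_max, P_mean,
  Score, h`; `rehab_feature_names(include_r_mean = TRUE)` opts in.

## Dataset assembly

* **Activity filter**: drop activities with fewer than 3 movements — no
  meaningful therapeutic exercise happens below that.
* **Split**: 80:20 at the activity level, stratified on the class label by
  default. Stratification uses largest-remainder rounding so the training
  set is exactly `round(0.8 n)` rows and each class is within one row of
  its share. Activity-level splitting means rows of one patient appear on
  both sides; this within-patient leakage is intentional — it mirrors how
  activity-level therapy datasets are split in practice, and is precisely
  what lets flexible models shine (see below). A patient-grouped split (`group_by_patient = TRUE`)
  is available for the honest-generalization variant, default off.
* **Normalization**: per-feature z-scores with mean/SD fitted on the
  training partition only and applied verbatim to the holdout — the
  leakage-hygiene contract. Zero-variance features keep SD = 1 (so they
  transform to 0 on the training set) and are flagged.

## Exploratory diagnostics

Pearson correlation (the standard default; nothing in the feature set
calls for a rank estimator) with the |r| > 0.9 exclusion rule, *strict*
inequality: a pair at exactly 0.9 is retained, consistent with keeping a
force pair observed "at about −0.9". When a pair exceeds the threshold the
*later* feature in the canonical data-dictionary order is dropped — a
deterministic tie-break. The F_flex/F_ext pair ships as a default
keep-override: flexion and extension strength recover along distinct
neuromotor pathways after stroke, so both are clinically informative even
when statistically coupled. Raising the threshold can only shrink the
dropped set (monotonicity, tested). Zero-variance features yield an
undefined correlation, reported as 0 with a warning flag. PCA
explained-variance ratios come from `stats::prcomp` on the z-scored
training rows; on real-data-like inputs no single component dominates,
which is why the full feature set is kept — on synthetic cohorts that
specific percentage is not asserted, only the simplex properties
(nonnegative, nonincreasing, sum to 1).

## Models

| kind | implementation | key hyperparameters |
|------|----------------|---------------------|
| `gradient_boosted_trees` | xgboost, leaf-wise (`lossguide`) growth | ≤200 rounds, learning rate 0.1, ≤127 leaves, early stopping (20 rounds) on an inner 15% validation slice |
| `extra_trees` | ranger, randomized splits, no bagging | 42 trees, 100% of features per split, unlimited depth |
| `logistic_regression` | nnet::multinom | multinomial objective, no added penalty |
| `feedforward_network` | package's own MLP | hidden layers (8, 5, 8), ReLU, Adam (lr 0.01), batch 32, ≤200 epochs, early stopping on a 15% slice |
| `majority_baseline` | modal class | — |

Notes on fidelity and substitutions:

* The boosted ensemble's hyperparameters are chosen so the *fitted*
  structure lands at the scale a consensus model of this kind reaches on a
  few thousand rows (a few hundred trees across 3 classes, tens of leaves
  each); the fitted tree count and maximum leaf count are recorded in the
  model metadata and reported by the reproduction script.
* The extra-trees spec records its reference configuration (entropy
  criterion, 8717 max leaf nodes) as metadata; ranger's randomized-split
  rule has no entropy option and no leaf cap, so trees are grown unbounded
  (`min.node.size = 1`) — at a few thousand training rows, 8717 leaves *is*
  unbounded, and the randomized-split mechanism is the defining element of
  the algorithm.
* No installed R package provides multi-hidden-layer ReLU networks
  (`nnet` is single-layer sigmoid), so the MLP is implemented in the
  package: He initialization, softmax cross-entropy, Adam updates,
  early stopping with best-weights restoration. `tune_network` grid-searches
  layer sizes, learning rate, batch size and epochs by inner CV, logs every
  evaluated point, and breaks ties toward the smaller network.
* Cross-validation is stratified k-fold (default 10) with remainder rows
  assigned to random folds so fold sizes stay even; per-fold accuracies
  are stored so the reported mean/SD are recomputable. One experiment seed
  governs split, folds and model seeds; tree-model runs are
  bit-reproducible under a fixed seed (single-threaded xgboost/ranger).

**Why trees beat the linear model here.** Multinomial softmax regression
is more expressive than folk wisdom suggests — its per-class linear scores
can carve strips and corners, so cluster geometry alone (XOR corners,
per-peripheral scales) does not defeat it. What does is the cohort
structure above: patient clusters from different classes interleave with
genuinely nonlinear optimal boundaries, and the activity-level split lets
tree ensembles resolve individual patients' pockets while a single linear
boundary cannot. On default cohorts the tree ensembles reach holdout
macro-F1 ≈ 95–100% versus ≈ 84–94% for logistic regression — the
expected qualitative ordering (trees ≫ linear) for cohorts of this
structure. The
network's relative standing is cohort-dependent and not asserted.

## Evaluation

Confusion matrices carry counts plus a row-percentage view (each nonempty
true-class row sums to 100). Precision = TP/column sum, recall = TP/row
sum, F1 = harmonic mean, all in percent; macro averages treat classes
equally, weighted averages weight by support. Both are always reported —
reporting conventions in this literature alternate between the two — and
the model ranking uses weighted F1. Zero denominators (a class never predicted, or absent
from the truth) yield 0 with an explicit flag rather than NaN; this only
affects degenerate predictors like the majority baseline. Display rounds
to 2 decimals; JSON artifacts keep full precision.

## Problem sizes and runtime

The test suite and the reproduction script run at desk scale by choice:
the default cohort is 33 patients / ≈2,200 activities (≈20M raw samples,
simulated and summarized in ≈10 s), oracle-equivalence checks use 100
random streams of 100–600 samples, and cross-validation uses 10 folds on
≈1,800 training rows. The full suite runs in about half a minute; the
reproduction script in well under a minute.

## Known limitations

* Synthetic validation only: absolute accuracies on these cohorts say
  nothing quantitative about real device data (see the generator's
  non-goals above).
* The activity-level split's within-patient leakage inflates all models'
  absolute scores; the patient-grouped split is provided but its results
  are not part of the default report.
* The force feature is a relative summary (`c = 1`), not a biomechanical
  force estimate.
* Winsorization percentiles are per-activity; very short activities
  (< ~100 samples) clip more aggressively than long ones.
* The MLP is intentionally minimal (no dropout, no weight decay, no
  learning-rate schedules); it is a baseline, not a contribution.
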