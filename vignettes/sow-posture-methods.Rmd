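---
title: "Quantifying sow posture and posture transitions from hind-end accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sow posture and posture transitions from hind-end accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowmotion)
```

## The problem

A farrowing sow poses a crushing risk to her piglets, concentrated in the
moments when she changes posture — above all the abrupt standing-to-lying
"flop" and side-to-side rolling. `sowmotion` implements a complete analysis
chain for a single tri-axial accelerometer glued to the sow's hind-end
(between tail-head and hip bones, ±8 g₀ range, nominally 100 Hz): it
recovers the sensor's orientation from the gravity component of the signal,
detects and delimits posture transitions, classifies the five posture
states, characterises each transition kinematically, and summarises an
animal's lying behaviour for comparison across a herd. A semi-Markov
simulator generates ground-truthed synthetic recordings so that every stage
is testable without animal data.

Axis convention: `x` craniocaudal, `y` mediolateral, `z` dorsoventral.

## Signal model and features

**Gravity estimation.** The static (gravity) component is estimated per
axis with the recursive exponential filter

$$g_i(t) = \alpha\, s_i(t) + (1 - \alpha)\, g_i(t-1), \qquad i \in \{x, y, z\},$$

seeded with the first sample. For constant input the estimate is a fixed
point of the recursion, and for bounded input it stays within the input
bounds (each output is a convex combination of inputs). A variant with the
recursion's second term negated is available (`literal_sign = TRUE`) for
auditing; it is not used by any other component because it fails the
fixed-point property a moving-average filter must have. The weight defaults
to `alpha = 0.01`, a ≈1 s time constant at 100 Hz: fast relative to posture
changes (several seconds to minutes apart), slow relative to gait, shuffling
and sensor noise.

**Per-frame features.** The trace is cut into consecutive, non-overlapping
2-s frames (200 samples at 100 Hz; trailing partial frame dropped). Each
frame `i` yields `f(i) = {p, r, a}`:

* pitch `p = atan(g_y / sqrt(g_x^2 + g_z^2))` in degrees, range [−90, 90] —
  hind-end lowering (sitting, lying) moves pitch away from the standing
  value;
* roll `r = atan2(−g_x, g_z)` in degrees, range (−180, 180] — left/right
  lateral lying sits near ∓90°. The two-argument arctangent is required to
  reach the full range; the `+180` boundary is the chosen convention for a
  sensor pointing straight down;
* activity `a`: the population standard deviation of the per-sample
  magnitude `m(t) = sqrt(x^2 + y^2 + z^2)` within the frame — an
  orientation-invariant movement-intensity proxy (population rather than
  sample SD; at 200 samples per frame the difference is negligible).

Orientation is computed from the *frame mean of the gravity estimate*
(average the vector, then take angles) rather than averaging per-sample
angles, which would wrap badly near the roll boundary. Frames carry their
mean gravity and the first two magnitude moments so that longer windows can
be aggregated exactly from them.

## Transition detection and segmentation

Each 2-s frame is merged with the five following frames into a 12-s
*extended frame*; consecutive extended frames overlap by 60 %, realized as
a whole-frame stride of `round(6 × 0.4) = 2` base frames (4 s). A pair of
consecutive extended frames is a *candidate* transition when

$$|p_i - p_{i-1}| > \theta_p \quad \lor \quad |r_i - r_{i-1}| > \theta_r,$$

and a candidate is *confirmed* only when at least one adjacent pair is also
a candidate (configurable via `confirm_adjacent`) — a single-pair excursion
is a temporary position adjustment, not a posture change. Runs of
consecutive confirmed pairs collapse to one transition point, the midpoint
between the centres of the first pair's frames.

**Threshold defaults.** The thresholds are, in the source protocol,
empirically determined. The package ships `theta_p = theta_r = 8°`, chosen
analytically from the detectability geometry rather than by trial: averaging
orientation over 12-s windows 4 s apart dilutes a step change of Δ degrees
to a maximum pair contrast of Δ/3, and the confirmation rule requires the
*second largest* contrast of the event to clear the threshold too, which for
ramp-like transitions up to about half the window length sits near Δ/4. The
smallest orientation contrast among the posture classes is the ≈35° sitting
pitch offset, giving usable contrasts of ~9–12°; a threshold of 8° keeps
those transitions detectable while remaining more than an order of magnitude
above the sub-degree orientation noise of a resting sow. (A threshold of
15° would silently make sit↔stand and sit↔sternal transitions undetectable
by construction.)

**Segmentation.** From each transition point the algorithm walks outward
over the 2-s frames and places the boundary at the last time the
orientation was *consistent* for at least 1.5 s, where consistent means
pitch varies ≤ `theta_p / 3` and roll ≤ `theta_r / 3` within the window
(the source protocol does not quantify "consistent orientation"; one third
of the detection threshold separates plateau wobble from transition motion
cleanly on simulated data). With 2-s frames the 1.5-s window spans two
consecutive frames. If no stabilization is found before the trace edge, the
edge is used and the segment flagged `truncated`. Overlapping segments from
nearby points are merged. Segmentation deliberately works on the
preprocessed frames, not raw samples, matching the rest of the detection
chain.

One bias is worth knowing about: the transition point is the midpoint of
the *first* threshold-exceeding pair, which with 12-s extended frames can
precede the physical onset of an abrupt transition by up to ~8 s, and the
segment always brackets its point. Measured durations therefore carry a
systematic upward bias of up to a few base frames. The bias is common to
all transitions of an analysis, so the comparative use of the duration
feature (per-animal ECDFs against a pooled baseline) is unaffected.

Two documented failure modes carry over from the underlying method: very
gradual posture changes (minutes-long drifts below threshold) are missed,
and large non-transition movements (scratching, shifting) can fire false
positives. The first is reproduced by a test; the simulator does not model
the second.

## Posture classification

Frames are labelled from interval annotations by their midpoints (half-open
`[start, end)` intervals; frames inside annotated transitions are excluded
— posture labels describe states, not movements). An RBF-kernel SVM
(`e1071`, i.e. libsvm's SMO) maps standardized `{p, r, a}` to the five
classes: standing (ST), sitting (S), left lateral lie (LL), right lateral
lie (RL), sternal lie (SL). Kneeling is transitory and has no class.

Hyper-parameters are grid-searched (`cost` ∈ {0.1, 1, 10, 100}, `gamma` ∈
{0.01, 0.1, 1, 10}) by internal cross-validation on the training animals
only, scored by macro-F1. The internal folds are *grouped by animal*
whenever at least `cv_folds` animals are present: ungrouped folds share
each animal's idiosyncratic posture offsets between training and
validation, which lets an overfit kernel width win the grid and then
collapse on a genuinely unseen animal — grouped folds score the quantity
the model is actually used for. Standardization statistics come from the
training fold only; nothing about held-out animals enters the model.

RBF-SVM training cost grows superlinearly with the number of frames, so the
grid search runs on a stratified subsample (≤ 400 frames per class) and the
final fit on ≤ 2000 per class; both caps are arguments. Evaluation is
leave-one-pig-out: one fold per animal, predictions pooled across folds,
per-class F1 from the pooled confusion matrix.

## Transition kinematics

Six descriptors per segmented transition: duration; peak acceleration (max
magnitude); acceleration range (largest per-axis max−min); jerk (first
derivative of acceleration, computed as the rate-scaled first difference of
the magnitude series and summarised by its maximum absolute value — the
summary statistic is unspecified in the source protocol, and the maximum is
what distinguishes a hind-end stopping suddenly from one lowered gently);
and the pitch and roll rates (maximum absolute frame-to-frame derivative of
the preprocessed orientation, symmetric with the jerk summary). Peak, range
and jerk use raw samples; the orientation rates use the preprocessed
frames — that contrast is deliberate and inherited from the method.

## Behaviour profiles

Per animal: the posture time budget (proportion of classified frames per
class), the transition-frequency series (count of transitions per 2-h
window stepped by 12 min; windows are half-open and only full windows are
emitted, so each transition is counted once per window position), and, for
each kinematic feature, the animal's ECDF against the pooled all-animal
baseline. The baseline includes the animal under comparison, as the
original comparison does; `leave_one_out = TRUE` excludes it. ECDFs are
`stats::ecdf` — exactly the "proportion of transitions with value ≤ x"
definition — and the pooled baseline is identically the
transition-count-weighted mixture of the per-animal ECDFs, which the tests
assert.

## The simulator

`simulate_sow()` draws a semi-Markov schedule — posture dwells with
shifted-exponential lengths and a preference-weighted next-posture choice —
and synthesises the signal it implies. Design choices, and what they are
for:

* **Orientation targets** ST (0, 0), S (−35, 0), LL (0, −90), RL (0, 90),
  SL (0, 0): lateral lies separated by roll, sitting by pitch, and
  standing/sternal deliberately sharing an orientation so that only
  activity separates them — the confusion structure reported for real
  herds.
* **Per-dwell orientation jitter** (5–8° SD; 14° pitch SD for sitting): a
  sow never reoccupies exactly the same position. Sitting gets the widest
  jitter and the shortest, rarest dwells (mean 60 s; ≈1 % of frames),
  which together reproduce sitting as the hardest class without making it
  unlearnable.
* **Dwell means** (ST 240 s, S 60 s, LL/RL 1500 s, SL 700 s) skew the time
  budget toward lateral lying, matching the reported herd budgets. The
  20-s minimum dwell reflects that a posture held only moments would be
  annotated as part of the transition.
* **Transition preference matrix**: stand↔lie moves preferred; direct
  ST↔SL swaps excluded, because those two postures share a sensor
  orientation (a same-orientation swap is unobservable in orientation
  space) and a real crated sow descends via a kneel/sit phase — the
  simulator routes such moves through S.
* **Transitions**: duration uniform on 8–16 s; orientation interpolated by
  a sigmoid (steepness 16, i.e. ~90 % of the change inside the central
  ~27 % of the interval) producing the stabilization plateaus segmentation
  needs; a half-sine impact spike (0.3 s) along the gravity direction with
  amplitude equal to the drawn *abruptness* (uniform 0.2–3 g₀), so peak
  magnitude ≈ 1 + abruptness — the flop signature.
* **Noise**: white sensor noise (SD 0.01 g₀, typical MEMS noise at this
  bandwidth) plus *band-limited* movement jitter — an AR(1) process
  (coefficient 0.9) scaled per posture (standing 0.08 g₀ … lateral lying
  0.008 g₀, with a per-dwell log-normal multiplier that makes activity
  levels overlap between postures). Movement is band-limited because a
  body does not shake at the Nyquist rate; white "movement" noise would
  dominate the sample-to-sample differences that jerk measures.
* **Pre-farrowing surge**: inside the configured window the transition
  rate multiplies (dwell means divide), emulating nest building.

Everything is reproducible from a single seed.

**What the simulator does not model**, hence what passing tests do not show
about real data: scratching/shifting movements that cause real false
positives, minutes-long gradual posture drifts (tested separately as a
constructed input), kneeling, sensor detachment or failure, piglet contact,
and any biomechanical coupling between abruptness and duration. Simulated
classification scores are therefore upper bounds, not predictions, of
real-herd performance; the acceptance checks assert the *qualitative*
structure (sitting hardest, lateral lies easiest, detector recall/precision
high on clean ground truth), not the real-herd numbers.

## Evaluation conventions

Event-based matching: a detection coincides with an annotated transition
when their intervals overlap after dilating the annotation by a tolerance
(default 2 s, one frame) that absorbs video/sensor clock error. Multiple
detections on one annotation count once; each unmatched annotation is one
FN; each detection matching nothing is one FP. Precision, recall and F1
follow, with zero-denominator metrics raising a typed error rather than
returning 0 — "no detections" and "all detections wrong" should not be
conflated. Frame-level classification uses the pooled confusion matrix with
one-vs-rest F1 per class (`2TP / (2TP + FP + FN)`).

## Numerical and degenerate-input choices

* Samples outside ±8 g₀ are clipped (sensor saturation), counted, warned.
* Pitch ±90° and roll 180° return closed-boundary values; only the
  all-zero gravity vector errors (no orientation exists).
* Roll at the boundary: `atan2` receives `0 − g_x` so that a signed zero
  cannot flip +180° to −180°.
* The extended-frame stride, `round(group_size × (1 − overlap))`, is the
  nearest whole-frame realization of the stated 60 % overlap; sub-frame
  interpolation is not attempted.
* Ties in the hyper-parameter grid resolve to the first combination in
  grid order, making training deterministic under a fixed seed.
* Raising the detection thresholds shrinks the set of confirmed frame
  pairs pointwise, but the number of *events* is not strictly monotone in
  the thresholds: a long confirmed run at a low threshold can split into
  two runs (two events) at a higher one. The property tests assert the
  pair-level monotonicity, which is the form that actually holds.
* Simulation problem sizes used by the test suite: 6-h recordings for the
  six-sow classification cohorts (ten seeds), 24-h recordings for detector
  recovery and kinematics (ten and three seeds), and a 96-h schedule-only
  run for the surge shape. These give a few hundred transitions and tens
  of thousands of labelled frames per check — enough that the asserted
  margins are far outside Monte-Carlo wobble.

## Known limitations

Streaming/online detection is out of scope; the native binary format of
the original logger is not parsed (CSV in, CSV out); very gradual
transitions are undetectable by design of the thresholded rule; the
sitting class is data-poor by nature and its scores are the most variable;
and real-herd F1 values cannot be reproduced without the original herd
data, which is not publicly deposited.
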