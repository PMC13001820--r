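---
title: "Methods: microsaccade modulation during goal-directed reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsaccade modulation during goal-directed reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachsacc)
```

## The problem and the design

During steady fixation the eyes produce microsaccades — rapid movements
of less than about a degree — at roughly 1–2 Hz. Their rate is not
constant: it falls in anticipation of behaviourally relevant events and
dips sharply after salient transients (oculomotor inhibition). This
package implements, end to end, the analysis needed to quantify that
modulation in a four-condition eye–hand task: participants fixate a
target 20 cm above a start position and either passively monitor the go
cue (*cue monitoring*), watch a cursor travel to the target on its own
(*cursor tracking*), or reach to the target with (*reach visible*) or
without (*reach invisible*) cursor feedback. The go cue follows a delay
of 1.8–2.0 s after target onset; passive response phases start 0.3 s
after the cue. Gaze is sampled at 500 Hz, the hand at 1000 Hz, and 1 cm
on the display subtends 1.5 visual degrees at the 37-cm viewing distance.

Because raw recordings from such experiments are rarely shareable, the
package treats the synthetic-data generator as a first-class module: it
produces trials with known microsaccades, known kinematic landmarks and
(optionally) planted violations of every exclusion rule, so each analysis
stage is testable against ground truth.

## The simulator

**Kinematics.** Reaches and the self-moving cursor follow the
minimum-jerk displacement profile
\(y(t) = a\,(10\tau^3 - 15\tau^4 + 6\tau^5)\), \(\tau = t/d\). The
printed form of this profile in task descriptions sometimes carries
all-positive signs; only the alternating-sign polynomial satisfies the
boundary conditions \(y(d) = a\) and zero endpoint velocity and
acceleration, so that is what the package implements. Peak speed is
\(1.875\,a/d\) at \(t = d/2\). The cursor's lateral bow is a half-sine
\(x(t) = \pm 0.25\,\sin(\pi t / d)\) cm — the bow's time course is a
design choice of this package; its constraints (zero at the endpoints,
extremal exactly once at the midpoint, 0.25-cm maximum) are the task's.
Reach durations are Normal(1.36, 0.08) s truncated to [1.1, 1.6];
reaction times are shifted log-normal (shift 0.15 s, log-SD 0.2) with
medians 0.38 s (visible) and 0.45 s (invisible). Condition-specific trial
ends are computed on the clean kinematics with the same rules the
analysis later applies to data: cursor inside the 1-cm-radius target for
500 ms, or hand speed below 10 cm/s for 200 ms (searched from the
post-onset speed peak — the rising flank of a slow reach is itself below
threshold and must not end the trial).

**Gaze.** Fixational gaze is a zero-mean random walk (step SD 0.001 cm
per 500-Hz sample) reflected at about 1 cm from the current fixation
centre, plus white measurement noise (SD 0.005 cm). The walk is folded
per axis at \(1/\sqrt{2}\) cm so the radial excursion stays within
~1 cm. Neither drift model is a claim about physiology; both are the
simplest processes with the right magnitudes. A target-acquisition
saccade (smooth 50-ms step) begins 40 ms after target onset by default;
on the shortest delays its tail overlaps the initial-fixation analysis
zone and slightly inflates that zone's estimated rate, which mirrors what
happens in a real session where fixation is acquired just after target
onset.

**Microsaccades.** Injected events are smooth minimum-jerk steps with
amplitude Normal(0.95, 0.25) cm truncated to [0.3, 1.8] and duration
Normal(86, 15) ms truncated to [50, 130] — magnitudes chosen to match
typical fixational microsaccades in this size regime. The minimum-jerk
waveform gives peak velocity \(1.875 \cdot \text{amplitude}/\text{duration}\),
a built-in main-sequence relation (~21 cm/s at the mean event). Event
directions are uniform, re-aimed toward the target once the accumulated
offset exceeds 1.5 cm so gaze stays on target. Onsets come from an
inhomogeneous point process via thinning. Events may not overlap (50-ms
minimum gap); because each accepted event blocks a stretch of timeline,
the thinning intensity is inflated by \(1/(1 - r\,b)\) with \(b\) the
mean blocked time, which makes realised onset counts match the integral
of the requested profile (verified against a Poisson band in the tests).

**The task-like rate profile** ramps from 1.3 Hz (1.8 s before the cue)
to 0.2 Hz at the cue, dips to 0.02 Hz over 0.10–0.28 s after it, and
rebounds to 0.6 Hz from 0.3 s — a stylised oculomotor-inhibition time
course with a high early baseline, anticipatory decline, sharp post-cue
dip and partial rebound. A per-participant log-normal factor (log-SD 0.1)
creates between-participant rate variance. These are simulator
parameters, not measurements.

## Preprocessing

Gaze is linearly interpolated onto the 1000-Hz hand grid (exact at the
original instants; linear interpolation is shape-preserving and exact for
the piecewise-linear test signals). Missing runs of at most 2 samples
(4 ms) are bridged; longer runs propagate as missing, and trials whose
analysis window touches a missing run are routed to the exclusion stage.
Filters are Butterworth low-passes applied forward and backward (zero
phase): 3rd order at 10 Hz for the hand, 2nd order at 15 Hz for gaze,
with 1 s of reflective padding so the transient never touches the data;
generated recordings extend 1 s beyond the analysis window on both sides
for the same reason. Velocities and accelerations use central differences
(one-sided at the ends), which are exact on the polynomial test signals.

## Detection choices

The detector uses the 5-sample moving-window velocity estimator
conventional for velocity-threshold microsaccade detection, with the
robust spread \(\sigma = \sqrt{\mathrm{median}(v^2) -
\mathrm{median}(v)^2}\) per axis, \(\eta = \lambda \sigma\) and
\(\lambda = 5\). Choices the method description leaves open, fixed here:

* thresholds are estimated per trial over the detection window
  \([t_{\text{show}}, t_{\text{end}}]\) — the medians are robust to the
  saccades inside it;
* the minimum duration is 40 samples at 1000 Hz ("40 data points", i.e.
  40 ms);
* the ellipse criterion is a strict inequality, so a sample exactly on
  the boundary is not saccadic;
* events separated by short gaps are *not* merged;
* no amplitude ceiling is enforced at detection — the 6-cm landing rule
  lives in the exclusion stage, which is also how the target-acquisition
  saccade is handled naturally.

The detector is verified sample-for-sample against an independent
brute-force scan on random traces, and its scale invariance (thresholds
recomputed after rescaling velocities by any positive constant) and
monotonicity in \(\lambda\) are tested as properties. With the default
noise, injected events are recovered at ≥ 95% with ≤ 0.1 Hz false alarms
(200 trials; the 15-Hz filter costs a few milliseconds of onset latency,
so the millisecond-accuracy check runs on unfiltered upsampled traces
where the 5-point window already provides smoothing).

## Segmentation, exclusion

Movement onset is the last upward crossing of 5% of peak speed before
the speed peak at which the hand is also accelerating at ≥ 5% of the
pre-peak acceleration maximum; offset mirrors this after the peak with
the deceleration maximum. "Acceleration" is the signed rate of change of
2D speed, matching the accelerating/decelerating phrasing of the
criterion. On clean minimum-jerk reaches the onset sits
\(\tau \approx 0.059\) of the duration after the true onset (the root of
\(30\tau^2(1-\tau)^2 = 0.05 \times 1.875\)); recovered reaction times
carry exactly this lag, which the tests confirm against a root-finding
oracle. The feedback metric is the mean 2D speed between the first
crossings of 25% and 75% of the vertical start–target distance (goal
20 cm/s).

Exclusion applies four rules sequentially, each trial attributed to the
first rule it violates so per-rule counts sum to the total: (1) reaction
time below 100 ms or missing eye data; (2) target fixation starting
≥ 100 ms after target appearance; (3) fixation ending ≥ 100 ms before
the condition-specific window end; (4) a detected saccade landing more
than 6 cm from the target. Fixation landmarks, which the rules presuppose
but no method section defines, are: fixation start = first gaze sample
within 6 cm of the target; fixation end = last such sample inside the
window; the window ends at the condition-specific trial end. Planted
violations are constructed to be unambiguous — e.g. fast-RT plants sit
well below 100 ms even after the onset-criterion lag is added — and the
tests require rule-for-rule, trial-for-trial agreement with the plant.

## Rates, zones, statistics

The state-based estimator divides the per-millisecond proportion of
trials with an ongoing microsaccade by the mean event duration (default:
the dataset's own mean detected duration). The causal-kernel estimator
convolves per-millisecond onset counts with
\(\omega(\tau) = \alpha^2 \tau e^{-\alpha\tau}\); \(\alpha = 1/0.05\)
1/s is the customary default for this estimator and is exposed as a
parameter. The kernel is truncated at \(12/\alpha\) (residual mass
\(<10^{-4}\)) and discretised at 1 ms, preserving unit mass to \(10^{-3}\).
Trials of unequal length are handled by normalising each time point by
the number of trials whose window covers it. Both estimators agree within
10% on stationary data and recover the planted profile's zone ordering
(initial fixation > post-inhibition > pre-cue > post-cue dip) in ≥ 95%
of replicates — the tested counterpart of the claim that the two methods
give the same answer. The movement zone is normalised per trial: onset
counts and phase durations are summed per participant and condition
before dividing.

Two printed pre-cue definitions (the 0.25-s analysis window and the
0.1-s inhibition window) are kept as distinct named zones to avoid
ambiguity; pre-cue variants of 0.375 and 0.5 s support the robustness
check across window lengths.

`rm_anova()` fits the classical univariate within-subject ANOVA via
`aov()` error strata. Uncorrected F is the default because sphericity
corrections are often left unreported in this literature; a
Greenhouse–Geisser option computes \(\epsilon\) from the covariance of
the subject-by-cell matrix projected onto each effect's orthonormal
contrast space (clamped to \([1/d, 1]\)). A zero-variance design returns
\(F = 0\), \(p = 1\) rather than 0/0. Post hoc comparisons are pairwise
paired t-tests with Holm correction by default — the post hoc procedure
is a known divergence risk since reports rarely name it, so `"none"` is
available — and compact letter displays are built from maximal cliques
of the non-significant-pair graph. The one-way F equals the squared
paired t for two levels to \(10^{-9}\), and under a null simulator the
test's type-I rate is calibrated at 5% ± 2% over 1000 datasets of 17
participants.

## Problem sizes and limitations

The test and acceptance suites run at deliberately chosen sizes: 100
random traces for detector–oracle equivalence, 200 trials for event
recovery and for each of the 100 zone-ordering replicates (ordering
replicates draw ground-truth onsets directly — the estimators, not the
detector, are under test there), 400 trials for estimator agreement, and
1000 summary-level datasets for the type-I calibration (the ANOVA sees
only participant-by-condition cell means, so nulls are simulated at that
level). Full-scale defaults (17 participants × 240 trials) are the
generator's defaults but are not exercised in the tests.

What passing tests do *not* show: the simulator omits eye-tracker
artefacts other than missing runs (no pupil-size coupling, no
post-saccadic oscillations, no calibration drift), models drift as a
bounded random walk, gives microsaccades a fixed smooth waveform, and
assumes gaze and hand noise are white. Results on real recordings will
additionally depend on those factors, and empirical rate levels, F and p
values are functions of the data, not of the pipeline. The package reads
its own delimited trial format; vendor formats (e.g. ASC) are out of
scope.
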