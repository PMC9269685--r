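---
title: "Measuring wheelchair sitting-pivot transfers with depth sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wheelchair sitting-pivot transfers with depth sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transferkin)
```

## The measurement problem

Manual wheelchair users perform many sitting-pivot transfers (SPTs) a day —
seated lateral moves between the wheelchair and another surface, powered by
the arms and trunk. Poor transfer technique loads the shoulders and is a
known contributor to upper-extremity pain, so clinics want objective,
low-cost ways to score transfer quality. Consumer depth sensors with
marker-less body tracking (Kinect V2, Kinect Azure, RealSense with the
Nuitrack SDK) stream named 3-D joint centers at up to 30 Hz and are a
practical capture device, but each SDK has its own joint vocabulary, noise
behaviour and failure modes. Before one sensor can substitute for another in
a scoring application, their agreement on the kinematic quantities that
drive the scoring has to be quantified.

`transferkin` implements that comparison pipeline end to end:

1. **I/O** — per-sensor CSV recordings (`read_recording()`,
   `write_recording()`), timestamp alignment of simultaneously recorded
   pairs (`align_pair()`).
2. **Harmonization** — each vocabulary is mapped onto five canonical
   joints: pelvis, upper spine, both shoulders, leading elbow
   (`harmonize()`).
3. **Segmentation** — the lift phase is delimited on the low-pass-filtered
   pelvis trajectory (`detect_phases()`).
4. **Features** — four lift-phase scalars per trial (`extract_features()`).
5. **Statistics** — intraclass correlations, Bland–Altman limits of
   agreement, percent agreement and confusion accuracy
   (`icc()`, `bland_altman()`, `percent_agreement()`,
   `accuracy_vs_truth()`).
6. **Simulation** — a synthetic transfer generator with closed-form ground
   truth (`simulate_trial()`, `simulate_session()`) that makes every stage
   testable without human recordings.

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write their tables under `results/`.

## Coordinate conventions and harmonization

Coordinates are camera-frame millimetres with **y vertical up** and **x
horizontal along the transfer direction**; recordings captured in another
frame must be pre-rotated. All internal arithmetic stays in millimetres;
only the displacement feature is reported in centimetres.

The five canonical joints map directly on the V2 (`SpineBase`,
`SpineShoulder`, shoulders, elbow). The Azure has no joint at the V2's
`SpineShoulder` location, so the upper spine is approximated by the midpoint
of the two clavicle joints. For the RealSense/Nuitrack vocabulary we adopt
the same collar-midpoint rule for the top of the trunk. **This is an
assumption**: the Nuitrack vocabulary provides left and right collar joints
but no canonical combining rule, and we choose the rule symmetric with the
Azure's. A derived joint is valid only when every source joint is tracked.

Transfers leading with the right arm are handled by mirroring the
shoulder/elbow mapping (`side = "right"`); all angles are unsigned, so
mirroring does not change their definitions.

## Lift-phase segmentation

The pelvis x-trajectory of a transfer is plateau — rise — plateau: sitting,
lifting across, landed. Features are computed over the rise (the *lift
phase*) only. The series is linearly gap-filled (a missing run longer than
0.5 s aborts the trial: a sensor that lost the pelvis for half a second
cannot be segmented trustworthily), sign-normalized so the transfer runs in
+x, and low-pass filtered with a 4th-order Butterworth filter applied
forward–backward. Zero-phase filtering matters here: a single-pass filter
would lag the plateau edges and bias both indices late (a single-pass mode
is available via `zero_phase = FALSE` for sensitivity checks). The filter
uses odd-reflection end padding with steady-state initial conditions, so a
constant segment passes through exactly.

The nominal cutoff is 15 Hz. At the sensors' 30 Hz frame rate that sits at
the Nyquist frequency, where a low-pass filter is undefined;
`detect_phases()` therefore clamps the effective cutoff to `0.45 * rate`
(13.5 Hz at 30 Hz), the closest realizable design. `lowpass_filter()`
itself requires `rate > 2 * cutoff`.

The phase boundaries are "the last point still at the sitting level" and
"the first point at the landing level". We estimate the two levels as
medians of the frames in the bottom / top 20% band of the displacement
(robust to jitter and to the skew of noisy extrema), and place the
boundaries at the last/first crossing of a noise-adaptive threshold above/
below those levels: `3 x MAD` of the plateau residuals, floored at 0.2% of
the rise. A prominence-gated extremum rule was considered and rejected: on a
noisy plateau the running minimum is a ~2.5-sigma outlier at an arbitrary
position inside the plateau, so "the last minimum" does not localize the
plateau edge, while the level-crossing rule pins it to about one frame.
Guards: net displacement below 100 mm is "no transfer"; a strictly monotone
series has no plateaus and errors out.

Properties verified in the test suite: time-shift equivariance (prepending
k constant frames shifts both indices by exactly k), amplitude invariance,
direction handling, and index error at most 3 frames for 95% of seeds under
5 mm per-coordinate jitter.

## The four features

With trunk vector `t` (pelvis to upper spine), shoulder-across vector `a`
(left to right shoulder) and chest normal `n = t x a`, over lift frames
`[start, end]` (both endpoints included):

* **DSWP** (cm) — pelvis travel along x: `(x[end] - x[start]) / 10`, on the
  **raw** series. Filtering is used only to find the indices; all feature
  values come from unfiltered data.
* **TF** (degrees) — mean per-frame angle between `t` and the vertical
  y-axis.
* **LE** (degrees) — mean per-frame angle between `t` and the leading
  upper-arm vector (shoulder to elbow).
* **LPOE** (degrees) — mean per-frame angle between the projections of `n`
  and the upper-arm vector onto the transverse plane.

The transverse plane is taken **body-referenced** (normal = trunk vector),
i.e. the anatomical transverse plane defined by the same basis that defines
the chest normal; `transverse = "lab"` projects onto the lab horizontal
instead for sensitivity analysis. Angles are unsigned in [0, 180] —
magnitudes are what the reliability analysis consumes — so no signed
plane-of-elevation convention is attempted. Frames missing a joint are
dropped from that feature's mean only; the dropped fraction is reported and
a trial losing more than 25% of frames for any feature is flagged low
quality. An arm parallel to the trunk makes the LPOE projection degenerate
and that frame is skipped with the same accounting.

Invariances asserted by tests: all angle features are invariant to global
translation and uniform scaling; LE and LPOE are invariant to arbitrary
global rotations; TF is not (it references the lab vertical) but is
invariant to rotations about the vertical axis.

## Reliability statistics

Per-trial features feed two intraclass correlations, both single-measure,
computed from the two-way ANOVA mean squares (between-targets MSR,
between-raters MSC, residual MSE; n targets, k raters):

* **Inter-sensor, ICC(2,1)** — two-way random effects, absolute agreement:
  `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, targets = pooled
  trials, raters = sensors, complete-case pairing. A systematic offset
  between sensors lowers it.
* **Intra-sensor, ICC(3,1)** — two-way mixed effects, consistency:
  `(MSR - MSE) / (MSR + (k-1) MSE)`, targets = subjects, raters = trial
  repetitions (subjects truncated to the common minimum count, with a
  warning).

A note on the ICC(3,1) form: in the McGraw–Wong taxonomy the
absolute-agreement single-measure estimator is numerically identical under
random and mixed models, which would make the two ICCs coincide and defeat
the purpose of reporting both. We therefore use the classical consistency
form for ICC(3,1) — the definition under which "ICC(3,1)" is usually cited
— and the absolute-agreement form for ICC(2,1). The documented and
test-verified consequence is that a pure rater offset leaves ICC(3,1)
untouched while depressing ICC(2,1). Confidence intervals are exact F-based
(consistency) and Satterthwaite F-based (absolute agreement); point
estimates and intervals are cross-checked in the tests against an
independent ANOVA oracle and against reference values from an external
implementation.

ICC categories: excellent (> 0.8), good [0.6, 0.8], moderate [0.4, 0.6),
fair [0.2, 0.4), poor (< 0.2). The source bands leave the exact boundaries
ambiguous except for the strict "> 0.8"; we resolve them as lower-bound
inclusive, which keeps the one strict inequality and makes
`categorize_icc()` a total monotone step function.

**Bland–Altman**: for paired differences `d = a - b`, limits are
`m -/+ 1.96 s` with `m` the mean and `s` the n-1 sample SD; the two methods
are called interchangeable when at least 95% of differences fall within the
limits. `bland_altman()` returns the per-pair (mean, difference) data for
plotting.

**Score agreement**: binary transfer-quality item scores (1 = proper,
0 = improper; the 11 modeled items are 1, 2 and 7–15) are compared between
sensors by per-item percent agreement, and against ground truth by
per-(item, transfer-type) confusion accuracy. The ground-truth generator
zeroes the targeted item of each deliberate technique error: feet off the
floor -> item 7, no trunk lean -> item 13, leading arm too far out -> items
9 and 12 (arm position is scored both before and after the transfer), fist
grip -> item 11. Whether the fist condition should also zero the push-off
grip item 10 is genuinely open; the default zeroes item 11 only and the
mapping is overridable.

## The synthetic transfer generator

No public recordings of instrumented SPTs exist at the scale the tests
need, so the package ships a generator whose outputs have closed-form
truth. It is a minimal rigid-segment model — pelvis, trunk (500 mm),
shoulder girdle (180 mm half-width, clavicles at 40 mm), leading upper arm
(300 mm) — **not** a biomechanically validated human model. It emulates
exactly the structure the statistics assume:

* pelvis x follows plateau / linear ramp / plateau with short C1
  smoothstep corner blends (half-width 5% of the lift, at least one
  frame). A fully smooth sigmoid ramp was rejected: its slope vanishes
  over many frames at the corners, making the plateau boundary physically
  ill-defined at the frame level at which segmentation is validated;
* angle profiles are raised cosines over the lift window with prescribed
  lift-phase means (TF ~31 deg, LE ~45 deg, LPOE ~84 deg by default) and
  modest excursions, continuous and flat at the window edges;
* default pelvis travel is 477.5 mm (DSWP 47.75 cm), lift duration 1 s
  between 2 s plateaus, 30 Hz;
* sensor artefacts: per-coordinate Gaussian jitter, per-joint dropout
  flags, constant per-joint bias, and a pelvis tracking lag (rendered by
  evaluating the pelvis trajectory `lag` seconds in the past), emulating
  the documented tendency of older sensors' pelvis estimates to trail the
  body;
* sessions draw subject-level feature means (between-subject SD defaults:
  5.2 cm, 5.3, 5.0, 7.0 deg) and per-trial deviations (1.5 cm, 1.6, 1.5,
  2.1 deg), chosen so that pooled SDs sit at realistic magnitudes and
  test-retest ICCs land around 0.9 for a clean sensor. RNG substreams are
  split per (subject, trial, sensor), so adding a sensor never perturbs
  existing trials, and everything is bit-reproducible from one seed.

What passing tests on this generator **does** show: the pipeline recovers
known kinematics through every stage (noiseless recovery better than 1 deg
/ 0.5 cm over a 100-profile sweep), the segmentation is frame-accurate
under realistic jitter, and the reliability estimators recover designed
variance ratios (within 0.03 at 500 subjects). What it does **not** show:
robustness to the artefacts the generator does not model — correlated
tracking errors, occlusion-induced systematic pose distortion, soft-tissue
and clothing effects, subject-specific anthropometry. Conclusions about
real sensors still require real paired recordings.

One instructive artefact of small cohorts reproduces readily: with 7
subjects the empirical between-subject spread of a feature can deviate
substantially from its generating value (a draw of 7 from an SD-7
distribution can easily show an SD of 2), dropping the apparent
test-retest ICC for that feature into the "moderate" band even though the
sensor is clean — visible in the shipped `analysis/` run for TF. This is
sampling variability of the design, not a pipeline defect, and it is why
the parameter-recovery acceptance checks run at n = 500.

## Numerical choices and problem sizes

* Timestamp pairing tolerance defaults to half the nominal frame period;
  pairing is mutual-nearest-neighbour, which is symmetric and never reuses
  frames. A constant clock offset between sensor laptops can be supplied
  explicitly (`offset`) rather than guessed.
* CSV round-trips write 17 significant digits, so sequences survive
  write/read bit-identically.
* `acos` arguments are clamped to [-1, 1]; zero-length vectors raise
  degenerate-geometry errors rather than returning NaN.
* Sample SDs use n-1 throughout. ICC matrices must be complete; the
  pipeline pairs complete cases upstream.
* Default problem sizes keep the full suite and the acceptance script
  within a few minutes on one core: 100-profile recovery sweeps,
  100-seed segmentation batteries, 500-subject feature-level sessions
  (the feature-level path skips skeletal rendering but exposes the same
  variance structure), and a rendered 7 x 10 x 2 demonstration session.

## Known limitations

* The RealSense upper-spine rule is an assumption (see above).
* SPSS conventions for mixed-model ICC confidence intervals are not
  bit-matched; intervals follow the published F-based formulas.
* One recording is assumed to contain exactly one transfer; continuous
  multi-transfer recordings must be split upstream.
* The generator's improper-technique kinematics are stylized (reduced
  trunk lean, abducted arm); feet and fist errors do not move the five
  modeled joints at all and exist only in the score tables.
* Simulated classifier predictions are independent per-item bit flips of
  the ground truth; real classifier errors are correlated with the
  kinematics and across items.
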