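---
title: "Models and methods: subfield coincidence coding and pointer-alignment trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tactcode)
```

This vignette documents the two computational components of `tactcode`: a
population model of first-order tactile neurons that measures how well a
binary coincidence code can signal the orientation of an edge contacting the
fingertip, and an event-detection pipeline for force and dial-orientation
traces from tactile pointer-alignment trials, driven by a synthetic trial
generator that carries ground truth.

## 1. The virtual fingertip

A patch of skin (default 2 x 2 cm) is innervated by model afferents
("units").  Receptive-field (RF) centers are placed uniformly at random, one
at a time, until the mean distance from each center to its six nearest
neighbours first falls to the target spacing of 1 mm (tolerance 0.02 mm),
reproducing the innervation spacing of human fingertip afferents.  The
stopping statistic is evaluated incrementally over all placed units,
including those near the patch border; border units have inflated 6-NN
distances, so the interior is slightly denser than the nominal figure.  On
the default patch this yields roughly 380-400 units.

RF sizes are drawn from a log-normal distribution with log10-scale mean 1
and SD 0.45.  The physiological convention for that distribution describes
RF *areas* in mm^2 (median 10 mm^2, i.e. a median RF diameter of about
3.6 mm), and that is the package default
(`fingertip_config(rf_size_interpretation = "area")`).  Because the
alternative reading — the same log-normal describing RF *diameter* in mm —
cannot be excluded from the distribution parameters alone, it is available
as a config switch for sensitivity analysis.  Under the diameter reading the
median RF is 10 mm wide; plate-like RFs that large almost never change state
while a 1 mm edge rotates, so most runs produce no threshold at all for
short edges in the uniform model.  We therefore regard the area reading as
the only self-consistent one and keep it as the default.

Each unit carries receptor elements, and the package builds two paired
variants of every fingertip:

* **subfield variant** — between 2 and 64 elements (discrete uniform), each
  250 microns in diameter.  The first two are placed at antipodal points of
  the RF boundary (a random diameter direction); the rest are uniform on the
  RF disk.  Elements may overlap; no exclusion rule is applied.
* **uniform variant** — exactly one element per unit whose center and radius
  coincide with the RF itself, giving a plate-like field of uniform
  sensitivity.

A paired (`build_fingertip()` + `make_uniform_twin()`) pair shares RF
centers and radii unit for unit; only the element layout differs.  The RNG
contract is one root seed with a child seed per fingertip, so paired
variants and repeated edge lengths reuse identical geometry.

## 2. Edge stimuli and activation

An edge is a line segment: center, length, orientation (degrees,
counter-clockwise, reduced modulo 180 since a segment is symmetric under
half-turns).  The apparatus edge spanning the whole contact surface is
represented as a 44 mm segment; on a 20 mm patch this exceeds the diagonal,
so it behaves as an unbounded line ("infinite" edge).  Length 0 is the
raised dot, a degenerate point segment.

Activation is binary and strict: an element is active iff the Euclidean
distance from its center to the segment is smaller than the element radius;
a unit is active iff any of its elements is.  For the uniform variant the
element radius equals the RF radius, so activation means the edge enters the
RF disk.  The strictness of the inequality is a measure-zero choice with no
practical effect, and is asserted as such in the tests.

## 3. The coincidence-code experiment

For an edge centered on the patch, the population's initial activation
vector is recorded, the edge is rotated about its center in 0.5 deg steps
(one direction; the search stops at 180 deg by symmetry), and the
discrimination threshold is the smallest rotation at which the Hamming
distance from the initial vector reaches 5% of the contactable pool N_c —
the units that could be activated by *some* orientation of the edge.  N_c is
computed analytically (an element is reachable iff its distance to the
rotation center is below half the edge length plus the element radius) and
cross-checked in the tests against a dense 0.1 deg rotational sweep.  The
criterion is evaluated in real arithmetic (no rounding of 5%); stimuli whose
activation never changes enough — notably the dot, which is rotation
invariant — report `NA`, never a coerced angle.

`run_paired_experiment()` repeats this for 100 paired fingertips per edge
length (defaults: 1, 2, 4, 8, 44 mm) and summarizes means with normal
approximation 95% confidence intervals (mean +/- 1.96 SD/sqrt(n)); the CI
construction is a package choice, as is the counter-clockwise search
direction.  `NA` outcomes are excluded from means and counted; a length
where more than half the repetitions yield `NA` is refused rather than
summarized.

Two properties of this geometry are worth knowing.  First, the mean
threshold is nearly invariant to innervation density, because both the
criterion count (5% of N_c) and the state-flip rate scale together with
density; the threshold instead reflects the ratio of pool size to flip rate
fixed by the stimulus geometry.  Second, the threshold is not strictly
monotone at the long-edge end: for the 44 mm edge the contactable pool is
the entire patch while the patch truncates the edge's sweep, so the
criterion count grows faster than the flip rate and the mean threshold
rises slightly between the 8 mm and the 44 mm edge.  The acceptance
experiment measures this; it is a property of the stated geometry (bounded
patch, over-long edge, pool normalization), not of the implementation.

## 4. Trial traces and the event pipeline

The pipeline consumes 1 kHz force (N) and dial-orientation (deg, target at
0) traces with go-time, shutter-opening time, initial orientation and edge
length as metadata.

**Triangular filters.** All smoothing uses zero-phase symmetric triangular
FIR kernels with reflection padding.  A kernel is specified by its cutoff;
the integer half-width is chosen so the gain at the cutoff is as close as
possible to the -3 dB value, erring if no width achieves 0.707 +/- 0.02.
The achievable -3 dB frequencies of integer-width kernels at 1 kHz are
spaced several percent apart, so the gain at the cutoff — not the -3 dB
frequency itself — is the design criterion.  The first-order low-pass used
by the apparatus emulation (10 ms time constant, per-sample coefficient
1/11) has its corner at 1/(2 pi tau), approximately 16 Hz, which validates
the cutoff convention.

**Events.**

* *Touch*: baseline is the median force over the 500 ms before the go
  signal; the first sample whose force exceeds 0.2 N anchors a backward
  search to the last sample at or below baseline + 0.01 N; touch is the
  next sample.  The forward 0.2 N search makes brief pre-contact blips
  harmless.
* *Force plateau*: force rate is the symmetric +/-1-sample derivative of
  the 8.7 Hz-filtered force; the maximum local rate peak within 50-350 ms
  after touch (ignoring peaks below a configurable noise floor, default
  0.05 N/s) anchors a forward search for the first sample below 10% of the
  peak.  The window excludes the initial impact transient and late
  adjustments.
* *Velocity and speed peaks*: orientation is filtered at 17 Hz and
  differentiated symmetrically; speed is its absolute value, smoothed at
  8.7 Hz for peak finding; peaks are negative-slope zero crossings of the
  speed derivative, ignoring peaks below 10 deg/s (the online movement
  criterion).
* *Segmentation*: the rotation is delimited by minima of the high-passed
  speed (speed minus its 2.1 Hz low-pass; "identity minus low-pass" is the
  package's reading of the high-pass topology).  Only movement-scale minima
  count: local minima deeper than 2 deg/s below zero, with plateaus
  resolved to their earliest sample; shallower ripple is noise.  Onset is
  the first such minimum searching backwards from the first speed peak.
  The end is the first such minimum after which the speed never again
  exceeds 10 deg/s before the shutter opened; minima followed by renewed
  movement separate successive sub-movements.  Speed peaks within 200 ms of
  the shutter opening (or after it) are discarded, because the shutter
  opens 200 ms after the rotation settles and later activity is visually
  guided correction.  This terminal-minimum formulation is equivalent to
  "the second and last minimum" on single-peak trials and remains
  well-defined when overlapping sub-movements merge into a single broad
  speed peak with an interior dip; a literal "last minimum more than
  200 ms before the shutter" rule would exclude its own end minimum on
  idealized kinematics, because the end minimum falls a few milliseconds
  *after* the online speed crossing that starts the 200 ms shutter hold.
* *Measures*: the alignment error is the orientation at the rotation end;
  displacement is final minus initial orientation signed so that positive
  means motion towards the target; zero displacement counts as incorrect
  direction; trials whose online-rule onset latency reaches 350 ms are
  flagged aborted and excluded from summaries.

**Summaries.** Per-participant medians of |error| and per-participant
proportions of correct direction are computed first and then averaged
across participants (mean +/- SEM); the aggregation order is asserted in
the tests.  Log transformation of |error| and arcsine-sqrt transformation
of proportions are available for parametric analysis.  The 75%-correct
edge-length threshold interpolates the mean proportion linearly in length
(mm) over the finite lengths; a proportion profile entirely above 0.75 is
reported left-censored at the smallest length, one never reaching 0.75 is
undefined.

## 5. The synthetic trial generator

`generator_config()` defaults encode the task statistics the pipeline
assumes: rotation onset 0.20 s after touch (between-participant SD 0.02 s,
within 0.05 s), plateau force 1.64 N (between 0.83 N, within 0.30 N chosen
by the package), rise to plateau 0.31 s (SD 0.09 s), sub-movements in 44%
of trials starting 0.22 s after onset, six edge lengths x six initial
orientations (+/-10, 20, 30 deg) x 18 repeats for each of 10 participants,
a +/-38 deg pointer range, and the online shutter rule (first-order
low-passed speed below 10 deg/s for at least 200 ms).

Force rises in a fast 10 ms contact step to 0.06 N (the impact toe that
makes contact observable at the sensor within a few milliseconds) and then
follows a minimum-jerk ramp to the plateau.  Rotations are minimum-jerk
displacement profiles — the canonical single-peak velocity shape — with
durations of 0.25 s plus 4 ms per degree of amplitude, in the range of the
observed rotation durations.  Sub-movement trials split the displacement
into two overlapping components (first fraction uniform on 0.4-0.7), the
second starting ~0.22 s after onset; a split is only emitted when both
components exceed 3 deg, because a component whose peak speed stays below
the 10 deg/s floor would be unobservable by the velocity-peak criterion
that defines sub-movements in the first place.

The per-length outcome model is parameterized by the target median |error|
and probability of correct direction; defaults taper from ~3 deg and ~100%
correct at the full-contact edge to chance direction for the dot, with the
2 mm edge at 75% correct so the implied direction threshold sits at 2 mm.
Correct-direction trials end at a Normal(0, sd) orientation truncated to
the toward-target side (so the direction label always matches the realized
displacement), with sd solved from the target median; wrong-direction and
dot trials move ~15 deg away from (or with random sign around) the start,
clipped at the pointer range.  `implied_measures()` evaluates this outcome
model directly (no traces) and is the reference for the calibration-closure
tests.

Sensor noise defaults are at the quantization scale of a 16-bit recording
chain (force SD 0.002 N, orientation SD 0.005 deg).  White orientation
noise much larger than this is not physically meaningful at 1 kHz — a
0.05 deg per-sample white noise would alias into tens of deg/s of velocity
noise and defeat any 10 deg/s movement criterion, including the
apparatus' own online rule.

Ground-truth onset and end use the standard 5%-of-peak-speed kinematic
convention evaluated on the noiseless trace (for the end, 5% of the final
component's own analytic peak): a minimum-jerk profile has zero velocity,
acceleration and jerk at its formal start, so the formal start is not an
observable event; the latency parameter nevertheless controls the formal
component start.

**What the generator does not emulate.** Real traces contain drift,
tremor, corrective micro-adjustments after the shutter opens, per-
orientation over/undershoot structure (supported but off by default),
force-orientation coupling, and participant-specific kinematic styles.
Passing recovery and calibration tests therefore shows the pipeline is
correct and well calibrated for data with the *stated* structure, not that
it is robust to every property of human recordings.

## 6. Problem sizes and runtime choices

The test suite uses fingertips on the default 2 x 2 cm patch (several
hundred units, ~13,000 elements), 100 paired fingertips per edge length for
the population experiment, 50 fingertips for the analytic-vs-sweep pool
cross-check, one 648-trial noiseless dataset for parameter recovery, and
the full 10-participant (6,480 trial) default dataset for calibration
closure.  These sizes keep the full suite in the minutes range on one CPU
while leaving the experiment at its full published scale.

## 7. Known limitations

* The population model reproduces the qualitative ordering (subfields beat
  uniform fields everywhere; the advantage grows as edges shorten) and the
  threshold scale, but not the exact published endpoint means; the
  parameters stated for the model leave its length-dependence shallower
  than reported, and no documented parameter choice (RF-size reading,
  placement density, element placement) moves it materially — the
  acceptance experiment records the discrepancy rather than hiding it.
* The slight threshold upturn from the 8 mm to the 44 mm edge (section 3)
  is inherent to normalizing by the contactable pool on a bounded patch.
* Event detection assumes one rotation episode per trial; trials whose
  movements never exceed 10 deg/s are reported unanalyzable rather than
  guessed at.
* The generator's outcome model is Normal-about-target per length; real
  error distributions are heavier-tailed with orientation-dependent bias.
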