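---
title: "Methods: Y-maze navigation, gaze dwell, and strategy inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-maze navigation, gaze dwell, and strategy inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ymazenav)
```

## The experimental paradigm this package models

`ymazenav` analyzes immersive virtual-reality Y-maze experiments in which a
subject learns a route from a fixed departure arm (A) to a goal arm (C) and
is then released, without feedback, from the third arm (B). The first
endpoint the subject reaches on these probe trials reveals the reference
frame of its spatial memory: reaching C requires a world-anchored
(allocentric) representation, while repeating the learned body turn lands
the subject in A (an egocentric response). Two maze variants dissociate the
cues supporting the allocentric solution: a *landmark* maze, equiangular
(arm separations of 120°, corridors 1.90 m long) and polarized only by
three distal landmarks (a star, a square and a circle) hung above the
walls; and a *geometry* maze with no landmarks, polarized instead by an
anisotropic arm layout (separations 50°/155°/155°, corridors 2.30 m long).
Corridors are 0.66 m wide in both variants and the walls are individually
sized to each subject's height plus 0.10 m, so nobody can peek over them.

Two data streams drive every analysis: a 30 Hz head-pose stream (position
and heading from the headset tracker) and a 120 Hz binocular gaze stream
(per-eye unit directions with validity flags from the eye tracker).

## Maze geometry and the gaze ray-caster

The maze model places the maze center at the origin with the floor at
z = 0, azimuths counter-clockwise from +x, and (by default) the goal arm C
at azimuth 90°. The paradigm fixes the physical dimensions; the frame
conventions are ours and are configurable through `build_maze()` overrides.
Decisions the paradigm leaves open, resolved here once:

* **The 50° pair.** Only the magnitude of the small separation is fixed by
  the design; which two arms it separates is not. Default: the two
  non-goal arms A and B, configurable (`fifty_pair`).
* **Landmark azimuths.** Each landmark is placed diametrically opposite the
  arm it "faces", so it stands straight ahead of a subject at that arm's
  end looking toward the center: the circle faces A (the learning
  departure), the star faces B (the probe departure), the square faces C.
* **Arm-end walls.** Corridors are closed at their far ends by walls of the
  same height, since subjects stop *at* arm ends rather than walking out.
* **Junction shape.** The central junction is the convex hull of the six
  inner wall-corner points (where adjacent corridors' facing walls meet);
  the paradigm never defines the junction polygon.
* **Eye height.** Viewpoint-dependent quantities (gaze-ray origin, landmark
  sizing) use subject height − 0.10 m by default, configurable; no eye
  height is prescribed by the protocol.

`cast_gaze_ray()` classifies a gaze direction by the nearest intersection
with the wall panels (up to wall height), the floor plane, or — if the ray
clears every wall — a sky sphere of radius 6 m about the maze center. Sky
hits in the landmark condition carry a landmark-centered *sector* label:
sector boundaries are the angular bisectors between adjacent landmark
azimuths, and a direction exactly on a bisector is assigned to the
counter-clockwise neighbor (an arbitrary but fixed tie-break; ties have
measure zero in real data). The ray-caster is validated in the test suite
against an independent oracle that finds crossings by dense sign sampling
and bisection rather than algebra, with disagreement tolerated only within
1 mm of a panel edge, where the label is not well defined numerically.

Landmarks are specified by the visual angle they subtend (10°) from the
maze center; `landmark_physical_size()` converts this to a physical
diameter d = 2·s·tan(5°) at slant distance s. Whether the reference
viewpoint sits at floor level or eye height is not prescribed; we use eye
height at the center, and the choice moves the diameter by well under 1%.

## Navigation measures

`segment_trial()` splits each trial at the moment the subject exits a 0.3 m
circle around the departure position: before it, the *orientation* period
(the subject looks around and self-localizes); after it, the *navigation*
period. The seven per-trial measures are the two period durations, their
sum (escape latency), traveled distance (summed successive displacements),
average speed, speed normalized by subject height (walking speed scales
with body height, and the cohorts span children and adults), and time in
the *central area* — the junction polygon plus the inner third of each
corridor. Zone entry is evaluated on the raw 30 Hz samples without
interpolation: with 0.3–0.4 m zones and human walking speeds a zone cannot
be skipped between samples. An optional low-pass position filter
(`compute_metrics(position_filter=)`) is available because head sway
inflates path length; it is off by default.

Strategy classification: a probe trial is allocentric if the first 0.4 m
endpoint disk entered is C's, egocentric if A's, and unclassifiable
otherwise (including first returning to the start arm B). The departure
position lies inside the start arm's own endpoint disk, so the initial
occupancy of that disk is ignored; *re-entering* it later counts. A subject
is allocentric with ≥ 2 allocentric probes out of the three B-start probes,
egocentric with ≥ 2 egocentric, and unclassifiable when unclassifiable
trials block a majority either way — such subjects are excluded from
behavioral and gaze analyses by default (`cohort_table(drop_unclassifiable
= FALSE)` keeps them, e.g. for pooling with the egocentric group in
profiling analyses). The protocol does not specify how partially
unclassifiable triplets resolve; the majority rule above is our documented
choice.

A learning trial succeeds when the goal is reached without entering arm B;
re-entering the start arm A is allowed by the stated rule.
`trials_to_criterion()` counts trials to the first run of four consecutive
successes.

## Gaze pipeline

`fuse_streams()` interpolates the head stream to the gaze timestamps
(linear for position, shortest-arc for heading — equivalent to spherical
interpolation for a heading-only orientation), combines the eyes with
`cyclopean()` (renormalized mean when both valid; single-eye fallback;
missing when neither — upstream validity flags are trusted, as the
eye-level noise judgment is made by the tracker), and rotates gaze into the
world frame. Fixations and saccades are deliberately *not* separated; no
velocity filtering is applied.

Dwell proportions are fractions of non-missing gaze time on walls, floor
and sky (missing samples leave the denominator, so the three sum to 1; sky
sector proportions sum to the sky proportion). The binned time course maps
the orientation period to 15 and the navigation period to 35
equal-duration bins — i.e., time-normalized within each period, since the
bin counts are fixed but the mapping for variable-duration periods is not;
each bin's value is computed over a 1 s window centered on the bin midpoint
and clipped at the period edges, which blurs bin-to-bin structure by about
half a window. Heatmaps accumulate hit points on a grid (azimuth ×
elevation at 2° for the sky, x × y at 0.1 m for the floor — grid choices
are ours) and are normalized by the maximal cell count.

The classifier feature is the mean gaze elevation relative to eye level
over the non-missing orientation-period samples of probe trials
(`mean_orientation_altitude()`).

## The synthetic cohort

Because the pipeline must be verifiable without access to cohort data, the
package ships a seeded agent simulator whose outputs have the statistical
structure the analysis assumes. Each agent has a strategy type
(egocentric; allocentric map-based; allocentric view-matching, which
pauses at the junction and re-fixates the circle — the landmark that stood
ahead during learning), a per-trial probability of an allocentric probe
choice, a learning error rate, walking-speed and pause distributions,
state-dependent gaze-elevation distributions, and a gaze missingness rate.

Trajectories are constant-speed polylines with rounded junction corners
and low-frequency positional sway (white noise moving-average filtered
over 1 s, amplitude 5 mm — i.i.d. jitter at 30 Hz would masquerade as
locomotion). Gaze is generated by a three-state machine: during the
orientation pause, allocentric agents in the landmark condition fixate the
sky sector of the landmark facing the start arm while all other agents
look down toward the junction floor; during navigation all agents look at
the walls ahead; view-matchers fixate the circle sector during their
junction dwell. Missingness is i.i.d. Bernoulli per sample by default,
with an optional two-state Markov burst mode (mean burst 8 samples) since
real blink losses are bursty; both modes satisfy the target overall rates.

Default parameters are package choices selected to reproduce the
qualitative pattern the pipeline is designed to detect, not measured
values: missingness 22% (young), 27% (older), 25% (children); walking
speeds around 0.6–0.85 m/s; orientation pauses of 2–4 s; gaze elevations
of +28° (sky orientation), −22° (floor orientation), −4° (wall-directed
navigation); view-match junction dwell around 8 s. Trial ends mirror the
protocol: learning trials end on goal entry, test trials after a 5 s stop
inside an endpoint disk.

What the simulator does **not** emulate: biomechanical gait, rendering- or
saliency-driven gaze, vestibular disorientation effects, drift or
calibration error in the trackers. Tests passing on simulated cohorts
certify the analysis logic (segmentation, geometry, classification,
statistics) under known ground truth; they do not certify robustness to
artifacts absent from the generator.

## Statistical layer

The age × condition analysis of the binary majority-allocentric outcome is
a binomial GLM with logit link and full interaction. The design is
saturated, so fitted cell probabilities equal observed proportions; the
package reports them from the cell counts directly, which also keeps them
exact when a cell is at 0 or 1 and the ML coefficients diverge. The
interaction is summarized by probability-scale *second differences*: for a
group pair (g₁, g₂), Δ = [P(g₁, geometry) − P(g₁, landmark)] −
[P(g₂, geometry) − P(g₂, landmark)]. The delta-method standard error
reduces, for the saturated model, to √(Σ p(1−p)/n) over the four cells;
cells at 0/1 contribute zero variance there, so a subject-resampling
bootstrap is provided as an alternative (`se_method = "bootstrap"`).

Contingency comparisons use Fisher's exact test with the conditional-ML
odds ratio (one-sided intervals of the form [L, ∞) when the caller states
a directional alternative — the direction is never auto-detected), φ, and
Cohen's w (= |φ| for a 2×2 table). Rank tests report r = z/√N with z from
the tie- and continuity-corrected normal approximation, N the total sample
size. Two-factor ANOVAs report main effects, the interaction, and
Bonferroni-corrected simple effects. The power analysis inverts the
noncentral chi-square distribution: smallest N with power ≥ target at
noncentrality N·w². The degrees of freedom are an explicit argument with
default 2, the value implied by a 3-group × 2-outcome contingency design.

The gaze-altitude classifier is a single-predictor logistic regression
with a 0.5 decision threshold, validated two ways: repeated 25% hold-out
(1000 repetitions by default; the reported p-value is the fraction of
repetitions classifying fewer than half of the held-out subjects
correctly) and leave-one-out. Hold-out splits are stratified by class by
default (whether the original procedure stratified is unknown;
`stratified = FALSE` gives the alternative, with class-absent splits
re-drawn and counted). Note that repeated hold-out within one dataset
measures that dataset's internal consistency: with chance-level features
its expected accuracy is 0.5 only on average over datasets, while any
single dataset's accidental feature–label correlation shifts it — the
tests average over replicate datasets for exactly this reason. Bayes
factors are out of scope and reported as not computed.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of up to 200
subjects per cell at the trajectory level (with the gaze stream generated
only where a gaze analysis consumes it) and 100 replicate cohorts at the
choice level for interaction-recovery checks; the ray-caster is checked
against its oracle on 10⁵ random rays per run. Degenerate inputs are
flagged rather than silently zeroed: trials that never leave the start
have undefined distance/speed, all-missing gaze streams have undefined
dwell proportions, Wilcoxon tests on all-zero differences are marked
degenerate, and leave-one-out folds that empty a class are flagged.

## Known limitations

* The simulator's trajectory and gaze models are deliberately simple;
  effect sizes measured on simulated cohorts characterize the pipeline,
  not human behavior.
* Second-difference p-values rely on the normal approximation of the
  delta method; for very small cells, prefer the bootstrap.
* Sketch scoring consumes structured sketch records; it does not interpret
  drawings.
* Ingestion of external datasets is a schema-driven adapter
  (`read_trials()`); no importer for proprietary tracker logs is provided.
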