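---
title: "Models and methods behind dodgegaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dodgegaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dodgegaze` is a synthetic test bed for gaze-based analyses of action
control: it simulates an obstacle-dodging task with motor perturbations,
generates binocular gaze with known structure, runs the detection /
classification / measurement stages, and fits the mixed models that a
study of this design would fit. This vignette explains the models, the
parameters that matter, and the design choices made where the design was
genuinely open. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## The task simulator

The environment is a 720-px-wide corridor of 9000, 13,500 or 18,000 px.
The 36-px ship falls 6 px per logical frame at an exact 60-FPS clock
(real-time frame-duration jitter is deliberately not modeled). A key
press moves the ship 6 px sideways; under *input noise* the step is drawn
from Normal(6, σ) px and applied signed as-is, so extreme draws can
momentarily move against the key — the simplest reading of a sampled
step. *Drift sections* span 270 px vertically and push the ship 3
px/frame; membership is evaluated on the ship's top edge within
`[y_start, y_start + 270)`, which makes a full uncontrolled traversal
last exactly 45 frames and accumulate exactly 135 px. (Testing membership
on any overlap of the 36-px sprite would instead give 51 frames / 153 px;
we use the top-edge rule so the closed form holds exactly.)

Collision uses half-open 36-px pixel boxes (abutting sprites do not
collide); touching either wall crashes the ship. Layout generation
scatters obstacles uniformly; two completability guards reject and
resample a layout: some vertical position with no collision-free column,
and obstacles over the spawn column in the first 360 px (the entering
ship cannot steer yet, so such a layout would crash unavoidably).
Entry-phase collisions are not checked for the same reason; control-phase
collisions end the trial.

The screen shows a 1920×1080 window with the ship fixed at top-left
(954, 270) and a 270-px occluder at the bottom; objects are visible while
their box intersects the top 810 px. With relative speed 6 px/frame an
object is on screen for (810 + 36)/6 = 141 frames (2.35 s) — close to the
task's commonly quoted "roughly 2.45 s", which corresponds to counting
two extra sprite heights at the boundaries.

## Scripted players

The agents exist to give every downstream stage inputs and to make
completion probability sensitive to the manipulations — not to model
human cognition. The greedy gap policy plans from the state predicted
once its queued keys land — a 6-frame reaction lag without systematic
overshoot, with the drift accumulated over the queue window included in
the prediction. It steers toward the nearest transit-safe gap, checking
every obstacle column crossed en route against its arrival time with a
3-frame clearance margin and a lateral speed that accounts for the felt
drift push; distance ties go to the wider gap, gaps narrower than 18 px
are never targeted (unholdable with 6-px quantized steps), and the agent
eases off the walls. When the column is clear it steers actively toward
the gap center rather than coasting, and it station-holds against felt
drift by counter-tapping on alternate frames (one 6-px key per two frames
cancels the 3-px-per-frame push) — the analogue of players easily
counteracting a visible, predictable force. Active steering matters
statistically: input noise only perturbs keyed frames, so an agent that
coasts would be immune to it; a continuously adjusting agent is exposed
to it the way players are, which is what gives the completion model its
noise signal. The part of that noise the agent cannot undo is whatever
accumulates inside the reaction-lag window before an obstacle pass.
A per-frame lapse probability (skill 0.92) and per-participant skill
jitter (SD 0.04) supply human-like variability and the completion model's
random intercept. These defaults were set in a one-off piloting step to
the design's stated target of roughly 50–60% completion with monotone
gradients over noise and difficulty, and then frozen. Like the design it
emulates, the agent's completion rate is depressed mainly by the upper
noise levels; recovery checks therefore summarize the completion effect
as the total successive-difference contrast (highest level against
baseline) rather than any single step.

## The gaze generator

Gaze is generated at 2000 Hz on a strict 0.5-ms grid, aligned to the
trial log. Fixation onset distances to the ship come from a two-component
mixture: Close (mean 3°, SD 1°) and Distant (mean 8°, SD 1.5°), with
P(Distant) = 0.4 — placing the data-driven class boundary near 5–5.7°.
Component means shift linearly, on the component's *generation scale*,
with the covariates of the onset frame (on-screen obstacles and drift
sections), the trial's noise level or block, and a per-participant random
intercept (SD 0.3°). Experiments 1 and 3 generate on the identity scale;
Experiment 2 generates Close distances on the square-root scale (mean
1.8, SD 0.3), producing right-skewed distances so the Box–Cox stage has
something to find.

Effect defaults are the study conditions. Where the design prints
estimates on a comparable scale they are used directly: Close-fixation
noise-level shifts are the cumulative successive differences (Experiment
1: 0, −0.02, −0.11, so strong-vs-weak is −0.09; Experiment 2 on the sqrt
scale: 0.04, −0.08, +0.10, −0.10), obstacles add 0.07°/obstacle to Close
distances, and the judgment model uses completion +1.5, hard difficulty
−0.44/−0.19, invisible block −0.69, fake block −0.03, +0.0116 per
fixation, +0.03 per prior crash-completion, residual SD 1. Where the
printed estimate lives on a transformed scale that is not comparable
(the Distant-distance drift-section effect), the plant (0.25°/visible
section) was sized so a 25-participant cohort reproduces the reported
z magnitude. Judgments are a latent Gaussian rounded and clipped to 1–7,
mirroring the untransformed treatment of rating scales.

Within a fixation both eyes track the fixated scene point (vergence
offset 6 px) as it scrolls with the world — smooth pursuit at 6 px/frame,
0.18 px/sample, well under the annotation threshold — plus independent
Gaussian jitter of 0.15 px per axis and sample. The jitter default keeps
the probability of a single step exceeding 1.25 px negligible across a
cohort, so fixation runs essentially never split spuriously. Saccades are
linear interpolations whose per-sample steps (≈ 4 px) always break runs,
with amplitude at least 0.5° enforced at planning time. Single-eye
dropout (2% of fixations) flags one eye invalid. With zero jitter and
zero dropout, detection recovers the generated onsets *exactly*; this
round trip is tested.

What the generator does not emulate: main-sequence saccade kinematics,
microsaccades, blinks beyond validity flags, oculomotor noise spectra,
and any dependence of gaze on the agent's actual policy decisions.
Passing tests therefore show that the pipeline recovers structure of this
statistical form — not that real gaze has that form.

## Event detection

The analyzed position is the cyclopean midpoint, falling back to the
valid eye when one signal is lost; samples with both eyes invalid break
runs. Fixations are maximal runs in which every available eye moves at
most 1.25 px (0.026°) between samples for at least 25 consecutive
samples; the onset is the cyclopean position at the run's first sample.
Saccade verification is velocity-based: per eye, a 5-sample centered
difference (a standard choice; the window length is not dictated by the
task), an elliptic threshold at λ = 6 times a median-based velocity
spread estimated per trial and eye, at least 4 samples (2 ms) with both
eyes above threshold, and at least 0.5° of amplitude — the amplitude gate
applied conjunctively after the threshold crossing, the most conservative
reading. Verified saccade samples are excluded from fixation runs before
the 25-sample rule; no run-merging heuristic is applied. All detection
works in screen px; degrees enter only in the measures via the fixed
equivalence 1.25 px = 0.026°.

## The Close/Distant split

Fixations are split by one-dimensional k-quantiles clustering (k = 2) of
distance to the ship. Each cluster is an asymmetric-Laplace component
whose location is a cluster-specific θ-quantile, with θ and scale
estimated per cluster on standardized data; the loss is the profile
negative log-likelihood with θ on a fixed 0.01-step grid (a scale floor
of 1e-9 guards the degenerate spike). In one dimension with two clusters
the admissible partitions are the contiguous splits of the sorted data,
so after the b = 50 random initializations of the general iterative
algorithm (assignment via the crossing point of the two log-densities,
which keeps assignments contiguous), the fit performs an exact vectorized
sweep over all splits — the reported partition is the provable global
optimum of the loss, and the test suite checks it against an
independently implemented exhaustive search. The decision threshold is
the midpoint between the boundary observations; a distance exactly at the
threshold is labeled Distant (an arbitrary but fixed convention). The
partition is invariant to positive affine rescaling by construction.

## Measures

Distances are measured at the fixation's onset: Euclidean distance to the
ship center (972, 288 on screen) and to the nearest *on-screen* obstacle
center, in degrees; rows with no obstacle on screen are excluded from the
obstacle-distance model. The drift-section covariate counts sections
whose span intersects the visible window whether or not their bar is
drawn — the covariate describes the environment, not the display (a flag
is not provided; the invisible-bar case is still a real force). Entry-
phase fixations are excluded; logs end at the crash frame, so no
post-crash fixations exist. Trial-level covariates include the fixation
count and the number of consecutive crash-completions among strictly
prior attempts (a crash immediately followed by a completion).

## Inference

Distance responses pass through Box–Cox selection: the profile λ of an
intercept-only model, mapped to the nearest named transform (reciprocal /
log / sqrt / identity at cut points −0.5, 0.25, 0.75); the
reciprocal-of-log transform is available only as an explicit override.
Nonpositive values are shifted by half the smallest in-domain observation
(logged on the result). Models are fitted with lme4 by maximum
likelihood; fixed-effects structures are never pruned, and only the
random-structure candidates compete by BIC (default ladder: participant
intercept, optionally plus a manipulation slope). Input noise enters as a
factor with successive-difference contrasts where level-to-level
comparisons are reported; completion is a Bernoulli-logit model of raw
attempts. Significance is |z| ≥ 2; 95% highest-density intervals come
from a parametric bootstrap (simulate from the fitted model, refit,
shortest interval containing 95% of the draws), with replications split
into independently seeded chunks for reproducibility and failed refits
counted (a warning above 1%). The |z| ≥ 2 rule's type-I error and the
bootstrap's coverage are calibrated in the test suite on null datasets
from the package's own LMM simulator.

## Problem sizes and test design

The test suite validates at these sizes, chosen as the smallest that
give the checks real statistical teeth: oracle equivalence of the
fixation detector on 10,000 random traces of 60–140 samples and of the
k-quantiles fit on datasets up to n = 500; type-I calibration on 200 null
datasets (rejections pooled over their null coefficients, expected ≈ 5%);
bootstrap coverage at 1000 replications over 20 outer datasets (expected
≈ 95%); and sign recovery on 10 seeded replicates of full 25-participant
cohorts of Experiments 2 and 3 — the clean input-noise design and the
drift-type design, which together carry all the planted signs — requiring
every target at |z| ≥ 2 in at least 9 of 10. Final-inference bootstraps use 10,000 replications;
tests use fewer because the CI endpoints converge with the number of
replications (also checked).

## Known limitations

The simulator's logical clock ignores real frame-duration jitter; agents
do not anticipate drift (so invisible drift affects JoC only through the
planted judgment effect, not through emergent crash rates); the gaze
generator ties fixation targets to scene statistics only through the
onset-frame covariates; the k-quantiles exact sweep is specific to one
dimension and two clusters; and ordinal models for the 1–7 judgments are
out of scope — judgments are analyzed as Gaussian, matching the design
this package emulates.
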