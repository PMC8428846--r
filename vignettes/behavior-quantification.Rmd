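---
title: "Quantifying millisecond-timescale somatosensory behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying millisecond-timescale somatosensory behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawkit)
library(dplyr)
```

`pawkit` quantifies the fastest behaviors a mouse produces in response to
brief cutaneous stimulation: paw withdrawals that begin within tens of
milliseconds of an optogenetic pulse, the whole-body movements they are
embedded in, and the head orienting that follows. This vignette explains
the measurement models, the thresholds and their defaults, what the
synthetic-trial generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## Conventions

Frame indices are 0-based. Times are in milliseconds relative to stimulus
onset (onset = 0 ms); an event first seen at frame `f` has latency
`(f - onset_frame) * 1000 / fps`. Images use the video convention: origin
top-left, y increasing downward; this fixes the sign of yaw angles. The
pixel pitch of the whole-body camera defaults to 0.32 mm/px.

## Withdrawal detection from FTIR contact signals

Skin contact with the glass floor frustrates internally reflected
near-infrared light, so the stimulation site appears bright while the paw
is planted; lifting the paw removes the signal. The input is the mean
8-bit intensity in a circular region of interest (60 px diameter in the
reference acquisition) per frame, at 250–1000 frames/s, with a 500 ms
baseline epoch before the pulse.

Baseline statistics are the mean and the *population* SD (divisor `N`) of
the pre-onset window. The choice of SD divisor is immaterial at 125–500
baseline samples, but fixing it makes runs bit-reproducible.

Two detection rules are offered:

* `sd5` (default): a withdrawal is a drop to or below
  `mean − 5·SD`. This is the general-purpose rule.
* `strict`: the drop must also remove 20% of the baseline signal —
  threshold `min(0.8·mean, mean − 4·SD)`. This trades sensitivity for a
  lower false-positive rate and is appropriate for pulse-train and
  patterned-stimulation protocols in which many marginal trials are
  expected.

Latency is the time from pulse start to the first qualifying frame,
reported at the frame grain — no sub-frame interpolation — because the
event is "first frame at which the response is detected". Rise time
(20–80%) *is* interpolated linearly between frames, because the 20% and
80% crossings of a 4 ms fall almost never land on frame boundaries.

Two numerical choices deserve note:

* **Degenerate baselines.** If the baseline SD is 0, `mean − 5·SD` equals
  the mean and the rule would fire on the baseline itself. The threshold
  is then placed a hair below the mean (only strict drops qualify) and a
  warning is raised. An all-constant recording therefore yields *no*
  response, and an all-constant pixel in a latency map gets the
  no-response sentinel (`NaN`; −1 in integer exports).
* **Response floor.** Extent (% of baseline signal removed) and the fall
  magnitude underlying rise time are measured to the minimum of a
  running-median (radius 2 frames) copy of the post-onset trace rather
  than the raw minimum. Over a 1000 ms post-stimulus epoch the raw
  minimum of a noisy trace estimates the extreme of ~500 noise draws,
  not the contact signal, and is biased by roughly three noise-SDs; the
  median-filtered floor removes most of that bias while leaving
  noise-free signals untouched. The filter radius matches the optional
  median-filter preprocessing the module already defines.

Quality control rejects trials whose baseline 8-bit mean is below 3 (too
little light to lose), whose baseline signal-to-noise ratio `mean/SD` is
below 23, or whose detected latency is 10 ms or shorter — too fast to be
caused by the stimulus, hence a spontaneous movement. The SNR criterion
is stated in the source material as `SD/mean ≥ 23`, which is arithmetically
impossible for 8-bit data with mean ≥ 3 and SD bounded by the data range;
we implement the evidently intended direction (`mean/SD ≥ 23`, an SNR
floor) and expose the direction as an argument so either convention can
be run.

The extent classification uses 75% of the baseline signal as the
full/partial boundary: a post-onset floor at or below 25% of the baseline
mean is a full response; a detected withdrawal above that level is
partial.

`pixel_latency_map()` applies the same rule independently to every pixel
(baseline statistics per pixel, first post-onset crossing), which
resolves the spatial spread of the withdrawal, and counts per pixel the
frame pairs whose absolute change exceeds the binarization threshold.

## Binarized whole-body motion energy

Whole-body movement is summarized per frame pair as the number of pixels
whose 8-bit value changes by *more than* a threshold (a change of exactly
the threshold counts as no motion). The threshold defaults to five 8-bit
values for 40 fps recordings and seven for the 400 fps high-speed view;
both exist to discard sensor noise and are configurable. Laser-corrupted
frames are dropped before pairing, so the remaining frames are differenced
across the gap.

The count series is normalized by subtracting the baseline mean count.
We define normalized motion as `value − baseline mean` (movement
positive), so the "peak" of a response is a maximum; the high-speed
variant additionally divides by the pixel count per frame. A trial shows
a global response when the peak normalized motion energy reaches at least
5 baseline SDs (baseline SD computed over the baseline frame pairs of the
normalized series); movement initiation is the first post-onset crossing
of 10 baseline SDs and the bout ends at the first return below that
level. For time-locked nociceptor protocols the peak search can be
restricted to the first 100 ms after onset. If the baseline SD is zero
the SD thresholds are degenerate; an absolute fallback threshold is used
with a warning.

## Pose post-processing and kinematics

The package consumes DeepLabCut-style tables (x, y, likelihood per part
per frame; both the 3-row wide header and a flat single-header layout are
accepted) — it never trains or runs a network. Six parts enter analysis:
nose, left/right hind-paw digits and heels, and tail base.

**Filtering.** A point is removed when (1) its likelihood is below 0.95,
(2) it jumps ≥ 10 px in a single frame relative to the previous retained
point *and* the next available frame returns to within 10 px of the
pre-jump position — a one-frame labeling glitch — or (3) it falls within
the stimulation frames. Sustained jumps are kept: at 400 fps a genuine
withdrawal can move a paw label many pixels per frame, and removing
sustained excursions would delete exactly the behavior being measured.
Removed points become gaps; nothing is interpolated, because downstream
statistics must not be driven by imputed coordinates. Filtering is
idempotent, and the jump comparison is made against the previous
*retained* point so that a removed glitch cannot mask a subsequent one.

**Trial QC** rejects a trial when any analysis part is missing in more
than 10% of frames after filtering (stimulation-frame removals do not
count — they are by design), or when more than 10 frames are flagged as
mislabeled. "Mislabeled" is operationalized as frames hit by the jump
rule; a hook accepts an externally supplied list of manually flagged
frames, honoring the manual pathway while keeping the default automatic
and testable. The missing fraction is assessed per part (worst part
decides) because a single unusable part invalidates the kinematics that
depend on it.

**Stimulated limb.** With FTIR illumination off, the stimulation laser
saturates pixels at the site. The saturated-pixel count in a 60 × 60 px
window around each hind-paw label is compared 7.5 ms before and 5 ms
after onset (rounded to the nearest frame; 3 and 2 frames at 400 fps);
the side with the larger increase is the stimulated limb, and ties or
absent saturation return `unknown` with a warning for a manual call.

**Movement onset** of a part is the first post-onset frame displaced at
least 0.5 px (~0.16 mm) from its baseline position (mean of the 10
pre-onset frames) that keeps moving at ≥ 0.5 px/frame for each of the
following 10 frames. The persistence requirement suppresses jitter
crossings; the latency is reported in ms or absent if no frame qualifies.

**Egocentric alignment** translates coordinates so the baseline tail base
is the origin and reflects the x axis when the stimulated paw lies on the
left, so the stimulated paw always sits at non-negative x. Because
mirroring swaps image left and right, the paired part labels are swapped
along with it — in aligned coordinates the stimulated paw *is* the right
hind paw, which is what makes trials with different stimulated sides
comparable feature-by-feature. No rotation is applied: body-axis
variability is part of the pose variance the PCA is meant to see, and a
rotation flag would silently remove one of its components. Alignment is
an exact isometry (all inter-part distances are preserved).

**Kinematic summaries** over a 300 ms post-onset window: per-part
Euclidean displacement from baseline and its maximum; the
stimulated-paw-to-nose distance with its minimum (orienting toward the
paw) and maximum (withdrawal away); and head yaw — the angle of the
tail-base→nose vector minus its baseline circular mean, wrapped to
(−180°, 180°], positive toward the stimulated side after alignment. The
window mean of yaw is a circular mean; with angles confined well inside
a half-circle it agrees with the arithmetic mean, but the circular form
is the one that remains correct near the wrap.

## Statistics

**Pose PCA.** The feature vector is 12-dimensional (x and y of the six
parts) in aligned coordinates at a single time point, 115 ms after onset
by default — late enough that the withdrawal is complete, early enough to
precede secondary behaviors. PCA is mean-centered, unscaled (all features
share pixel units); the first three components are kept. Component signs
are fixed by making each component's largest-magnitude loading positive,
so refits and plots are identical run to run. A train/test split helper
(80:20) reports the variance fractions the training components explain in
both sets. Projecting whole time courses onto the fitted components gives
per-frame scores and the fraction of time-course variance captured
(`1 − residual/total`).

**Trajectory directions.** Each trial's direction is the angle of its
PC1–PC2 displacement between the start and end of a 35–115 ms window.
Only the first two PCs enter (a 3-D option exists but is off by default —
the third component is both small and hardest to estimate). Across
trials, the circular SD `sqrt(−2 ln R̄)` summarizes how stereotyped the
direction is; zero-length displacements are excluded and counted. The
control analysis permutes part identities within each trial before
projection: direction structure tied to *which* part moved is destroyed,
while trial-level common-mode movement survives.

**Balanced hierarchical bootstrap.** Behavioral trials are nested in
mice, and mice differ; a flat bootstrap would understate the uncertainty.
Each of the 10,000 replicates resamples M mice with replacement (M = the
number of mice), then k trials with replacement from each sampled mouse.
The balanced k makes every mouse contribute equally; since the source
material does not state its value, k defaults to the rounded mean number
of trials per mouse, which keeps the resample close to the original size
(configurable). The reported estimate is the mean of the replicate
statistics (median by default; mean for quantities like peak motion
energy) and the reported uncertainty is the SD of the replicate
distribution. With a single mouse and k equal to its trial count the
procedure reduces exactly to the ordinary one-level bootstrap, which the
tests verify distributionally.

**Probability sum rule and pulse matching.** For a train of n pulses
with per-pulse response probability p, independence predicts
`P(X ≥ 1) = 1 − (1 − p)^n`. Pulse-matched latency re-expresses a trial
latency relative to the most recent pulse (index capped at the last
pulse); if train responses are pulse-driven, residual-latency
distributions for different frequencies superimpose.

**Friedman/Dunn.** Within-subject comparisons across stimulation
protocols use the tie-corrected Friedman chi-square on within-subject
ranks (implemented directly; the tests cross-check it against the
independent implementation in `stats`), followed by Dunn's pairwise z on
rank sums. No multiplicity adjustment is applied by default because the
procedure is reported without one; any `p.adjust` method can be selected.
A fully tied table returns statistic 0 and p = 1 rather than the 0/0 the
raw formula produces. Incomplete subjects are an error — the caller must
drop them explicitly, making the exclusion visible.

**Regression fits.** Dose-response style relations are fit by least
squares in the transformed space: `y ~ x` (with Pearson's r), power laws
as `log y ~ log x`, and "lognormal" relations as `y ~ log x` — with the
`log y ~ log x` alternative reported alongside whenever y is strictly
positive, since the parameterization of such fits is a modeling choice.
R² is reported in the fitted space.

## The synthetic-trial generator

Every analysis stage has a generator producing inputs with programmed
ground truth, under the study conditions as defaults: 1000 fps FTIR
traces, 500 ms baseline in a 1500 ms trial, 8-bit baseline mean 100 with
Gaussian noise SD 2, logistic withdrawal falls removing 75% of the signal
with a 4 ms 20–80% time, latencies around 30 ms (trial SD 5 ms, additive
mouse effect SD 2 ms), cohorts of 8 mice × 8 trials; 400 fps whole-body
stacks; pose cohorts with a stimulated-paw onset near 29 ms and a 20°
head yaw. Where the study conditions fix no value we chose once:
resting-pose variability of 3 px per part and axis, log-normal movement
magnitude (SD 0.2), a 25° SD jitter of the withdrawal direction,
contralateral paw movement at 0.7 of the stimulated paw's magnitude, a
4 px whole-body weight shift in a random direction, and a sub-ISI
log-normal latency (median 50 ms) after the triggering pulse in
pulse-train simulations — sub-ISI because only then is "most recent
pulse" the triggering pulse, the regime in which pulse matching is
exact.

Two conventions make closed-loop recovery well-posed:

* Programmed FTIR latencies are quantized to the frame grid, and the
  noise-free waveform is placed so that at the latency frame it sits one
  noise-SD beyond the five-SD detection level. The recorded truth is then
  comparable frame-for-frame with the detector's first crossing; without
  the margin, a crossing that lands just past a frame boundary is a coin
  flip against the noise and "within one frame" would be ill-defined.
* The withdrawal waveform is logistic by default (observed falls are
  sigmoidal); a linear option exists because ramps have closed-form
  20–80% times for analytic tests.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: correlated (non-Gaussian,
non-i.i.d.) camera noise, illumination drift, fur texture and occlusion,
postural diversity beyond Gaussian perturbation of one resting pose,
licking/guarding behaviors, or realistic DeepLabCut error structure
(dropout is programmed independently per frame). The part-shuffled
trajectory control degrades directionality in the synthetic cohorts but
less dramatically than in real data, whose movement patterns are far more
heterogeneous; tests assert the direction of the effect, not its size.
The synthetic whole-body arena is scaled down (64 px) relative to a real
chamber, so limb-detection tests use a proportionally scaled saturation
window.

## Problem sizes and runtime choices

The test suite and the acceptance script run on desk-scale problems:
200-trial FTIR cohorts for detection recovery, 50 random 64 × 64 × 20
stacks for the motion-energy oracle, 100 simulated cohorts (n_boot =
1000 each) for bootstrap coverage with the single-cohort estimate at the
full 10,000 replicates, 8 × 8-trial pose cohorts for the PCA and
kinematics loops, and 500-trial arms for the pulse-train construction
check. These sizes give sampling error comfortably inside the stated
tolerances while keeping a full run in the tens of seconds.

## Known limitations

* No video decoding: frame stacks are read from per-frame PNG
  directories or multi-page TIFF; AVI/MP4 material must be exported to
  one of these first.
* Latency is frame-grained by definition; at 40 fps whole-body material
  this is a 25 ms grain, and conclusions about ~10 ms effects need the
  high-speed views.
* The jump-glitch filter assumes isolated one-frame excursions; two
  consecutive mislabeled frames in the same place are kept (they look
  like a sustained movement) and must be caught by trial QC or manual
  flags.
* `detect_stimulated_limb` needs laser saturation in the frame; with the
  FTIR illumination on, saturation at baseline makes the comparison
  uninformative and the function returns `unknown`.
* The hierarchical bootstrap quantifies uncertainty; it is not a
  hypothesis test and no mixed-effects modeling is provided.
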