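---
title: "Detecting local calcium releases in beating pacemaker cells: methods and design notes"
author: "LCRtrack"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Detecting local calcium releases in beating pacemaker cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LCRtrack)
```

## The problem

Sinoatrial node cells (SANC) — the heart's pacemaker cells — generate
spontaneous, localized Ca²⁺ releases (LCRs) from the sarcoplasmic reticulum
during diastolic depolarization. Unlike the stereotyped Ca²⁺ sparks of
ventricular myocytes, LCRs are heterogeneous: they appear stochastically,
propagate by Ca²⁺-induced Ca²⁺ release, split, collide, and either fade away
or merge into the next action-potential-induced whole-cell transient. Two
obstacles make automated analysis of 2D+time fluorescence movies of these
cells hard:

1. **Motion.** The cell contracts once per cycle, so a fixed pixel does not
   report a fixed cytoplasmic location.
2. **Noise and global signal.** LCR amplitudes sit close to camera noise and
   on top of a whole-cell transient that dwarfs them.

`LCRtrack` addresses both: a curvature-based tracker renders the cell
motionless by piecewise-affine warping, and a spatiotemporal differential
filter then detects and tracks LCRs through their full lifecycle.

## Stabilization: spine, curvature, and the triangular mesh

With the cell roughly parallel to the x axis, each image column gets a
midline ("spine") height — the intensity-weighted centre of mass

$$\zeta(x,t) = \frac{\sum_y y\, a(x,y,t)^{1.5}}{\sum_y a(x,y,t)^{1.5}},
\qquad
a = \begin{cases} i - b & i > b + 3\sigma \\ 0 & \text{otherwise,}\end{cases}$$

where $b,\sigma$ are the mean and population SD of the fluorescence in a
user-chosen off-cell rectangle. The 1.5 power weights the bright cell body
over its dim halo. The signed local curvature

$$k(t,x) = \frac{\zeta_{xx}}{(1 + \zeta_x^2)^{3/2}}$$

is computed with Savitzky–Golay derivative filters along x. Bends in the
cell are conserved under contraction, so bands of constant curvature in the
$k(t,x)$ map are trackable landmarks.

Tracking is deliberately semi-automatic, driven by programmatic inputs
rather than an interactive GUI: the user names one contraction (a frame
window and column range on the curvature map); a least-difference search
finds all others; horizontal guide lines along curvature bands, bent inside
the template contraction by a user polyline, are replayed in every matched
window. Each guide's per-frame position, paired with the spine height there,
gives a tracked spine point. Adjacent point pairs form the bases of
isosceles triangles above and below the spine (apexes offset vertically by a
user-defined height), with intervening opposite-oriented triangles filling
the strip. For each triangle, the affine map $M_d M_r^{-1}$ (homogeneous
vertex matrices of the deformed and reference triangle) carries reference
pixels to the deformed frame; backward warping with bilinear sampling then
renders every frame in the reference geometry, with no holes and exact
vertex correspondence.

Numerical choices: point-in-triangle tests include edges with a $10^{-9}$
barycentric tolerance, ties between adjacent triangles resolve to the lowest
triangle index, out-of-frame samples are clamped to the border and counted,
and pixels outside the mesh take the constant background mean.

### Savitzky–Golay parameters

The window (11 columns) and order (3) are package defaults, exposed in the
configuration; derivatives are interior-only (no polynomial extrapolation at
the span ends), and interior gaps in the spine are filled by linear
interpolation and flagged. Larger windows suppress curvature noise at the
cost of blurring short bends.

### Match threshold semantics

The dissimilarity between a candidate window and the template is the mean
absolute difference of the curvature sub-matrices over the template's column
range. A candidate is accepted when it is a local minimum of the
dissimilarity profile lying below `match_threshold` percent of the profile's
maximum, so raising the threshold admits more matches. Because even a
perfect structural match retains a noise-difference floor (two independent
noise realizations never agree exactly), noisy recordings genuinely need a
higher threshold; on simulated contracting cells at realistic noise the
default 20 finds only the template while 30 finds every contraction — the
same sensitivity behaviour practitioners report for real recordings.

## Detection: conditioning, candidacy, and clusters

On a stabilized stack:

1. **Max Filter.** The per-pixel maximum over time, cut at the mean of all
   maxima, separates cytoplasm from the darker background; the largest
   4-connected component is the cell mask.
2. **Normalization.** $F_{norm} = 255\,(F - F_{min})/(F_{max} - F_{min})$
   over masked pixels and all frames: the masked extremes map to exactly 0
   and 255.
3. **Transient removal.** The whole-cell average $F_a(t)$ is subtracted per
   frame and negatives are clipped to 0, leaving $F_{nt}$ — signal locally
   above the cell average. Skipped entirely when `transients_present` is
   unset (e.g. permeabilized cells).
4. **Optional despeckling.** Mask-aware 3×3 median and/or mean filters
   (median first) for salt-and-pepper noise; off by default.
5. **Differential filter.** $S$ averages $F_{nt}$ over a
   $(2d+1)\times(2d+1)$ window (default $d=3$: a 7×7 window, 3.16 µm² at
   0.2539 µm/px) truncated to in-mask pixels; $D(t) = S(t) - S(t-1)$
   (zero at frame 0) isolates fast local rises and cancels static
   heterogeneity such as uneven indicator loading. The scalar
   `sigma_cell` — the population SD of $D$ over all cell pixels and frames
   ≥ 1 — is the single scale for every threshold.
6. **Candidacy.** A pixel is an LCR candidate when
   $D > \texttt{sd\_detection}\times\sigma_{cell}$ (default 1) outside
   suspended frames; one fill pass grants candidacy to any cell pixel with
   at least 7 of its 8 neighbours already candidates.
7. **Clusters and births.** Candidates group into 4-connected clusters
   ("common borders"); a cluster founds a new LCR only if its pixel count
   reaches `size_threshold` AND its summed differential mass reaches
   `intensity_threshold` × `sigma_cell` (a Boolean AND — newborns must be
   large *and* bright). Failing clusters remain continuation-only
   fragments: they may join an existing LCR but cannot found one.

### Why the brightness test sums D, in σ units

Two design decisions here were genuinely open and were settled by
measurement on simulated recordings:

* **What to sum.** Summing the conditioned intensity $F_{nt}$ over a
  cluster does not discriminate: after transient subtraction the cell
  interior rides a spatially varying pedestal (several gray levels above
  the cell average, because dim edge pixels drag the average down), so the
  $F_{nt}$ sum of a pure-noise cluster simply grows with its area. The
  summed differential mass — the total signal that *appeared within one
  frame* — separates cleanly: on reference simulations, noise clusters stay
  below ≈120σ while true event births exceed ≈160σ.
* **What units.** The false-positive control (below) re-normalizes an
  off-cell noise region to the full 0–255 range, inflating absolute gray
  units roughly ten-fold. `sigma_cell` inflates identically, so a threshold
  expressed in σ units means the same thing in every run; an absolute
  threshold would be ~10× too lenient on a control region.

The default `intensity_threshold = 165` sits above the noise-cluster mass
tail and below the weakest seeded-event births of the reference simulation;
like every sensitivity parameter here it is a per-study tunable — tuned once
against the false-positive control, exactly the workflow the control exists
to support.

### Transient cutoff

During the rising transient the whole cytoplasm lights up and LCRs can no
longer be discriminated; frames on the rising limb past
`transient_cutoff_percent` of the nadir-to-peak excursion are suspended.
With an upstroke a few frames long, the *per-frame* fractional rise is large
(one third per frame for a 3-frame upstroke), so the cutoff must sit below
it: the default 20% provably suspends every rise frame of such a transient,
whereas 50% admits the first rise frame — which floods the differential
filter with a cell-wide "event". Decay frames are never suspended; LCRs on
the falling transient remain detectable.

## Lifecycle tracking

Per frame, clusters join the active LCR whose previous-frame pixels they
overlap or 4-touch. A cluster bridging two or more LCRs triggers a
collision: the largest (previous-frame area; ties to the lower id) survives
and incorporates the bridged pixels and the other events' pixels; the others
die `dead_by_collision`. An LCR whose candidates reappear as several
separated components keeps a single identity over all of them
(separation ≠ death). Remaining birth-eligible clusters found new LCRs.

**Termination.** The decayedness of a pixel is judged by the *elevation* of
its locally averaged signal above the event's own pre-birth baseline,
$S(p,t) - S(p,\,b{-}1)$. Carried pixels are retained while their elevation
holds at `sd_termination` × `sigma_cell` (default 1); the event dies
`dead_by_stochastic_attrition` when its mean elevation falls below that
threshold or its pixel set empties. An event alive when a suspended frame
arrives dies `dead_by_transient` (it merges into the rising whole-cell
signal). Events alive at the last frame stay open (`dead = false`, all
death booleans false).

The elevation form deserves a note: comparing an *absolute* level (mean
$F_{nt}$) against any global scale cannot work on cells whose interior sits
on a pedestal above the cell average — decayed regions are then
indistinguishable from active ones by level, and in early versions of this
package events outlived their release several-fold, accreted noise
fragments, and wandered. The elevation is a change-since-birth, i.e. a
difference-scale quantity, which is exactly what `sigma_cell` measures; on a
clean zero-baseline fixture it reduces to the plain "mean signal below
threshold" rule. With it, simulated events die within a frame or two of
their programmed decay.

**Output parameters** per LCR: path bounding box (`min_x`…`max_y`), start /
maximum / path areas (the path area — the union of every pixel the LCR ever
occupied — quantifies propagation), birth from nadir (negative ⇒ "early"
LCR), LCR cycle (frames since the preceding transient peak, the local
Ca²⁺-clock period), birth from stack start, inclusive duration (a 1-frame
event has duration 1), half-maximum amplitude on the conditioned 0–255
scale, and the death bookkeeping (dead ⇔ exactly one mode flag). Per-event
size traces and their per-frame ensemble sum (a formal sum of all traces)
and a hot-spot occurrence map complete the outputs. When
`transients_present` is unset the two cycle-referenced timings are empty.

## False-positive control

A rectangle far from the cell contains instrumental noise but no LCRs.
`falsePositiveRate()` runs the identical detection twice — on the cell, and
treating the control rectangle as the cell area — and normalizes by area:

$$fp = 100\cdot\frac{N_{ctrl}/A_{ctrl}}{N_{cell}/A_{cell}} \,\%$$

(0 when both counts are 0). The control run is performed under the *cell
run's calibration*: the same Eq-6 normalization anchors and the same
`sigma_cell`. Re-deriving these from the control region itself would
stretch pure noise to the full gray range and lower the candidacy bar (a
transient-free region has a smaller SD of $D$), i.e. it would measure the
false positives of a *different*, more trigger-happy detector than the one
actually used on the cell. With frozen calibration the control is the same
instrument pointed at a region where nothing exists; at default thresholds
it reports 0 events — hence a 0% rate — in every reference simulation.

## The simulator and what passing tests mean

`simulateMovie()` generates ground-truthed movies: an elongated soft-edged
plateau cell (curved midline, tapered ends) over a dark background;
multiplicative whole-cell transients (3-frame upstroke, exponential decay
with an 8-frame time constant, period 50 frames ≈ 2 Hz at 10 ms/frame);
LCRs as isotropic Gaussian blobs (σ 2.5 px ≈ 1.5 µm FWHM at 0.2539 µm/px)
with a 2-frame linear rise and 3-frame exponential decay — matching the
5–10 ms rise times of real sparks and LCRs at 100 frames/s — born during
diastole, optionally drifting at 0.5 px/frame to emulate propagation; an
optional known piecewise-affine contraction (x-shortening plus a vertical
bow synced to the transient) applied forward through a triangular mesh; and
additive Gaussian camera noise. The reference conditions used throughout
the tests are 100-frame, 64×256 px movies with 10 events per cycle at an
amplitude of 5× the noise SD.

Three placement rules keep the ground truth meaningful:

* events sit with their blob support on the plateau proper (8 px from the
  soft edge) — an edge-straddling blob is truncated by the cell profile and
  no longer has its nominal amplitude;
* co-active events (births within a lifetime of each other) keep at least
  26 px separation = 2 × (4σ blob support + search distance), the distance
  at which two events' candidate regions begin to touch and merge —
  "well separated" must be judged at the detector's scale;
* the event layout is drawn before the noise, so runs differing only in
  `noise_sd` share the same truth.

What the simulator does **not** emulate: photon shot noise and camera gain
calibration, bleaching and dye kinetics, morphologically complex cells
(fronds), whole-dish translational drift, and truly heterogeneous indicator
loading. Passing recovery tests therefore demonstrate the algorithmic chain
is correct and well-calibrated under controlled conditions, not that any
particular real recording will yield these rates; on real data the
sensitivity parameters are expected to need per-recording tuning against
the false-positive control, and recordings whose contractions cannot be
matched should be discarded.

Scoring (`scoreDetection()`) matches greedily, one-to-one, within 2 frames
of birth and 8 px of centroid. The 8 px tolerance reflects the detector's
localization scale — the reported bounding box covers the travelled path
plus the search-window dilation, so its centroid is intrinsically offset
from the birth centroid by up to ~7 px — while staying below half the
seeded separation, so cross-matching is impossible.

## Problem sizes and determinism

The test-suite and acceptance runs use 10 recovery seeds and 20
false-positive seeds of the reference movie sizes above, brute-force oracle
comparisons on 16×16×10 stacks (100 random trials), and analytic curvature
fixtures of ~100 columns; a full detection run on a reference movie takes
on the order of a second. All randomness flows from explicit seeds: the
same configuration, input and seed reproduce byte-identical outputs.

## Worked example

```{r example, eval = FALSE}
library(LCRtrack)

sim <- simulateMovie(seed = 1)                 # ground-truthed movie
res <- detectLCRs(sim$stack, runConfig())      # full detection
res
head(eventRecords(res))
scoreDetection(sim$truth, eventRecords(res))[c("recall", "precision")]

# motion correction for a contracting recording
movie <- simulateMovie(seed = 3, contraction_amplitude = 0.06,
                       n_events_per_cycle = 0, noise_sd = 2)
bg    <- estimateBackground(movie$stack, c(4, 0, 40, 5))
cmap  <- curvatureMap(spineMap(movie$stack, bg))
wins  <- matchContractions(cmap, c(5, 16), c(40, 215), match_threshold = 30)
lines <- lapply(c(80, 120, 160), function(g) trackLine(cmap, g, NULL, wins))
mesh  <- buildMesh(spinePoints(lines, cmap), height = 20)
still <- stabilize(movie$stack, mesh, ref_frame = 0, background = bg$b)
```

## Known limitations

* The cell must lie roughly parallel to the x axis and must not translate
  as a whole; there is no rigid pre-registration.
* Fully automatic contraction tracking is out of scope: the curvature bands
  become noisy just before each contraction (large pre-systolic LCRs), so a
  template window and guide positions are required inputs.
* 1-sample-duration events are detected but their shape and duration are at
  the resolution limit and should be interpreted with caution.
* The collision rule keeps the larger event by fiat; biology may disagree.
* Events that would survive an aborted transient are nevertheless
  terminated at the first suspended frame.
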