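---
title: "Quantifying retinal vascular morphology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal vascular morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retivasc)
```

## The measurement problem

Rhegmatogenous retinal detachment (RRD) separates the neurosensory retina
from the pigment epithelium. Beyond the detached region itself, the disease
is suspected to alter the retinal vasculature globally — vessel density,
caliber, and tortuosity. Ultra-widefield (UWF) fundus photography captures
about 200 degrees of retina in one frame, which makes such morphometry
possible but introduces two practical complications this package is built
around:

* eyelids and eyelashes intrude at the frame periphery, so measurements are
  restricted to a centered oval *general cover* (~43% of the frame by
  default), and
* in detachment eyes the frame must be split into a detached (*RRD*) and an
  attached (*non-RRD*) region along a clinician-drawn boundary, with every
  statistic computed per region.

`retivasc` implements the full chain: ROI covers, vessel extraction, a
segment-and-rectangle vessel model, three metric families, and the
rank-based group statistics, plus a synthetic fundus generator so that the
whole chain is testable against known ground truth without any clinical
data.

## Vessel model: segments and minimum enclosing rectangles

The binary vessel map is skeletonized (Zhang–Suen thinning) and the
skeleton is cut at branch points, detected by a crossing number of at
least 3 — the number of background-to-foreground transitions around the
8-neighbor ring, which is robust to the staircase corners that inflate a
plain neighbor count. Each branch-free arc is subdivided into runs of at
most `max_seg_len` skeleton pixels (default 30 px), and every foreground
pixel is attached to its nearest run by geodesic label propagation.

Each segment gets its minimum-area enclosing rectangle, fitted by rotating
calipers over the convex hull of the pixel centers (hull-edge angles plus a
1-degree grid are scanned; both sides are padded by 1 px for the unit
extent of a pixel). The rectangle provides everything downstream:

* the **width** `W` (short side) is the segment's caliber,
* the **long side** direction is the segment's orientation,
* `L`, `W`, and `L*W` are the weights of the tortuosity variants.

Segments are typed by their along-vessel neighbor count: isolated (I),
marginal (II, one neighbor), intermediate (III, two neighbors). Runs
meeting at a bifurcation are deliberately *not* neighbors: an
inter-segment angle is a bend along one vessel, not the branching angle
between two vessels — and a segment at a bifurcation would otherwise have
three neighbors, which the II/III typology cannot express.

### Qualification criteria

A rectangle width is only a trustworthy caliber reading if the segment is a
solid, elongated, roughly radial bar away from the optic disc. Four
criteria (`qualify_params()`) encode this; all are configuration keys:

| criterion | default | rationale |
|---|---|---|
| fill ratio `>=` | 0.5 | pixel count / rectangle area; rejects blobs, corners, sparse scraps |
| long side in | [8, 60] px | too short: orientation meaningless; too long: direction no longer local |
| radial angle `<=` | 60 deg | retinal vessels radiate from the disc; tangential scraps are usually artifacts |
| disc distance `>=` | 1.5 x disc radius | the disc region itself is bright, crowded, and unmeasurable |

The tortuosity statistics additionally require type II or III (an angle
needs a neighbor). The "distance from the disc" criterion is our reading of
a qualification ingredient whose original concentric-circle construction is
not fully recoverable; treating it as a minimum distance of the rectangle
center from the disc center excludes the same unmeasurable zone.

## The three metric families

**Absolute density** is the exact integer ratio of vessel-foreground pixels
to ROI pixels — no resampling, no smoothing.

**Caliber** is the mean and median of `W` over caliber-qualified segments.
With an even count the median is the midpoint of the central pair.

**Tortuosity** starts from inter-segment angles: for a type II segment the
acute angle between its long-side direction and its neighbor's; for a type
III segment the mean of the two acute angles to its neighbors. Acute angles
of undirected lines live in [0, 90] degrees. Five statistics summarize the
angle set: the unweighted mean, and weighted means with weights `L*W`
(area), `L` (length), `W` (width), and `1/W` (inverse width). The weighted
variants' intent: area combines length and width information; length
compensates the segment-size bias introduced by subdividing arcs; width
amplifies thick-vessel tortuosity; inverse width reveals thin-vessel
tortuosity. All five coincide when all rectangles are identical, and every
one lies between the smallest and largest angle — both properties are
asserted in the test suite.

Angles are reported in degrees throughout. Rank-based group comparisons are
unit-invariant, so this choice does not affect any test statistic.

**Missing-value policy.** Zero is a legitimate tortuosity (a perfectly
straight chain), so undefined metrics are *never* coerced to 0: with no
qualified segment, caliber and tortuosity are `NA` and are dropped from
group statistics.

## Vessel extraction

The paper trail for extraction is deliberately scale-relative; all knobs
live in `extract_params()`:

1. green-channel grayscale (strongest vessel/background contrast);
2. background flattening: subtract a local mean over a window of 1/8 of
   the short frame side;
3. Sobel gradient magnitude, hysteresis thresholding at the 85th/96th
   percentile of gradient magnitude inside the ROI (weak edges survive
   only in components that touch a strong edge);
4. body filling: the edge pixels are grown geodesically through the mask
   of pixels darker than the local background (`dark_thr = -3` gray
   levels), then closed (radius 2), hole-filled, and trimmed to
   below-background pixels;
5. connected components below 64 px are dropped;
6. intersection with the ROI.

Two numerical choices deserve comment. *Hysteresis percentiles*: at
realistic vascular density (10–17% of the ROI), vessel boundary pixels
alone exceed 10% of ROI pixels, so a 90th-percentile weak threshold would
clip edges and fragment thick vessels; 85/96 keeps the edge budget
comfortable at every frame size we generate. *Geodesic filling*: a fixed
closing radius can only bridge lumens up to twice its size, which hollows
out any vessel wider than ~4 px and collapses its measured caliber to the
width of an edge strip; growing through the darkness mask fills a lumen of
any width, while the darkness bound (and the sub-percolation fraction of
dark background pixels) stops leakage. The HSV value channel is used only
for optic-disc detection; the disc is the largest connected component
above the 99.5th brightness percentile, refined by re-growing at a
threshold halfway to the background so the full disc, not just its
brightest core, defines center and radius. A manual override
(`manual_center`) always wins.

## Rank statistics

The group layer reports what detachment cohort studies print: mean ranks.
`mann_whitney()` uses midranks for ties, reports both `U` statistics (so
no convention ambiguity), and takes its two-sided p from exact enumeration
of all group assignments when `N <= 12`, otherwise from the normal
approximation with tie-corrected variance and continuity correction. The
continuity-corrected normal never strays more than 0.05 from the exact p
anywhere in the `N <= 12` range, and no more than 0.02 wherever the exact
p is at most 0.1 — both bounds verified exhaustively in the suite (the
approximation is weakest near p = 1, where nothing is decided anyway).

`wilcoxon_signed_rank()` drops zero differences, midranks the absolute
differences, and reports the mean rank among positive (first argument
larger) and negative differences separately — the paired analogue of the
mean-rank effect summary. Swapping the arguments swaps the two mean ranks
and negates `Z` exactly.

`required_sample_size()` is the proportion-estimation formula
`n = z^2 p (1 - p) / eps^2`, with the exact normal quantile (1.959964 for
95%) and a ceiling. With a rare condition (incidence 0.042%) at a 5%
margin, the raw requirement is ~0.645 and the returned minimum is 1.

`compare_cohort()` runs, per metric, healthy-vs-detached and
healthy-vs-attached Mann–Whitney tests and the paired detached-vs-attached
Wilcoxon test, and draws the mean ranks as a three-panel radar plot with
the eight metric axes anti-clockwise from density. Unadjusted p-values
with 0.05/0.01/0.001 stars are the primary output, as is conventional in
this literature; a Bonferroni column is available on request.

## The synthetic cohort generator

`grow_vessel_tree()` emulates the one anatomical regularity the metrics
rely on — vessels sprout from the optic disc rim and radiate outward — as
a bounded-turning random walk (per-step heading change uniform in
`+/- bend_amplitude`) with occasional binary branching and width tapering
(factor 0.75, floor 1 px). `render_fundus()` wraps the rasterized tree in
gross fundus photometry: radial background falloff, vessels darkest in
green, the disc brightest in all channels, additive Gaussian noise.
Detachment boundaries are emulated by `make_detachment_partition()` as a
straight cut of the oval cover at a seed-chosen orientation, with the
offset solved for the requested detached-area fraction (both sides of a
straight cut of a convex cover are simply connected, like a real
fluid-demarcation boundary at this scale).

`generate_cohort()` draws per-image parameters lognormally
(`cv = 0.15`) around group means, with group-B multipliers for density
(root count), caliber (root width), and tortuosity (bend amplitude).
Defaults — 6 roots, 7 px root width, 12-degree bend, noise 5 gray levels,
45% detachment fraction, 256 x 256 frames — give vascular densities around
10–16% of the cover, in the range of real UWF morphometry; the contrast
direction (detached group thinner and straighter) mirrors what detachment
cohorts report. With all multipliers at 1 the groups are exchangeable by
construction, so cohort-level tests have exactly nominal size — the suite
verifies a ~5% rejection rate over 200 replicate null cohorts.

What the generator does *not* emulate: artery/vein classes, central
reflexes, stereographic projection distortion, eyelash occlusion,
photoreceptor texture. Passing recovery tests therefore demonstrate that
the measurement chain is correct on images whose gross geometry and
photometry match fundus frames — not that extraction is competitive on
clinical captures.

## Problem sizes and determinism

Everything is a pure function of explicit seeds (`withr::with_seed`; the
session RNG state is never touched). The test suite and the acceptance
script size their simulations to run on one CPU in minutes: recovery
properties use 144–256 px frames (20 replicate cohorts of 2 x 20 images
for the caliber-sign property; 20 images for the tortuosity–bend
monotonicity), and the power/size simulations run on the generator's truth
parameters (40 per group; 20 replicates for power at caliber multiplier
0.7, 200 for size), where rendering adds nothing: the multiplier acts on
the generating widths directly, and the measured-recovery path is covered
separately by the sign property and the width-5 caliber readback.

## Known limitations

* Extraction is classical (filters + edge detection); no learned
  segmentation. On heavily textured real UWF images the config defaults
  will need tuning, and the package makes every threshold a config key for
  that reason.
* Crossing vessels are not disambiguated; a crossing becomes a branch
  point and its runs end there (they only lose tortuosity eligibility,
  never produce spurious angles).
* Caliber carries the +1 px pixel-extent padding; at very low resolution
  this biases thin-vessel widths upward by up to half a pixel.
* The clinical mean ranks of the detachment study that motivated this
  design are not reproducible here: the underlying UWF images are not
  publicly deposited. The package therefore validates against synthetic
  ground truth and self-contained analytic values only.
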