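---
title: "Extracting single-neuron trees from multicellular fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting single-neuron trees from multicellular fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Confocal images of cultured neurons are thin z-stacks (10–30 optical
sections of a 512×512 field at ~0.28 µm/px) that are routinely collapsed to
2D by maximum- or average-intensity projection before analysis. In a
multicellular culture the projected neurites of different neurons appear to
cross, so a tracer that merely extracts centerlines of "everything tubular"
cannot answer the question that image-based neuron profiling actually asks:
*which* soma does a given piece of neurite belong to, and what path connects
it to that soma? `neurotracer` models each neuron as a directed rooted tree
— soma as root, one directed path from every node back to the root — and
extracts one such tree per soma, resolving apparent crossings, so that
fluorescence intensity can be quantified along each neurite as a function of
arclength from its own soma.

The pipeline is: (optional) denoising → segmentation → soma detection and
splitting → per-soma tree extraction (initialization, seeding, fan tracing)
→ background-corrected intensity profiling and AIS statistics. Every stage
can be bypassed by supplying its output (a mask, a soma label image), and
every stage is deterministic given its inputs.

## Denoising

Photon shot noise is Poisson. `denoise()` applies the Anscombe transform
(`2*sqrt(x + 3/8)`), a translation-invariant à-trous (starlet) B3-spline
wavelet decomposition, thresholding of each detail scale at `k` times
that scale's noise standard deviation (estimated robustly from the finest
scale by the median absolute deviation, propagated to coarser scales through
the exact ℓ2 norms of the equivalent filters), and the inverse transforms.
The starlet system is isotropic rather than directional; it satisfies the
contract the downstream stages need — edge-preserving multiscale
thresholding under Poisson noise — with `scales = 3` and `k = 3` as
defaults. Hard thresholding is the default rule: keeping significant
coefficients at full amplitude preserves the brightness of thin neurites,
whereas soft thresholding shrinks them and biases thin structures downward
(soft remains available via `denoise_config(rule = "soft")`). Both remain configurable because no single threshold rule is
optimal across acquisition settings. Denoising is skipped automatically when
a segmentation mask is supplied.

## Segmentation

`segment_image()` provides two routes to the binary mask `f`:

* a pixelwise linear-kernel SVM (`train_classifier()`) over a feature bank
  of multiscale isotropic Laplacian-of-Gaussian responses plus oriented
  elongated second-derivative (ridge) responses at 8 orientations — the
  classifier is trained once per image type on labelled examples (for
  phantoms, on image/truth pairs) with a deterministic, balanced pixel
  subsample;
* a model-free Otsu threshold fallback.

The mask is then cleaned: components below `min_size = 20` px are removed
and holes below `max_hole = 10` px are filled, because seeding assumes a
connected tubular foreground. On noiseless phantoms with zero background the
fallback recovers the ground-truth mask exactly; on the Poisson phantoms at
the package's default signal levels its Dice coefficient against truth
exceeds 0.95, which is the regime in which the tracing defaults were
validated.

## Soma detection

The Directional Ratio (`directional_ratio()`) scores local isotropy: line
filters of length 15 px at 16 orientations are applied to the *mask* (not
the intensities — the descriptor measures geometry, and the mask is already
computed), and each pixel's score is the minimum over orientations of the
response divided by the maximum. Interiors of somas score near 1; a tube of
width w scores near w/length. Pixels scoring ≥ 0.6 form soma cores
(after a radius-2 morphological opening and a 100 px area minimum); each
core is refined by geodesic growth of up to 5 px inside the set
`{foreground, score ≥ 0.3}`, which rounds out the soma boundary while
excluding neurite stumps. Cores that merge several somas are split by a
watershed on the interior distance transform with a 2 px tolerance
(`split_clustered_somas()`). The filter length must exceed twice the widest
neurite; all values are configuration because the right scale depends on
cell type and magnification.

## Tree extraction

This is the core of the package (`extract_trees()`), in three steps per
soma, somas processed in descending area order.

**Initialization.** The soma mask S0 is scaled about its centroid by rates
1.1, 1.2, 1.3 (geometric scaling, so ring thickness is proportional to soma
size; for small somas the rates are raised just enough to keep each ring at
least 1.5 px thick, otherwise rasterization disconnects them). The symmetric
differences S1⊕S0 and S3⊕S2 are intersected with the segmented structures
(all soma masks excluded); each neurite leaves one short segment in each
ring. Inner and outer ring segments are paired by mutual nearest centroids;
the inner→outer direction is the neurite's initial orientation θ0 and the
soma-boundary pixel nearest the inner centroid is its start point. When the
pairing is missing, contested, or points more than 60° away from the radial
direction (which happens when a neurite of *another* neuron passes through
the rings), the radial direction from the soma centroid is used instead:
genuine neurites emanate roughly radially, so this recovers them, while ring
segments of tangentially passing neurites produce only inert stubs instead
of hijacking a foreign arbor.

**Seeding.** The exact Euclidean distance transform Df of the mask is
convolved with the 3×3 sharpening kernel (centre 2, others −1/8), min–max
normalized over the foreground, and thresholded at 0.16. The threshold is
applied to the *normalized* response — the raw transform is in pixel units,
where a fixed 0.16 would be meaningless; the raw variant remains available
via configuration. Surviving candidates are pruned greedily in decreasing
Df order: each kept seed removes all candidates inside its ball of radius
Df(s). Ties in Df are broken by distance to the image centre, which is
invariant under quarter-turn rotations of the input, then by index. Because
the global normalization is dominated by the somas, thin distal segments can
fall below threshold; wherever the balls of the kept seeds fail to cover the
foreground skeleton, the response is re-normalized *locally* in the gap's
bounding box and thresholding plus suppression are re-run there. A final
pass promotes skeleton pixels to seeds until consecutive seeds along every
skeleton path (nearest seeds of adjacent skeleton pixels) have intersecting
balls — the property the tracer needs so that no neurite is abandoned
mid-way. The skeleton used here is a Zhang–Suen thinning symmetrized over
the four quarter-turn rotations, making the whole seeding stage exactly
equivariant under 90° rotation of the input.

**Fan tracing.** From each start, the tracer repeatedly searches for the
next seed in an orientation-constrained fan. Round r (r = 0…9) uses
rectangles of length 10 + 2r px; within a round the axis-aligned rectangle
is tested first, then pairs of rectangles at angular offsets ±m·π/16, each
5% shorter than the last, until the offset exceeds 2π/5. Rectangle width is
`max(3, 2·Df(current))` so the window spans the local neurite diameter; a
window at offset φ additionally only accepts seeds deviating at most
|φ| + π/16 from the expected orientation, so the swept windows form a true
circular sector and a wide rectangle cannot capture seeds of a transversal
neurite. Within a window the nearest seed wins (ties: smaller deviation,
then lower index), and a seed is only eligible if at least 60% of the
straight segment to it lies on the foreground — short seeding gaps are
tolerated, jumping across background onto a different neurite is not.

The expected orientation is the principal axis of the trailing 16 px of
trace, slew-rate limited to π/9 per accepted seed. This implements the
smoothness premise directly: neurites change orientation gradually, so one
sideways-displaced seed inside a junction blob cannot corrupt the heading
and tip the sector preference toward the intersecting neurite. Crossings are
then resolved by two cooperating mechanisms: the sector prefers the
continuation closest to the current orientation, and seeds consumed by one
neuron stay dead for all later neurons, so the second neurite through a
junction skips the shared blob seed and picks up its own continuation
beyond. Accepted steps also consume alive seeds within 3 px of the
connecting segment (near-duplicates from local gap repair), preventing a
later trace from riding an already-claimed centerline. Claims within 2 px of
another tree's nodes are counted in a per-tree conflict log, since shallow
crossings can be ambiguous even for a human annotator.

**Branching.** Trees must branch, and the fan provides the mechanism: when
a round finds alive seeds in two angular sub-fans separated by more than one
angular step — and none dead ahead — the sub-fan nearest the axis continues
the neurite and each other sub-fan spawns a child branch rooted at the
current node. Two guards keep this from firing at crossings: the branch
representative must deviate less than π/5 (an intersecting neurite at the
≥45° angles the phantoms model deviates more), and the back-extension of the
branch direction must be free of seeds not belonging to the current trace
(a genuine bifurcation has an empty back-sector; a transversal neurite
continues behind the junction). A branch seed whose clearance ball still
intersects the continuing seed's ball is part of the same junction blob, not
a separated arm, and is ignored.

**Termination and large images.** A neurite is complete when all ten rounds
find nothing. For large stitched fields, `tile_large_image()` groups somas
by single-linkage clustering of their centroids (100 px cutoff), assigns
each group a rectangle containing its soma masks plus a margin, and
`run_tiled()` traces each tile independently, merging trees with globally
unique ids; a soma overlapping a tile boundary belongs to no subset of that
tile, and trees touching an interior tile border are flagged truncated.

## Intensity profiles and AIS statistics

`sample_profile()` resamples a traced neurite at 1 px arclength steps and
reads the image by bilinear interpolation. The local background at each
sample is the mean of a pair of 3×3 windows on the perpendicular to the
local trace direction, placed 2 px beyond the local structure edge on each
side; windows overlapping segmented structures are pushed outward (up to
15 px), a single clear window is used if only one side clears, and the
global median background is the last resort. Corrected = raw − background,
not clamped at zero (clamping would bias areas under low-signal profiles;
it can be applied downstream if wanted).

`ais_metrics()` quantifies the axon initial segment over the first 70 px
(19.6 µm at 0.28 µm/px): the trapezoidal area A_AIS, the variance V_AIS,
and a least-squares Gaussian bell fit g(x) = H·exp(−(x−µ)²/(2σ²))
(Levenberg–Marquardt; H0 = max, µ0 = argmax, σ0 = interval/6, σ bounded to
[1, 70]). The polarity ratio R_AD divides A_AIS by the mean area of two
dendrites over the same interval. The axon is identified as the neurite
with the highest mean corrected target-channel intensity over its first
70 px (AIS markers are enriched there); the dendrite pair is chosen among
the remaining neurites spanning the interval, by closest mean radius to the
axon. Neurons with no qualifying axon are excluded and counted, mirroring
the practice of dropping cells whose axon leaves the field of view.
`compare_groups()` applies two-tailed equal-variance t-tests per metric.

## The phantom generator

`generate_phantom()` renders 512×512 scenes of 1–8 neurons: elliptical somas
(major semi-axis 9–15 px, aspect ≤ 1.4), 3 neurites per soma by default,
smooth centerlines (AR(1) heading increments bounded by 0.03 rad/px),
half-widths 1.8–2.8 px, per-neuron intensities 150–220 over a constant
background plus a linear ramp, and optional Poisson sampling. All geometry
is drawn once from a seeded RNG; the output is bit-identical per seed.

Crossings are *controlled*: a forced crossing dedicates a neuron whose soma
sits on the back-extension of a straight segment through a chosen point of a
host neurite at the sampled angle, so the crossing neurite genuinely
emanates from its own soma. All other inter-neuron interactions are excluded
by construction — an occupancy store with clearance radii forbids accidental
crossings and near-parallel passages, keeps foreign neurites out of every
soma's initialization rings, and keeps crossing sites at least 50 px apart
so no three neurites meet in one blob. This is deliberate: the ground-truth
crossing table is then an exhaustive description of inter-neuron ambiguity,
which is what makes the crossing-resolution rate a well-defined metric. The
cost is equally explicit: phantoms do not model dense tangles,
varicosities, spines, out-of-focus haze or a PSF, so passing the suite
demonstrates correct geometry handling under sparse-culture conditions, not
performance on arbitrarily crowded real fields. `render_bell_signal()`
paints a target channel in which each tube pixel carries the value of its
nearest centerline sample, so the along-arclength profile equals the
requested Gaussian exactly on the centerline — the fixture for validating
profiling end to end.

## Validation conditions and what they show

The package's own checks run on fixed seeded conditions: a standard suite of
twelve 512×512 phantoms with 2–8 neurons and one or two forced crossings at
45–90°, Poisson noise at high SNR; a crossing suite at exactly 45°, 60° and
90°; single-neuron phantoms for profiling; and n = 12 neurons per group for
the two-regime AIS experiment. On these conditions the tracer reaches
neurite-level sensitivity ≳ 0.95 and precision ≳ 0.98 and resolves ≳ 90% of
forced crossings; below ~20° crossing angle resolution degrades, which is
recorded rather than hidden — at such angles the assignment is ambiguous at
the image level. The AIS experiment separates a bell-on-axon regime
(R_AD ≈ 3) from a flat-axon regime (R_AD ≈ 1) with t-test p-values far
below 0.01 through the full measurement chain, not from synthetic numbers.

## Numerical and design choices

* 1-based (row, column) coordinates internally; SWC output in µm with z = 0.
* Threshold 0.16 on the normalized sharpened distance transform; fan step
  π/16; 5% per-step length decay; both unspecified by the design brief this
  implements and therefore exposed in `trace_config()`.
* Deterministic tie-breaks everywhere: seed suppression by (−Df, centre
  distance, index); window selection by (distance, |deviation|, index);
  soma processing by descending area. No stage uses the RNG at run time.
* Soma pairing in evaluation is greedy nearest-pair under a 20 px gate —
  exact for the well-separated somas the phantoms produce; a Hungarian
  assignment would only differ for near-coincident somas.
* Degenerate inputs: empty masks give empty seed sets and empty soma lists;
  an all-foreground mask is rejected (Df undefined); a soma not contained in
  the foreground is rejected; all-zero profiles flag the Gaussian fit and
  the polarity ratio as undefined rather than returning numbers.

## Limitations

Tracing is 2D; loops and anastomoses are outside the model (trees only);
bifurcation detection relies on the angular sub-fan rule and will merge arms
separated by less than one angular step; seed starvation can truncate a
neurite when a neighbouring arbor's trace overruns a shared corridor first
— the conflict log marks such regions for manual review. Real tissue with
densely packed, fasciculating neurites will degrade gracefully but below the
suite's headline numbers.
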