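---
title: "Methods: from bead-sprouting images to network morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bead-sprouting images to network morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sproutgraph)
```

This vignette is the package's own account of its science: the measurement
model, the tunable parameters and why they default the way they do, what
the synthetic phantom does and does not emulate, and the numerical choices
that were genuinely open.

## The measurement model

A bead-sprouting assay grows a branched capillary-like network radially
outward from an endothelial-cell-coated bead (~265 µm diameter) embedded
in fibrin. Confocal z-stacks are acquired daily (calibration 1.25 µm/px by
default) and max-projected. The pipeline reduces each projection to a
planar graph and a small vector of morphometrics:

1. **Segmentation.** Gaussian blur over an 11-pixel window, global
   threshold at 1.17× the mean of the blurred image (strictly above),
   filling of enclosed holes whose 8-connected boundary-pixel count is
   below 200, and the largest 8-connected component.
2. **Bead.** A binary opening with a disk half the expected bead radius
   erases the (order-of-magnitude thinner) sprouts and keeps the bead
   blob; the bead circle is its centroid and equivalent-area radius. All
   pixels within radius + 2 px are cleared; the cleared foreground
   supports the cell-on-bead area *A*~c~.
3. **Skeleton graph.** The sprout mask is thinned to a unit-width
   centerline and converted to a graph whose nodes are junctions, sprout
   bases (contact with the bead) and tips, and whose segments carry the
   classes *tip* (ending in a tip), *bifurcating* (internal) and
   *primary* (touching a base). Tip segments shorter than 50 px
   (62.5 µm) are pruned unless primary.
4. **Metrics.** *A* (sprout area), *A*~c~, *L* (sum of segment lengths),
   *λ = A/L*, *r*~max~ (farthest tip from the bead centre),
   *N*~tip~, *N*~pb~, and *G* = 1 + log~2~(*N*~tip~/*N*~pb~).
   Over a day series, *v*~tip~ = Δ*L*/(Δ*t·N*~tip~) with a trailing
   2-day mean.
5. **Angles.** At each degree-3 junction the three branch directions are
   measured at 60 px of arclength; the smallest of the three sector
   angles is the bifurcation angle, and junctions whose angle bisector
   points back toward the bead (angle to the radial vector above 90°)
   are excluded as anastomoses.
6. **Growth statistics.** Logistic fits of *L(t)* and *A(t)*,
   exponential fits of segment-length distributions, MAPE/WMAPE, and the
   n-sigma comparison test.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `blur_kernel_px` | 11 | px | the stated recipe; σ = kernel/6 (±3σ support), so σ ≈ 1.83 px |
| `threshold_factor` | 1.17 | – | relative-mean global threshold; assumes a substantial nonzero background (see phantom intensities below) |
| `hole_perimeter_px` | 200 | px | 250 µm at calibration; boundary measured as 8-connected boundary pixels of the hole, the same tracer the tests use |
| `bead_radius_um` | 132.5 | µm | the 265 µm bead |
| `bead_margin_px` | 2 | px | clearance beyond the detected radius |
| `skeleton_smooth_px` | 2 | px | binary opening before thinning; suppresses boundary-noise spurs and centerline wiggle; must stay below half the thinnest sprout |
| `prune_length_px` | 50 | px | 62.5 µm spur cut, primaries exempt |
| `base_contact_px` / `base_reach_px` | 10 / 30 | px | base classification (below) |
| `arm_length_px` | 60 | px | ~75 µm; calibrated against manual angle measurement in the assay literature |
| `bin_width_um`, `min_length_um` | 25, 62.5 | µm | segment-length histogram; lower cut at the pruning scale where skeletonization over-produces short segments |
| `velocity_window_days` | 2 | d | trailing moving average for *v*~tip~ |

The mean used for thresholding includes the bright bead region; the 1.17
factor implicitly compensates. Both the factor and the choice of mean are
configurable.

## Skeleton-to-graph: the numerical choices

**Branch counting.** On 8-connected thinned skeletons, up to a third of
the pixels along shallow-angle lines have 3–4 neighbours without being
junctions (staircase patterns). Degrees are therefore computed on a
*reduced* pixel adjacency in which a diagonal edge is dropped whenever one
of its two orthogonal corner pixels is itself on the skeleton; a pixel is
a junction iff its reduced degree is ≥ 3. Adjacent junction pixels merge
into one node at their rounded centroid.

**Path lengths.** Segment length is the sum of inter-pixel steps, with
diagonal steps weighted √2. Zhang–Suen thinning leaves 4-connected
staircases at shallow angles, which would inflate that metric by up to
40%; traced polylines are therefore simplified to minimal 8-chains (an
interior vertex whose two neighbours are themselves 8-adjacent is
dropped). The residual digitization bias of the √2 metric is ≈ +5% in the
worst direction and +2–4% averaged over orientations, partly cancelled by
the ~half-width retraction of thinned endpoints; the phantom round-trip
tests bound the end-to-end error at 5%.

**Sprout bases.** Thinning retracts the endpoint of a stroke cut at the
bead-removal circle by about half the stroke width — and much more when
the cut is oblique (a 19 px retraction was observed at 10 µm width). An
endpoint-distance rule alone is therefore unreliable. When the sprout mask
is available, the package floods the mask from its contact arcs with the
cleared disk out to `base_reach_px` (30 px) and classifies endpoints
inside that region as bases; the distance rule (within `base_contact_px`
of the circle) is the fallback.

**Pruning** iterates to a fixed point: removing one spur can expose
another. Junctions left with two incident segments are dissolved by
concatenating the segments (lengths add exactly); junctions left with one
become tips. Self-loops shorter than 10 px are discarded as pinhole
thinning artifacts; longer loops (real anastomoses) are kept.

## Angle measurement and its bias

Thinning a V-shaped stroke union displaces the skeleton branch point
outward from the true apex by ≈ (w/2)/sin(φ/2) (w = stroke width) and
curves the branches toward it. Vectors taken literally from the junction
node to the 60 px arm points over-read the angle by 5–10° at typical
widths — the very effect the fixed arm length is meant to control, but not
eliminate. The package instead uses the *branch chord* between the
polyline points at arclengths `arm/4` and `arm`: for straight branches
this is exact, and rendered test junctions at 50°/70°/90° measure within
~1–3°. Setting `arm_offset_px = 0` restores the literal rule. The
smallest-of-three selection cannot return more than 120° (the three sector
angles sum to 360°), so angles above 120° are unmeasurable by
construction; the 90° bisector-to-radial boundary is classified as a
bifurcation (inclusive).

## The phantom: a stated world

`phantom_spec()` defaults describe one realistic high-VEGF bead assay:

* bead radius 132.5 µm, 6 primaries placed uniformly on the rim subject to
  a 20° minimum gap (two bases closer than a stroke width are unresolvable
  in pixels, and observed primaries are distinct);
* tips advance in 1 px arclength steps with Gaussian direction jitter
  (σ = 1°/step) and a weak outward drift (weight 2×10⁻⁴ per step). The
  drift weight is a free parameter; it was set so that the direction
  relaxes toward radial over ~5000 px, keeping the curvature bias of the
  60 px angle arms under a degree while preserving outward-directed
  growth. Strong drift (e.g. 0.2/step) erases the generating branch
  geometry within a few pixels and is not compatible with measuring the
  drawn angles at all;
* branching is a Poisson process with rate 1/l\* per unit arclength
  (l\* = 100 µm), daughters deviating ±φ/2 with
  φ ~ Normal(70°, 18°) truncated to (0°, 180°);
* total length follows the logistic schedule Y~max~ = 4000 µm,
  k = 1.2/day, t₁ = 7 d over days 0–14, shared round-robin among active
  tips and capped at 100 µm/day per tip;
* rendering: strokes of width 10 µm and the bead disk at intensity 3200
  over a background of 2000 with Gaussian noise (σ = 100), clamped to 16
  bits. The modest foreground/background contrast (~1.6×) mimics GFP
  confocal projections and is what makes a *relative-mean* threshold
  (1.17×) meaningful: on a zero background the blurred stroke fringes
  would pass any threshold tied to the global mean and dilate every
  structure;
* tips terminate when they approach foreign strokes within 2.5 widths
  (keeping rendered surfaces separated even after blur dilation) or reach
  the frame margin.

Identical spec + seed gives bit-identical networks; rendering noise is
seeded separately per day.

**What a green round-trip test establishes** — that segmentation,
skeletonization, graph extraction, pruning, counting, length and angle
measurement are mutually consistent at realistic geometry, contrast and
noise. **What it does not establish** — performance on real images with
uneven illumination, autofluorescent debris, out-of-focus haze,
anastomoses, or drift between days; none of these are emulated.

### Censoring of completed segment lengths

A subtlety worth stating precisely: with binary branching at rate 1/l\*
per unit arclength in an exponentially growing tip population, the
*completed* (bifurcating) segments observed at any finite time are not
Exponential(l\*). The standing tips always hold a constant share of the
length, and a segment is observed complete only if its drawn length was
shorter than its lineage's remaining growth — classic inspection bias. In
the pure exponential phase the tip-age distribution is itself
Exponential(l\*) in arclength, so completed lengths are Exponential with
scale exactly l\*/2. The property tests assert this parameter-free
prediction (and the exponential *shape*, which is what the assay data
show); the mechanistic inter-branch rate along any single lineage remains
1/l\* as specified. By the same token, a fitted characteristic length from
real data is an observed population scale, not a per-lineage branching
rate.

### Well-separated fixtures

Exact recovery of *N*~tip~ and *N*~pb~ is only meaningful when branches
are separated beyond the pixel resolution and no leaf straddles the
pruning threshold (a stub within ~half a stroke width of 62.5 µm is
genuinely undecidable). The round-trip fixtures therefore enable three
generator options that are off by default: a branch-free refractory
arclength of 35 µm (3.5 stroke widths), a topology freeze at the
inflection day so every surviving leaf outgrows the pruning scale, and
retraction of terminated stubs shorter than 80 µm (failed sprouts do
regress in real assays). Ground truth for the comparison applies the same
pruning rule as the pipeline to the generated tree
(`ground_truth_metrics()`).

## Growth statistics: numerical choices

**Logistic fits** use `nls` (port algorithm) with positivity bounds on
Y~max~ and k. Initialization: Y~max~⁰ = 1.05·max(Y); t₁⁰ from linear
interpolation of the half-maximum crossing; k⁰ from the local slope there
via the midpoint identity slope = Y~max~k/4. Standard errors come from the
linearized covariance at the optimum. The derived quantities
t₀ = t₁ − 2/k (x-intercept of the inflection tangent) and
(dY/dt)~max~ = Y~max~k/4 are exact identities of the fitted parameters,
asserted as such. Non-convergence returns a structured failure carrying
the initializer and residuals rather than an error. MAPE is undefined when
a fitted point's actual value is zero (the infinite-error hazard); the fit
then reports `NA` for MAPE while WMAPE remains defined.

**Exponential fits** histogram lengths with a fixed 25 µm bin width
starting at the 62.5 µm pruning cut, normalize to a density, and fit
ln *P(l)* against the bin centre by ordinary (unweighted) least squares,
mirroring plain linear regression; l\* = −1/slope with its standard error
propagated as se(slope)/slope². One guard was added after simulation:
bins below a tenth of the peak density are excluded. Keeping 1-count tail
bins while 0-count bins drop out floors the observed tail, flattens the
slope, and biased l\* upward by ~25% at n = 1000 (3·SE coverage 74%);
the relative-density cut reduces the bias to ~6% (coverage ~98%) and —
unlike a minimum-count cut — keeps the fit exactly invariant under
duplicating every sample. Whether the reference analysis normalized
density or counts does not affect the slope, only the intercept.

**n-sigma test**: |x₁−x₂| ≤ n·√(u₁²+u₂²); symmetric in its two arguments
and monotone in n. TRUE means the two fitted values are statistically
compatible at n combined standard errors.

**Tip velocity** divides each day's length increment by the tip count *at
the later day* of the pair (the increment is laid down by the tips present
while growing into that day); the alternative convention is one flag away.
The 2-day moving average is trailing, matching daily sampling.

## Known limitations

* 2D projections only; no z-resolved analysis, no inter-day registration.
* Angles above 120° are unmeasurable (smallest-of-three construction).
* Degree-4+ junctions (X-structures from partial fusion) are skipped in
  angle statistics, not decomposed.
* The anastomosis filter is geometric (outward bisector) and cannot
  distinguish tip-to-tip fusion loops from bifurcations on topology alone.
* The length metric inherits the ~2–5% digitization bias of 8-connected
  chains; the acceptance bound (5%) absorbs it.
* The phantom shares no optics model (PSF, depth attenuation) with real
  confocal data; intensities are flat per structure.
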