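# sproutgraph

Morphometry of bead-sprouting microvascular networks.

In the fibrin-gel bead-sprouting assay, endothelial cell-coated beads
(~265 µm polystyrene spheres) are embedded in a hydrogel and imaged daily
for about two weeks while capillary-like sprouts grow radially outward,
elongating and bifurcating into a star-like branched network. `sproutgraph`
turns those fluorescence projections into quantitative morphometrics:

* **Segmentation** — Gaussian blur (11 px kernel), global threshold at
  1.17× the mean intensity, filling of holes with boundary under 200 px,
  largest connected component, bead detection by size-selective
  morphology, bead removal.
* **Skeleton graph** — topology-preserving thinning to a centerline,
  conversion to a graph of nodes (junctions, sprout bases, tips) and
  segments (tip / bifurcating / primary), with iterative pruning of tip
  spurs shorter than 50 px (62.5 µm).
* **Morphometrics per bead per day** — sprout area *A*, cell-on-bead area
  *A*<sub>c</sub>, total network length *L*, mean sprout width
  *λ = A/L*, maximal tip radius *r*<sub>max</sub>, tip count
  *N*<sub>tip</sub>, primary-branch count *N*<sub>pb</sub>, and the
  generation number *G* = 1 + log₂(*N*<sub>tip</sub>/*N*<sub>pb</sub>);
  ensemble tip velocity *v*<sub>tip</sub> = Δ*L*/(Δ*t·N*<sub>tip</sub>)
  with a 2-day trailing average.
* **Bifurcation angles** — at each degree-3 junction, arm points at 60 px
  (~75 µm) of arclength along each branch, the smallest of the three
  sector angles as the bifurcation angle φ (never above 120°), and an
  outward-bisector filter that excludes anastomoses (bisector pointing
  back toward the bead).
* **Growth statistics** — nonlinear least-squares logistic fits
  *Y(t) = Y*<sub>max</sub>/(1+e<sup>−k(t−t₁)</sup>) with derived onset
  *t₀ = t₁ − 2/k* and maximal rate *Y*<sub>max</sub>*k*/4; semi-log
  exponential fits *P(l) ∼ e^(−l/l\*)* of segment-length distributions;
  MAPE/WMAPE fit metrics, the n-sigma comparison test, and a Damköhler
  number utility (k·d²/D ≈ 85 for VEGF uptake in a 1.6 cm well).
* **Phantom generator** — ground-truthed synthetic bead networks (radial
  branching random growth with exponential inter-branch lengths,
  quasi-Gaussian branch angles, a logistic total-length schedule, rendered
  16-bit frames with noise), so the entire pipeline is validated by
  round trip without any raw microscopy data.

## Worked example

```r
library(sproutgraph)

spec <- phantom_spec(rng_seed = 42)       # a realistic high-VEGF bead assay
net  <- generate_network(spec)
net
#> <phantom_network 94 segments, 44 bifurcations, L = 3999 um at day 14>

img <- render_image(net, day = 12)        # 16-bit frame, 1.25 um/px
res <- process_image(img, run_config())   # segment -> skeleton -> graph -> metrics
print(res$record, row.names = FALSE)
#>  bead_id day condition   A_um2   Ac_um2     L_um lambda_um  rmax_um N_tip N_pb        G
#>        1  12           46512.5 56134.38 3808.116  12.21405 514.7792    15    5 2.584963

ad <- angle_distribution(res$graph)
#> bifurcation angles: n = 8, mean = 62.9 deg, SEM = 5.5 deg
```

The record reads: at day 12 this bead carries 46 500 µm² of sprouts of
total centerline length 3 808 µm (mean width 12.2 µm), reaching 515 µm
from the bead centre, with 15 growing tips on 5 primary branches —
about 2.6 branch generations. Eight junctions passed the anastomosis
filter, averaging 62.9° (the generator drew angles around 70°).

Fitting the measured length curve over all 15 days recovers the growth
schedule the phantom was built on (Y_max = 4000 µm, k = 1.2/day, t₁ = 7 d,
hence onset t₀ = 5.33 d):

```r
L   <- sapply(net$days, function(d)
  process_image(render_image(net, day = d), run_config())$record$L_um)
fit <- fit_logistic(time_series(net$days, L, "L", "um"))
fit
#> <logistic_fit Y_max = 3825 +/- 21, k = 1.146 +/- 0.033 /day, t1 = 7.22 +/- 0.029 d>
#>   onset t0 = 5.475 d, (dY/dt)_max = 1096 /day, WMAPE = 0.0133
```

Batch processing (directories of `bead<i>_day<d>.tif` stacks, or phantom
mode) runs through `run_pipeline(run_config(...))` or the CLI at
`inst/scripts/sproutgraph`; outputs are `records.csv`, `angles.csv`,
`fits.json`, `summary.csv` and a structured log, all stamped with the
configuration hash.

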