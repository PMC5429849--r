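---
title: "Star-shaped template cuts for seeded lesion segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-shaped template cuts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starcut)
```

## The segmentation model

`starcut` segments a focal lesion in a 2D B-mode ultrasound image from a
single seed point placed inside it. The construction is:

1. **Circular ray template.** `R` rays leave the seed at equidistant angles,
   clockwise in screen coordinates starting east. Along each ray, `L` nodes
   are placed at distances `(i + 1) * radius / L`, `i = 0, ..., L - 1`; the
   seed itself is not a node (it contributes a region statistic instead, so
   the innermost sample starts one spacing away from the click).
2. **Costs.** A local average gray value `m` is computed over a disc of
   radius `avg_radius` around the seed. Each node's cost is
   `c = |m - g|` for its bilinearly sampled intensity `g`: near zero inside
   a homogeneous lesion, large where the ray has crossed into tissue of
   different echogenicity.
3. **Terminal weights.** Per ray, the innermost node is bound to the source
   with capacity `c[1]`, the outermost to the sink with capacity `c[L]`, and
   every interior node carries the difference of adjacent costs
   `w = c[i] - c[i-1]`, bound to the sink when `w >= 0` and to the source
   with `|w|` otherwise. A large positive `w` marks the lesion-to-tissue
   transition; cutting such a node to the source side is expensive, so the
   minimum cut settles just inside it.
4. **Structural edges.** "Infinite" intra-edges run down each ray (node `i`
   to `i - 1`), which forces the source side of any finite cut to be a
   per-ray prefix — the star-shape guarantee: each ray crosses the boundary
   exactly once. Infinite inter-edges connect each node to its two cyclic
   neighbour rays at level `max(i - delta_r, 0)`, which bounds the cut-level
   difference of adjacent rays by `delta_r` (contour smoothness).
5. **Min cut.** The minimum s-t cut of this network is computed by max-flow
   and read off as a cut vector `k[r]` (lesion-side node count per ray),
   then converted to a polygon through the inter-node midpoints and
   rasterised to a mask.

The model assumes the lesion is star-shaped around the seed, roughly
homogeneous in echogenicity near the seed, and delimited by an intensity
transition within the template radius.

## What the cut actually optimises

Summing the severed capacities telescopes, per ray, to

```
cost(k) = cost(0) + c[k - 1] - 2 c[0],    1 <= k <= L - 1,
```

so up to the smoothness coupling the cut places each ray's boundary at the
node whose intensity is *closest to the seed average*, with collapse
(`k = 0`) priced at `2 c[0]`. Two consequences matter for interpretation:

* On a noiseless piecewise-constant lesion the interior costs are exactly
  zero, every interior level ties, and the *choice among tied minimum cuts*
  decides the output (next section).
* Under speckle the interior cost field is `|noise|` with no radial trend,
  so the minimising ring is selected by the noise realisation rather than by
  the true boundary. This is intrinsic to the published cost model — it has
  a boundary term but no regional term — and is exactly what the package's
  speckled-suite test measures (see *Limitations*).

## Canonical cut and collapse

Minimum cuts of this network form a lattice: the set of minimisers is closed
under pointwise `min`/`max` of cut vectors, with two deterministic extremes.
We return the **maximal** minimum cut — the complement of all nodes that can
still reach the sink in the residual network. Rationale: the minimal cut
degenerates on exact ties. On any noiseless phantom, collapse ties with the
boundary cut (`cost(boundary) - cost(0) = c[k-1] - 2 c[0] = 0` when interior
costs vanish), so the minimal choice would always return an empty
segmentation; the maximal choice expands through the zero-cost interior and
stops at the first node where cost rises — the lesion boundary.

Collapse is reported (never raised as an error) in two situations:

* the cut keeps no node (`k = 0` everywhere), or
* the maximal minimum cut is the *full template* (`k = L` everywhere). If
  even outlining the whole template costs nothing extra, there is no
  intensity boundary anywhere inside the template: the canonical feedback
  when the seed hovers homogeneous parenchyma. This is how a strictly
  uniform image collapses.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `radius` | 60 | px | template radius; must exceed the lesion radius, and the boundary must lie inside it |
| `rays` (`R`) | 60 | — | angular resolution (6 degrees); sub-pixel arc spacing at typical lesion radii |
| `nodes` (`L`) | 40 | — | radial resolution; node spacing `radius / L` bounds boundary accuracy to about half a spacing |
| `delta_r` | 2 | levels | smoothness: max cut-level difference between adjacent rays; 0 forces a concyclic (circular) contour, larger values follow irregular boundaries |
| `avg_radius` | 3 | px | seed averaging disc; a robust local mean that does not swallow boundary pixels |

`R = 60`, `L = 40` keep the graph at 2 402 nodes and under 10 000 edges, for
which a full re-solve takes well under a second — the package re-runs the
entire pipeline per seed rather than warm-starting, which is fast enough for
the interactive loop.

## The phantom generator

`phantom_spec()`/`generate_phantom()` emulate B-mode appearance as a
piecewise-constant echogenicity map — uniform parenchyma (default level
100), one elliptical lesion, optionally a darker halo ring — multiplied by
an i.i.d. gamma speckle field with mean 1 and standard deviation
`speckle_scale`, then blurred with a Gaussian point-spread of `blur_sigma`
pixels (default 1.5 px, a plausible resolution-cell scale at typical
abdominal imaging geometry; the blur also gives the speckle its grain-like
spatial correlation). Ellipses reflect the roughly spherical growth of
hepatic metastases. The five standard echo-pattern classes are covered:
hyper-, iso- and hypoechoic, and iso/hyper with a hypoechoic halo.

Suite generation (`phantom_suite()`) draws semi-axes 15–28 px, axis ratios
up to about 1.4, lesion levels 55–70 (hypo) or 130–150 (hyper), halo widths
4–7 px at levels 45–60, and a centre jitter up to 5 px, all under one master
seed. "Iso" lesions are drawn *nearly* isoechoic (98–100 against background
100, inside the 2% iso band): a lesion whose level matches the background
exactly is invisible to an intensity cost even across a halo, because every
cut level beyond the rim ties with every interior level. Purely isoechoic
lesions without halo are generated (class support) but are undetectable by
design and excluded from recovery expectations.

What the phantoms deliberately do **not** model: attenuation and
time-gain-compensation gradients, posterior enhancement/shadowing,
curvilinear fan geometry, log-compression characteristics, and spatially
correlated parenchymal texture beyond the PSF blur. Passing phantom tests
therefore demonstrates correct mechanics of the pipeline on controlled
contrast, not clinical-grade accuracy.

## Numerical choices

* **Infinity** is the finite capacity `1 + sum(all terminal capacities)`:
  any cut severing such an edge costs more than severing every terminal edge
  at once, so structural edges are provably never cut, for any float or
  integer solver.
* **Off-lattice sampling** is bilinear; node positions outside the image are
  clamped to the nearest border pixel, keeping the graph structure identical
  for seeds near the border.
* **Rasterisation** of the contour polygon uses the standard even-odd
  scanline rule, half-open in both axes, so a square of side `s` covers
  exactly `s^2` pixel centres and adjacent polygons never double-count
  pixels.
* **Tie tolerance**: the exhaustive oracle treats costs within `1e-9`
  (relative) as tied, matching float max-flow arithmetic on gray-value
  magnitudes.
* **Boundary placement** is the midpoint between the last inside and first
  outside node: unbiased between the two samples that bracket the
  transition; no spline smoothing is applied, matching the dotted outline a
  user of the interactive tool sees.
* **Degenerate inputs**: uniform images collapse; empty masks are rejected
  by the metrics (Dice of two empty masks and Hausdorff of any empty mask
  are undefined and raise errors); collapsed predictions in batch
  evaluation score Dice 0 and a missing Hausdorff value.

## Verification strategy and problem sizes

The minimum-cut solver is verified against an independent exhaustive oracle
(`brute_force_min_cut()`) that enumerates all smoothness-feasible cut
vectors — including the same maximal tie-break — on 100+ random instances of
up to 6 rays and 5 nodes; duality (cut cost equals max-flow value),
star-shape, smoothness and the never-cut-infinity property are asserted on
every solve. Metrics are verified against direct all-pairs formula
evaluation on masks up to 64 x 64 and against an independent computational
geometry implementation. End-to-end tests use 120–200 px phantoms and a
20-case speckled suite; a full default-size segmentation of a 512 x 512
image runs in roughly a quarter second on one core.

## Known limitations

* **No regional term.** As derived above, on texture-free speckled interiors
  the cut position is noise-selected; the speckled-suite Dice test
  documents this honestly rather than passing by construction. In clinical
  use the operator compensates interactively — sweeping the seed and judging
  the contour — and published evaluations of this family of methods also
  used additional helper seeds; neither aid is available to a fixed
  single-seed batch protocol.
* Only star-shaped lesions around the chosen seed can be outlined; the
  boundary must fall inside the template radius, and lesions larger than the
  template collapse (reported as "no boundary").
* Iso-echoic lesions without halo are undetectable by an intensity-cost
  model.
* The Hausdorff distance is reported in pixels; conversion to millimetres
  depends on probe and depth and is out of scope.
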