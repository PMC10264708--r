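---
title: "From rhizobox frames to root-system traits: the rhizotrack pipeline"
author: "rhizotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rhizobox frames to root-system traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrack)
```

# The measurement problem

Seedlings grown in thin, glass-fronted soil containers (rhizoboxes) expose
their root systems in approximately two dimensions, and a fixed camera
taking a frame every few minutes turns early root development into a
time-lapse sequence. What a root biologist wants from such a sequence is a
small set of architecture traits per frame: how much root there is (area,
total length), how far the system reaches (longest root, bounding-box
width, convex hull area), and at what angles it grows (primary root angle,
the root growth angle RGA, and the seminal root growth angle SRGA — the
angle between the first two seminal roots with its vertex at the grain).
Contrasting barley genotypes differ strongly in SRGA, so an automated
measurement must recover angles to a few degrees to be useful.

rhizotrack implements the measurement chain as composable steps:

1. **Binarization** (`binarize()`): a threshold rule turns a frame into a
   `BinaryRootMask`. Three rules are provided — a fixed intensity cut, a
   per-channel color box (the natural rule when roots were manually traced
   in a saturated color on top of the photograph), and an automatic global
   threshold that maximizes between-class intensity variance over the
   256-bin histogram. `cleanMask()` removes speckles smaller than
   `min_object_px` (8-connected) and fills enclosed background holes
   smaller than `fill_holes_max_px` (4-connected).
2. **Skeletonization** (`skeletonize()`): topology-preserving thinning to
   a one-pixel skeleton (details below).
3. **Graph construction** (`buildGraph()`): the skeleton becomes an
   undirected multigraph whose nodes are endpoints, junction clusters,
   isolated pixels and cycle anchors, and whose edges are maximal
   degree-2 pixel chains carrying geodesic lengths. `pruneSpurs()`
   suppresses short thinning barbs and collapses 1-2 px self-loops.
4. **Traits** (`extractTraits()`): all per-frame traits from the mask,
   the graph and the grain landmark.
5. **Series** (`computeSeries()`, `detectEmergence()`): per-frame records
   ordered by hours after sowing (HAS), with emergence detection.

Throughout, pixel coordinates are 0-based with x rightward and y downward,
and a single isotropic scale in mm per pixel converts to physical units
(scale 1 reports pixel units; rhizobox imaging is typically around
10 px/mm).

# Skeletonization

No single "the" skeleton exists for a digital shape, so the choices are
spelled out:

* Foreground is 8-connected, background 4-connected — the standard
  complementary pair that avoids topological paradoxes.
* Thinning runs Guo–Hall two-subiteration erosion, but each
  subiteration's parallel candidate set is applied *sequentially* under a
  live simple-point recheck: a pixel is deleted only while its Yokoi
  connectivity number (for 8/4 connectivity) is 1 and it has at least two
  foreground neighbours. The recheck guarantees exactly that the number
  of 8-connected components and of 4-connected background holes never
  changes, and that endpoints are never deleted — purely parallel
  schemes notoriously annihilate isolated 2x2 blocks, and Zhang–Suen
  erodes two-pixel diagonal ribbons from their ends, which visibly
  shortens oblique root tips. The Rutovitz crossing number is *not* a
  valid simple-point test here (it misses diagonally bridged neighbour
  runs), which is why the Yokoi number is used.
* A final sequential pass erodes remaining simple non-endpoint pixels
  (staircase and corner redundancy), taking candidates in order of
  decreasing neighbour count so ribbon interiors thin before ribbon ends.
* Each endpoint is then extended forward through the mask to the local
  extremity ("tip extension"). Rasterized roots end in round caps and the
  erosion otherwise stops at an orientation-dependent position up to
  ~1.5 px short of or beyond the true tip; extension pins the skeleton
  tip to the cap extremity at every orientation. The extension follows
  the outgoing direction (straight ahead preferred, 45 degrees
  tolerated) and never touches the skeleton elsewhere, so thinness and
  topology are preserved.
* The image border is background: roots running off the frame still end
  in endpoints.

The whole operator is idempotent, and the package's test suite checks
subset, component and hole preservation, and idempotence on seeded random
masks.

# Skeleton graph and lengths

Pixel degree (number of 8-neighbour skeleton pixels) classifies skeleton
pixels: 1 = endpoint, 2 = chain, >= 3 = junction. Mutually adjacent
junction pixels — thinning produces small clumps at crossings — merge into
a single junction node placed at the integer-rounded cluster centroid.
A pure cycle (all pixels degree 2) gets one `cycle_anchor` node at its
lexicographically smallest (y, x) pixel and a self-loop edge. Every other
skeleton pixel belongs to exactly one edge chain; chains are stored
inclusive of their terminal node pixels.

Lengths use the geodesic pixel metric: 1 per axial step, sqrt(2) per
diagonal step, times the scale (`chainLength()`). This metric is simple
and deterministic but *not* unbiased for Euclidean length: a straight
digital line at angle theta measures `max(|cos|, |sin|) +
(sqrt(2) - 1) * min(|cos|, |sin|)` per unit length, up to ~8% above 1
near 22.5 degrees. No corner-cut correction is applied; instead the
synthetic generator reports ground truth in the same metric
(`total_length_digital_mm`) so that measurement error can be separated
from metric bias. When validating measured lengths, add half a stroke
width per free root end — `(strokeWidth - 1) / 2` px in the pixel-center
convention — for the rasterizer's protruding end caps.

`pruneSpurs(graph, minLenMm)` iteratively removes edges shorter than the
threshold that end in an endpoint, and short self-loops at junctions,
then rebuilds the graph so a junction reduced to degree 2 dissolves and
its chains merge. The default threshold of 5 px times the scale
suppresses 1-3 px thinning barbs without deleting lateral roots at the
generator's default stroke width (3 px). An edge that is its component's
only edge is never removed.

# Seed-anchored traits

The grain position is a manual landmark. Because the grain body itself is
not root, a disk of `seedExclusionRadius` (default 10 px) around it is
removed from the mask before any trait is computed; synthetic fixtures
render no grain body, so examples and tests on generated images set the
radius to 0.

* **Primary root** = the maximum-geodesic-length simple path from the
  grain-nearest skeleton position to any endpoint, found by exhaustive
  depth-first enumeration (skeleton graphs are small). If the nearest
  skeleton position falls inside a chain — e.g. a two-root system whose
  apex at the grain is a plain degree-2 bend — the chain is split there
  into an `anchor` node first, so paths genuinely start at the grain.
  Ties prefer more edges, then the smallest terminal (y, x).
* **Primary root angle** is the orientation of the principal axis
  (dominant eigenvector of the coordinate covariance; orthogonal
  regression) of the primary path's pixels, in (0, 180] degrees to the
  horizontal: vertical = 90. Ordinary y-on-x regression would be
  degenerate for near-vertical roots, which are the common case.
* **Seminal tips** (`seminalTips()`): endpoints are partitioned by the
  first edge their maximum-length path takes out of the start node (per
  connected component when seed exclusion splits the system); the k
  longest-path partitions each contribute their farthest-from-grain
  endpoint. The mapping of graph endpoints to "the first two seminal
  roots" is a length-order convention — temporal emergence order is not
  recoverable from a single frame — and manual tip overrides on the
  `Landmarks` object take precedence verbatim.
* **RGA** is a protractor-style reading in [0, 90]:
  `atan(|dy| / |dx|)` between the horizontal through the grain and the
  line to the most distant tip (90 when straight below).
* **SRGA** is the vertex angle at the grain between the lines to the
  first two seminal tips, via the arccosine of the normalized dot
  product, in [0, 180].
* **Areas and extents**: root area is the foreground count times
  scale squared; convex hull area is the shoelace area of the hull of
  foreground pixel centers; bounding-box width is the inclusive pixel
  extent `(max_x - min_x + 1) * scale`.

Frames with no root material yield an all-zero record with absent angles;
per-trait failures (too few branches for an angle) become `NA` rather
than errors, so a series never aborts.

# Time series and emergence

`computeSeries()` applies the pipeline per frame in timestamp order;
unreadable frames become absent rows. Emergence is the timestamp of the
first record whose root area reaches `min_area_px` (default 20 px,
roughly a 7 px root segment at stroke 3) sustained for two consecutive
frames — the persistence requirement rejects single-frame speckle. With
the default analysis cadence of 40 min (every 10th frame of a 4-min
capture) and realistic elongation around 1 mm/h at 10 px/mm, a root
crosses the area threshold within one frame interval of its true
emergence, which is the accuracy the tests assert.

# The synthetic generator

Real rhizobox images of this kind are not publicly deposited, so the
package ships a parametric generator that doubles as the test oracle.
A `RootSystemSpec` defines roots by heading (degrees from the downward
vertical, positive clockwise), emergence time, growth rate, length cap,
constant curvature (deg/mm), seeded per-step heading wobble, and optional
branching from a parent root. Growth is linear:
`length(t) = growth_rate * max(0, t - emergence)`, capped at
`max_length` — so every trait has a closed-form or directly computable
ground truth (`groundTruth()`): per-root lengths and tips, total length
(Euclidean and digital-metric), SRGA from the tip vectors of the first
two grain-anchored roots, hull area and bounding width of the centerline
vertices with stroke-inflated variants for comparing against
mask-derived measurements.

Rasterization sweeps a disk of radius `strokeWidth / 2` along the
centerline polylines (round caps), and `renderSeries()` writes PNG frames
at a fixed cadence with the ground truth alongside; identical seeds give
byte-identical output. Defaults were chosen once to mirror the imaging
conditions the pipeline targets: 0.1 mm/px, stroke 3 px, growth
1.2 mm/h, first emergence at 64 HAS, and two genotype presets with
seminal spreads of 109.3 and 62.7 degrees for end-to-end demonstrations.
What the generator deliberately does *not* emulate: soil texture and
background clutter, uneven IR illumination, lens distortion, root
overlap with the seed body, root hairs, and gravitropic curvature beyond
constant bend plus wobble. Passing recovery tests therefore demonstrate
the correctness of the measurement chain on clean masks, not robustness
of thresholding on difficult photographs — on real data the binarization
step (or manual tracing) carries that burden.

# Numerical choices and degenerate inputs

* Thresholds: intensities are integers 0-255; the automatic rule's
  between-class variance is flat between well-separated modes, so the
  midpoint of the maximizing plateau is used (deterministic and
  mode-symmetric).
* Angle traits on synthetic two-root systems are measured with the
  default 10-px seed exclusion: the overlapping stroke caps at the grain
  form a blob whose thinning residue can masquerade as a third branch,
  exactly the artifact the exclusion disk exists for. Emergence and
  single-root length recovery use radius 0, since the generator renders
  no grain body and the proximal root extent would otherwise be
  truncated.
* All tie-breaks in graph construction (node ids, cycle anchors, path
  terminals, tip partitions) are lexicographic in (y, x), so reruns are
  bit-identical.
* Collinear or singleton foregrounds have hull area 0; a single pixel
  has bounding width 1 px; a 1-pixel chain has length 0.
* An empty graph raises "no root material" from `longestRoot()`;
  `extractTraits()` converts that to an all-zero record.
* The rank comparison of genotype groups in the validation suite uses
  the Wilcoxon rank-sum test at alpha = 0.05.

# Problem sizes in tests and validation

The packaged checks run at deliberately modest sizes chosen as
representative rather than exhaustive: random masks up to 64 x 64 for
topology properties (50 cases), thin skeletons up to 40 x 40 against the
brute-force chain enumerator (100 cases), abstract graphs of up to 12
edges against exhaustive path enumeration, a 20-case recovery grid of
single roots (20-150 px long, headings -55 to 45 degrees, stroke 3 px)
plus two-root systems for hull and SRGA recovery, and 200 replicates of
a 7-vs-4 genotype comparison on 400 x 260 px frames. The acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch at a fixed seed.

# Known limitations

* Traits are 2-D projections; depth excursions shorten lengths.
* The geodesic metric's orientation bias (up to ~8%) is inherent and
  documented rather than corrected.
* Root order classification beyond the seed-anchored longest path (e.g.
  lateral hierarchies) is out of scope, as is diameter/width profiling.
* Emergence detection reports analysis-cadence resolution; at 40-min
  spacing the true emergence may precede detection by up to one
  interval.
* The length-order convention for "first two seminal roots" can disagree
  with temporal order when a later seminal outgrows an earlier one; use
  manual tips where that matters.
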