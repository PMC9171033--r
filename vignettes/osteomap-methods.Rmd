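---
title: "Non-linear osteometric modeling of longitudinal bone surface growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-linear osteometric modeling of longitudinal bone surface growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomap)
```

## The problem

A growing bone changes shape non-uniformly: in the mandible, the condylar
head and posterior ramus grow much faster than the corpus. Longitudinal
imaging (monthly CBCT of growing minipigs is the motivating setting) yields a
time series of triangulated surface models, one per instance. osteomap turns
such a series into continuous per-vertex growth-rate maps: for every vertex
and every month, the local percent change of the surface per month, plus its
anatomical direction components.

The package operates on closed triangulated surfaces in mm. One "month" is a
four-week interval; instance times default to `1, 2, ..., K` months.

## The correspondence model

Given the model at instance *i* with vertices `P_{i,j}` and the model at
instance *i+1*, the corresponding vertex for *j* maximizes the correlation

\[
f \;=\; \operatorname{corr}(Q_{i,j},\, Q_{i+1,j})
   \;=\; \frac{\operatorname{cov}(Q_{i,j},\, Q_{i+1,j})}
               {\sigma_{i,j}\,\sigma_{i+1,j}}
\]

between the neighborhood point sets `Q` (all vertices within radius *r* of
the center), subject to the rigid constraint
\(P_{i+1,j} = R_i P_{i,j} + v_i\).

Two quantities in this objective are underdetermined and the package fixes
them as follows.

**Pairing.** A correlation needs matched samples of equal length, but the two
neighborhoods generally have different cardinalities. The package transforms
the source neighborhood by the current rigid estimate, pairs every
transformed source point with its nearest target point, centers both matched
lists on their own centroids, and computes the Pearson correlation of the two
flattened coordinate vectors (length 3m). An `"index"` pairing is available
when a positional correspondence is known a priori. A consequence of
nearest-neighbor pairing worth knowing: a target set that is the point
reflection of the source through its centroid scores exactly −1 only under
index pairing — nearest-neighbor pairing provably never pairs the
extreme points with their own reflections.

**The rigid constraint pins the center.** The constraint says the transform
maps the source vertex exactly onto its correspondent, so for each candidate
target vertex the translation is fixed (`v = c − R P_{i,j}`) and only the
rotation is refined (up to five Kabsch fits on nearest-neighbor pairings,
initialized at the global pre-alignment rotation). This reading matters in
practice: if the local transform is instead fit freely (a local ICP), every
candidate near the true match converges to the same registration of the two
neighborhoods and the correlation stops discriminating between candidates,
so recovery of known correspondences degrades sharply. The shipped tests
exercise the pinned form against exhaustive search and known ground truth.

**Search.** A global iterative-closest-point pre-alignment (Kabsch updates on
nearest-neighbor pairings) removes gross motion; candidates are all target
vertices within ρ of the pre-aligned position. Defaults: `r` = 5 × mean
source edge length — the neighborhood must span several vertex rings before
the correlation is informative, and discrimination degrades again when the
neighborhood is so small that measurement noise dominates; `ρ` = 3 × mean
edge length, several times larger than any plausible between-month
displacement after pre-alignment. Both are configurable
(`correspondence_params()`).

**Ties and uniqueness.** The correlation saturates near 1 for all plausible
candidates: on noisy surface data the score difference between the true
vertex and its mesh neighbors is routinely in the 1e-4 to 1e-3 range — the
same order as the score variation the measurement noise itself induces, so
decisions at that resolution are coin flips. Candidates scoring within
`score_tol` (default 2e-3) of the maximum are treated as tied, and the tie
goes to the candidate nearest to a
*predicted* position: the pre-aligned position corrected by the mean
nearest-neighbor displacement of the vertex's mesh neighbors. The prediction
is a smoothness prior on the displacement field — growth between consecutive
months is smooth at the scale of one edge — and is used only for ranking,
never for scoring. Finally, because each source vertex chooses independently,
two vertices can claim the same target; `build_correspondence()` resolves
such claims (best score keeps the target, the displaced vertex re-matches
among unclaimed candidates) so the map is one-to-one and chained tracking
cannot collapse an edge to zero length. Every step is deterministic: ties
end at the smaller vertex index, so repeated runs are bit-identical.

## From correspondences to rates

For each edge (pair of adjacent vertices, from face adjacency) of the first
model, both endpoints are tracked through the composed maps and the length
`L(T_i)` recorded. The normalized monthly change is
\(g_i = 100\,(L(T_{i+1}) - L(T_i))/L(T_i)\) %/month, assigned to the
interval's end instance. Negative changes (resorption) pass through
unchanged.

The rate is the gradient of a least-squares cubic spline. The spline is
fitted to the *cumulative* change \(C(T_1)=0,\; C(T_{i+1}) = C(T_i) + g_i\)
versus time: the units only cohere this way — with a constant monthly change
*c* the cumulative curve is a line and the gradient is exactly *c* %/month at
every instance. "Least squares" is meant literally: for series of eight or
more instances the default fit is a cubic B-spline regression with roughly
one basis function per three instances (`df`), which averages measurement
noise across time; an interpolating spline would pass every noise excursion
straight into the gradient, and its end conditions amplify noise further at
the first and last instances. Interpolation remains available (`df = NA`,
or automatically for short series), uses Forsythe–Malcolm–Moler end
conditions so that cubic polynomial data are reproduced exactly (a natural
spline would flatten the ends), and `smoothing > 0` switches to a penalized
smoothing spline (`lambda` passed through). No extrapolation outside the
fitted range is allowed.

Vertex rates are the unweighted mean of the incident edge rates. Directional
components use squared direction cosines: for an edge with unit direction *u*
and rate *g*, the component along anatomical axis *a* is \(g\,(u \cdot a)^2\).
Because the axes are orthonormal the three components sum to *g* exactly —
the decomposition conserves the total by construction, per edge and per
vertex. The anatomical frame is built from landmarks: ML is the unit vector
between the lateral condylar poles, AP points from the gonion midpoint to the
genial tubercle (orthogonalized against ML), SI completes the right-handed
triad. This construction uses only standard mandibular landmarks; any
orthonormal right-handed frame can be supplied instead.

Reported per-interval tables label the rate at instance *i+1* with the
interval `Ti-Ti+1`; nothing is reported at the first instance, where no
change has been measured yet.

## Validation

Landmarks are snapped to the nearest vertex of the first model (snap distance
logged, warning beyond 3 × mean edge length) and propagated through the
chain; position RMSE against gold-standard positions is computed per landmark
and instance over replicates (the study design this mirrors had eight
animals). Inter-landmark distance change rates are compared by RMSE the same
way. Both reports reshape into the conventional wide tables (rows =
landmarks/pairs, columns = instances/intervals, margin means and SDs).

The vertex-count sensitivity scan decimates the whole series by a fixed
fraction of the starting count per step (quadric edge-collapse, exact target
count) and compares per-region mean percent changes against the
full-resolution reference with a paired two-sided test — a paired t-test by
default, Wilcoxon signed-rank as an option; the default is the
smallest-assumption conventional choice, explicitly a package decision since
nothing stronger is implied by the design. The scan returns the second-last
count before the first significant difference (α = 0.05).

## The synthetic generator

Real CBCT series cannot be shipped, so the generator builds a mandible-like
closed surface: a tube swept along a horseshoe centerline with two posterior
rami rising to condylar knobs, capped at the condyle tops. The centerline is
assembled from straight and circular-arc segments with explicit bend radii
(40 mm anterior arch, 20 mm gonion corner), several times the tube radius:
on the inside of a bend, ring spacing contracts by the ratio of tube to bend
radius, and a too-tight bend produces near-degenerate edges whose normalized
changes amplify measurement noise without bound. Rings are placed uniformly
in arc length for the same reason. Cross-sections are oval with a slow twist
and carry a fine helical relief — bone surfaces are not featureless tubes,
and without local shape detail *no* correlation-based matcher could
distinguish neighboring candidates at realistic noise levels. Six regions
partition the arc-length fraction into bands proportioned like the
anatomical regions (condyle through anterior corpus), with thresholds
snapped to midpoints between rings so no ring straddles a boundary;
17 landmark analogs sit at deterministic template vertices.

Growth is *intrinsic*: each instance is rebuilt in closed form with the
centerline arc length and the ring radii stretched by the cumulative local
factor \(m_{k+1}(t) = m_k(t)\,(1 + \text{profile}_k\, \text{rate}(t)/100)\).
This construction makes local edge growth track the local rate field; the
obvious alternative — scaling positions about a global center by a spatially
varying factor — injects spurious edge growth proportional to the distance
from the center and was rejected (the shipped test that ground-truth
regional means sit at the scenario rates is exactly the property that
construction violates). Per-region rates blend across narrow
transition bands (smoothstep, half-width 0.02 in the sweep parameter), so
ground-truth regional means stay within 0.05 %/month of the scenario rates.

Default scenario conditions mirror the magnitudes reported for growing
minipig mandibles: condyle 1.9, posterior ramus 1.5, anterior ramus 1.0,
corpora 0.4 %/month; 12 monthly instances; measurement noise σ = 0.2 mm
applied along vertex normals (surface-reconstruction-like error that cannot
drift tangentially and corrupt the ground-truth correspondence, which is the
identity map by construction). Ground-truth rates are computed from the exact
noiseless edge lengths by the same accumulation the pipeline uses, so
recovery errors measure the pipeline, not the bookkeeping.

What passing synthetic tests does **not** show: performance on real CBCT
segmentations with topology changes, missing data, erupting dentition, or
landmarking error; the generator's relief is also more regular than real
anatomy. The synthetic series exercises the estimator under known truth, not
the imaging chain.

## Numerical choices and degenerate inputs

* Vertex welding tolerance 1e-6 mm (five orders below CBCT voxel size);
  meshes are cleaned on read, unreferenced vertices dropped.
* Rotations are validated to `R'R = I` and `det R = +1` within 1e-9;
  reflections are rejected. Kabsch uses the SVD determinant correction and
  reports degeneracy (collinear point sets) instead of returning a reflection.
* Euclidean (not geodesic) neighborhoods by default: cheaper, well-defined
  across disconnected parts; a Dijkstra-based geodesic ball is available.
* Zero-variance neighborhoods (coincident points), zero-length edges and
  zero gold-standard distances are hard errors naming the offending item.
* Decimation skips edge collapses that violate the link condition, which
  preserves watertightness; the target count is met exactly.
* Thickness rays start 1e-6 mm above the surface, stop at a 30 mm cutoff,
  and the hit fraction is reported (warning below 50%).
* All tie-breaks end at the smallest index, so every pipeline output is
  bit-reproducible for identical inputs.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
study scale — 653 vertices × 12 monthly instances for regional-rate
recovery, 5 instances for the uniform-scaling check, and twenty ~30-vertex
meshes for exhaustive-search agreement — sizes chosen to match the reported
study design while keeping a complete run in the minutes range on one core.

## Known limitations

* Correspondence is vertex-to-vertex; sliding below the sampling density is
  invisible, and matching accuracy degrades on featureless surfaces (see the
  tie-handling discussion above).
* The method measures surface morphological change; it cannot attribute
  change to apposition versus resorption, nor detect internal remodeling.
* The uniqueness pass is greedy, not a global assignment; on pathological
  inputs a non-injective map can survive (it is kept rather than failing).
* Rate tables at the first instance are undefined by construction; the
  ground-truth generator copies the first interval there for shape
  compatibility.
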