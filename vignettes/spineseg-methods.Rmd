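---
title: "Curvature-based dendritic spine segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based dendritic spine segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dendritic spines are micrometre-scale protrusions on neuronal dendrites
that carry most excitatory synapses; their shape (thin neck, bulbous
head) changes with learning and disease. Electron-microscopy
reconstructions deliver dendrite segments as triangulated surface meshes
with 10^4 to 10^6 vertices, and the analysis bottleneck is separating
each spine from the roughly cylindrical shaft so that per-spine
morphology (neck diameter, head diameter, length, area, volume) can be
quantified at scale.

`spineseg` frames this as per-vertex binary classification with
geometric features, followed by connected-component reasoning on the
mesh graph:

1. **Differential geometry.** Per-vertex mean curvature H (cotangent
   mean-curvature normal, barycentric vertex areas) and Gaussian
   curvature K (angle deficit). The sign conventions are chosen for
   dendritic anatomy: convex regions (spine heads) have negative H and
   positive K; saddle regions (neck-shaft junctions) have negative K;
   the cylindrical shaft has K near 0. An optional bending-energy
   (Willmore) gradient flow smooths measurement noise before curvature
   is read off.
2. **Classification.** Three small multilayer perceptrons (four hidden
   layers of fifty ReLU units, two independent sigmoid outputs) trained
   with a weighted binary cross-entropy: `dnn1` sees clipped curvatures
   `(H, H^2, K, K^2)`; `dnn2` adds the Euclidean distance D from each
   vertex to the skeleton of the `dnn1`-predicted shaft (a two-stage
   pipeline); `dnn3` sees `(K, K^2)` plus nine K-means region labels
   `S_2..S_10` obtained by clustering D on the whole-dendrite skeleton -
   mean curvature is deliberately excluded there because it promotes
   dome-like false positives.
3. **Detection.** Probabilities are thresholded (spine iff
   `a * p_spine > b * p_shaft`, ties to shaft), the largest connected
   shaft component becomes *the* shaft, everything else is regrouped
   into spine components, and dust components are reabsorbed.
4. **Morphometry.** Each spine's skeleton path (base at the shaft, tip
   in the head) carries a thickness profile - the mean distance of the
   spine vertices assigned to each path point - from which neck diameter
   (2x the basal minimum), head diameter (2x the distal maximum) and
   spine length (spline arc length) are read. Area sums the spine's
   triangles; volume integrates the patch after capping its boundary
   loops.

## The synthetic testbed

No EM data ships with the package. Instead, `dendrite_spec()` /
`generate_dendrite()` build labeled dendrites from an implicit signed
distance field: a flat-capped cylindrical shaft (radius 0.4 um, length
8 um by default) with mushroom spines - a neck capsule joined to a head
sphere - placed at random axial positions and azimuths with a minimum
separation. The surface is extracted by marching tetrahedra, which is
watertight by construction, and every vertex is labeled by its nearest
primitive, with the ambiguous junction ring (within one voxel of the
decision boundary) assigned to the shaft the way human annotators place
boundaries on the shaft side.

Default spine dimensions are biologically scaled to hippocampal spine
statistics: neck diameter ~0.17 um, head diameter ~0.51 um, base-to-tip
length ~1.35 um, at a marching resolution of 0.06 um (necks are ~3
voxels across). The shaft ends are cut planes rather than hemispherical
caps: EM segments are clipped out of larger volumes, and a dome cap
would be geometrically indistinguishable from a spine head, which no
classifier operating on curvature could ever separate.

Ground truth records, per spine, the exact neck radius, neck length and
head radius, the base-to-tip length (neck length + head radius), and
Monte-Carlo estimates of exposed surface area and volume with standard
errors (sampling the primitive surfaces/bounding boxes and discarding
covered portions).

What the generator does *not* emulate: reconstruction noise is reduced
to an optional smooth radial displacement field (default off), there are
no multi-branch arbors, no merged spine clusters, no partial-volume or
sectioning artifacts, and spine identity never depends on synapse
presence. Passing tests on this testbed therefore demonstrate that the
pipeline recovers geometry it was designed for; they do not certify
performance on real EM reconstructions, where annotation conventions and
surface quality dominate.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k_bend` | 1 | energy | bending modulus of the smoothing flow |
| `dt` | `1e-4 * h^2` (h = median edge) | - | initial flow step, adapted by backtracking |
| `n_iters` | 150 | steps | smoothing iterations |
| `voxel_size` | 0.03 | um | skeletonization grid (~1/3 of the smallest neck radius) |
| clipping | K to [-45, 45], K^2 to [0, 45], H to [-15, 15], H^2 to [0, 15] | 1/um^2, 1/um | feature ranges; extremes carry no signal and destabilize training |
| `a`, `b` | 1, 1 | - | class weights of the spine/shaft decision |
| `epochs`, `lr` | 400, 1e-3 | - | Adam full-batch training |
| `l1`, `l2` | 1e-5 | - | penalties on hidden-layer weights |
| `min_spine_vertices` | 10 | vertices | dust floor |
| `min_spine_area` | 0.1 | um^2 | physical dust floor (no real spine is close) |
| `iou_threshold` | 0.5 | - | per-spine match criterion in evaluation |

The K^2 clip to [0, 45] is applied exactly as stated even though a
clipped K alone could reach K^2 = 2025; the rule is deliberate (squares
act as bounded interaction features, not as faithful squares).

## Numerical choices

**Curvature.** The mean-curvature normal is assembled per face from
cotangents (`M_i = 1/2 sum_j (cot a_ij + cot b_ij)(X_i - X_j)`), with
`|H_i| = |M_i| / (2 A_i)` over the barycentric area and the sign taken
from the projection onto the outward vertex normal; Gaussian curvature
is the angle deficit over the same area (boundary vertices use the `pi`
deficit). Gauss-Bonnet (`sum K_i A_i = 2 pi chi`) holds to well under 1%
on closed test meshes and is asserted in the tests.

**Smoothing flow.** The discrete bending energy
`W = (k_bend/2) sum H_i^2 A_i` is differentiated analytically
(hand-written reverse mode through the cotangent and area terms; the
gradient is verified against central differences to better than 1e-4
relative). The descent direction divides the gradient by the barycentric
vertex area - the pointwise bending-force density, which is the
consistent discretization of the continuum flow - and caps the per-vertex
force so that near-degenerate corners cannot pin the global step.
Bending flow is fourth-order stiff, so the step size is controlled by a
backtracking line search (halve on increase, double after three clean
accepts): the recorded energy history is non-increasing by construction.
After every accepted step the mesh is rescaled to its initial enclosed
volume; without this, curvature flows shrink spheres. Boundary vertices
of open meshes are held fixed.

**Isosurfaces and wrapping.** Marching tetrahedra (six tetrahedra per
grid cube sharing the main diagonal) produce watertight surfaces by
construction because surface vertices are keyed to grid edges. The
watertight wrap rasterizes the triangle shell into a voxel grid,
morphologically closes it (dilate, flood the exterior, erode back) so
that holes up to several voxels cannot leak the flood fill, and extracts
the isosurface of the box-smoothed occupancy. The isolevel is 2/3 on the
solid side: the rasterized shell spans the surface by half a voxel, and
for a flat interface the smoothed occupancy crosses 2/3 at the true
surface - this removes the half-voxel volume bias a 1/2 level would
carry.

**Skeletonization.** Topology-preserving sequential thinning: a voxel
may be deleted only while it is simple (exactly one 26-connected object
component in its 26-neighbourhood and one 6-connected background
component in its 18-neighbourhood touching a face neighbour) and not a
curve endpoint. Deletion proceeds in six directional subiterations
ordered by a 3-4-5 chamfer distance transform, which keeps the erosion
symmetric and the centerline medial (a cylinder's skeleton stays within
1.5 voxels of its axis in the tests). No branch pruning is applied by
default.

**1-D K-means.** The region features cluster a one-dimensional quantity
(distance to skeleton), whose k-means optimum is always a contiguous
partition of the sorted values. The package therefore solves it exactly
by dynamic programming over (weighted) distinct values rather than by
Lloyd iterations with restarts, which were observed to miss the optimum
on a noticeable fraction of unstructured inputs. Labels are ordered by
ascending cluster center, so `S_k` is an ordinal quantization of D and
stable across runs; the seed argument is retained for interface
stability but has no effect.

**Training.** Full-batch Adam on standardized features (the scaler is
estimated on the training set and stored with the model). The loss is
`(1/m) sum_j w_j^2 (1/n_j) sum_i BCE(Y_ij, Yhat_ij)` with both one-hot
output units in the BCE and predictions clamped to `[1e-7, 1 - 1e-7]`;
per-mesh weights default to 1 with an optional inverse-class-frequency
mode. Initialization is Glorot-uniform under a local, restored RNG
state, so fits are bit-reproducible given the seed. Dense meshes carry
far more vertices than the classifier needs, so training may subsample a
seeded fixed set of rows per mesh (the default pipeline uses 4000);
prediction always covers every vertex.

**Spine extraction.** The classifier's dust - tiny components along
classification boundaries - is absorbed into the shaft by two floors: the
10-vertex floor, and a physical floor of 0.1 um^2 surface area. The
vertex floor alone is resolution-dependent and meaningless on dense
meshes; the area floor sits an order of magnitude below any plausible
spine (the synthetic spines measure ~1 um^2, reported hippocampal means
are >2 um^2).

**Morphometry.** Thinned skeletons terminate near the head centroid (a
ball erodes to its center), so the raw path arc length systematically
misses the distal head radius. The reported spine length therefore adds
the thickness-profile value at the distal path endpoint
(`tip_correction = TRUE`); the raw spline arc length is available and is
what the analytic-curve tests exercise. Path points sit on voxel
centers, so the path is presmoothed with a short running mean before the
interpolating cubic spline is measured, suppressing stair-step
inflation. The pointwise thickness profile is likewise smoothed (window
5) before the neck minimum and head maximum are read: each raw value
averages only a handful of vertices and a plain minimum of noisy
estimates is biased low. Spine volume caps each boundary loop of the
spine patch with a triangle fan at the loop centroid and integrates the
signed tetrahedron sum; if the capped patch fails the edge-manifold
audit, the voxel wrap is used instead.

## Design decisions on open ground

* **Smoothing default.** The pipeline configuration ships with the flow
  disabled for all variants: the synthetic meshes are noise-free, where
  curvature is already clean and smoothing only rounds genuinely sharp
  features (the cut ends). On noisy reconstructions the flow does what
  it is for - the jittered-sphere tests show a >2x reduction of
  curvature noise - and can be enabled per variant. Operating the
  region-feature variant without smoothing is also independently
  validated usage.
* **Classification rule.** Spine iff `a * p_spine > b * p_shaft` with
  ties to shaft, both weights exposed; the decision is scale-invariant
  in `(a, b)`.
* **Object-level accuracy** in the evaluation report is
  `TP / (TP + FP + FN)` (the Jaccard form), the only definition
  consistent with accuracy below both precision and recall; it is
  printed alongside the per-spine IoU threshold it depends on.
* **Matching.** Predicted and annotated spines are paired greedily by
  descending IoU (one-to-one); an exhaustive optimal assignment is
  available for small instances and agrees with the greedy matching on
  non-pathological fixtures.
* **Two-stage dnn2.** The distance feature of `dnn2` is computed from
  the shaft predicted by a `dnn1` model; fitted `dnn2` objects carry
  their stage-1 model so that prediction on new meshes reruns the full
  two-stage path.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
6 training and 6 test dendrites at the default spec (~30,000-35,000
vertices each, 36 test spines), 400 training epochs per variant, 4000
training vertices per mesh, skeletonization at 0.03 um voxels. These
sizes were chosen so a complete train-and-evaluate cycle of all three
variants finishes in minutes on a single core while keeping necks
several voxels wide and at least 30 spines in every morphometric
summary.

## Known limitations

* Touching spines are segmented as one component; splitting merged
  clusters is out of scope, and the union-of-spines evaluation criterion
  exists precisely to score such cases fairly.
* The curvature-only variant (`dnn1`) misreads strongly convex
  non-spine geometry - most visibly the rims of cut segment ends, which
  after any rounding are locally dome-like. The distance and region
  features of `dnn2`/`dnn3` resolve this; on some seeds `dnn1` reports
  one or two such false spines per mesh (they are the documented
  weakness of curvature-only features, not noise).
* Willmore smoothing of meshes with near-degenerate triangles advances
  slowly: the force cap that protects the step size also throttles the
  energy descent where slivers dominate. Decimating first helps.
* The voxel skeleton is only as good as its resolution: spines mapping
  to zero skeleton points at coarse voxels are reported with a warning
  prompting a finer `voxel_size`.
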