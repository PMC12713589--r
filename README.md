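# spineseg

Automated segmentation and morphometry of dendritic spines on
triangulated surface meshes.

Dendritic spines - the micrometre-scale neck-and-head protrusions that
carry most excitatory synapses - are reconstructed by volume electron
microscopy as dense triangle meshes with 10^4-10^6 vertices. Separating
every spine from the roughly cylindrical dendritic shaft, and measuring
each spine's neck diameter, head diameter, length, surface area and
volume, is the bottleneck between a reconstruction and quantitative
statements about synaptic structure. `spineseg` is for neuroanatomists
and image-analysis developers who need that step automated, testable and
reproducible.

## The method

Per-vertex discrete differential geometry feeds small neural
classifiers, and mesh topology turns their output into spines:

* **Curvature.** Mean curvature H from the cotangent
  mean-curvature-normal with barycentric vertex areas,
  `|H_i| = ||1/2 Σ_j (cot α_ij + cot β_ij)(X_i − X_j)|| / (2 A_i)`,
  signed so convex regions (spine heads) are negative; Gaussian
  curvature K as the angle deficit `(2π − Σ θ) / A_i`, positive on
  heads, negative at neck-shaft saddles, ~0 on the shaft. An optional
  smoothing flow performs gradient descent on the bending (Willmore)
  energy `W = (k_bend/2) Σ H_i² A_i` with an exact analytic gradient,
  backtracking step control and volume renormalization.
* **Classifiers.** Three MLPs (4 × 50 ReLU units, two sigmoid outputs)
  trained with the weighted binary cross-entropy
  `L = (1/m) Σ_j w_j² (1/n_j) Σ_i BCE(Y_ij, Ŷ_ij)`:
  `dnn1` uses clipped curvature features `(H, H², K, K²)`; `dnn2` adds
  the distance D of every vertex to the skeleton of the
  `dnn1`-predicted shaft (two-stage); `dnn3` uses `(K, K²)` plus nine
  K-means region labels `S_2..S_10` of the distance to the
  whole-dendrite skeleton. Skeletons come from topology-preserving 3D
  thinning of the voxelized mesh.
* **Detection.** A vertex is a spine vertex iff
  `a·p_spine > b·p_shaft`; the largest connected shaft component is
  *the* shaft, every remaining vertex is regrouped into connected spine
  components, and sub-spine dust is reabsorbed.
* **Morphometry.** Along each spine's skeleton path, the thickness
  profile (mean vertex distance per path point) yields the neck
  diameter (2× basal minimum) and head diameter (2× distal maximum);
  length is the spline arc length `L = Σ ||V_{i+1} − V_i||`; area and
  volume integrate the spine patch after capping its boundary.

A synthetic spiny-dendrite generator (implicit shaft + mushroom-spine
union, marching-tetrahedra extraction, exact per-vertex labels and
per-spine ground truth) makes the whole pipeline testable without any
microscopy data.

## Worked example

```r
library(spineseg)

## a labeled synthetic dendrite: 0.8 um shaft, 4 mushroom spines
spec <- dendrite_spec(n_spines = 4, seed = 7)
d <- generate_dendrite(spec)
d$mesh
#> triangle_mesh: 30581 vertices, 61158 faces
#>   bbox [um]: x -4..4  y -0.953..1.95  z -1.8..1.7
#>   watertight: TRUE

## train the region-feature variant on three independent dendrites
train <- generate_dataset(3, spec, seed = 11)
cfg <- pipeline_config(epochs = 200)
model <- train_spine_model("dnn3", lapply(train, `[[`, "mesh"),
                           lapply(train, function(g) g$truth$labels),
                           cfg)
model
#> spine_mlp vertex classifier (dnn3)
#>   features: K, K2, S2, S3, S4, S5, S6, S7, S8, S9, S10
#>   architecture: 11 -> 50 -> 50 -> 50 -> 50 -> 2 (sigmoid)
#>   trained 200 epochs, loss 1.4301 -> 0.1300

## segment the held-out dendrite and score it
seg <- segment_dendrite(model, d$mesh, cfg)
evaluate_segmentation(seg$spines, d$truth$spine_sets,
                      nrow(d$mesh$vertices))
#> spine segmentation evaluation
#>   spines: 4 predicted / 4 annotated
#>   per-spine IoU criterion (threshold 0.50):
#>     TP 4  FP 0  FN 0
#>     accuracy 1.000  precision 1.000  recall 1.000  F1 1.000
#>     mean per-spine IoU 0.831
#>   union-of-spines criterion:
#>     IoU 0.832  accuracy 0.832  precision 0.832  recall 1.000  F1 0.908
#>   shaft vertex IoU 0.957

## per-spine morphometry (um)
spine_morphometry(d$mesh, seg$spines, attr(seg, "skeleton"), seg$shaft)
#>   spine_id neck_diameter_um head_diameter_um length_um area_um2 volume_um3
#> 1        1            0.126            0.455     1.634    1.362      0.075
#> 2        2            0.157            0.509     1.335    1.314      0.089
#> 3        3            0.142            0.418     1.505    1.250      0.064
#> 4        4            0.130            0.437     1.320    1.141      0.063
```

All four spines are found (TP 4, no false detections); the matched
per-spine overlap averages IoU 0.83, and the recovered diameters sit in
the biological range the generator draws from (neck ~0.13-0.16 um, head
~0.42-0.51 um, length ~1.3-1.6 um).

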