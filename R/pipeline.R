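#' Pipeline configuration
#'
#' Collects every tunable of the segmentation pipeline with its default:
#' the per-variant smoothing toggle (off by default - curvature on clean
#' surface reconstructions is already exact, and running the region-based
#' variant without smoothing costs no accuracy; enable it for noisy EM
#' meshes), the skeletonization voxel size, the classification weights a
#' and b, and the dust floors for spine extraction.
#'
#' @param voxel_size skeletonization voxel size (um); about 1/3 of the
#'   smallest expected neck radius.
#' @param smooth named logical: run Willmore smoothing before curvature,
#'   per variant.
#' @param k_bend,dt,n_iters smoothing-flow parameters ([smooth_mesh()]).
#' @param a,b classification weights ([classify_vertices()]).
#' @param min_spine_vertices,min_spine_area dust floors for
#'   [extract_spines()] (vertices, and um^2 of surface).
#' @param iou_threshold per-spine TP threshold for evaluation.
#' @param kmeans_seed seed for the K-means region features.
#' @param epochs,lr,l1,l2 training hyperparameters.
#' @param seed master training seed.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size = 0.03,
                            smooth = c(dnn1 = FALSE, dnn2 = FALSE,
                                       dnn3 = FALSE),
                            k_bend = 1, dt = NULL, n_iters = 150,
                            a = 1, b = 1, min_spine_vertices = 10L,
                            min_spine_area = 0.1,
                            iou_threshold = 0.5, kmeans_seed = 1L,
                            epochs = 400, lr = 1e-3, l1 = 1e-5, l2 = 1e-5,
                            seed = 1L) {
  structure(list(voxel_size = voxel_size, smooth = smooth, k_bend = k_bend,
                 dt = dt, n_iters = n_iters, a = a, b = b,
                 min_spine_vertices = as.integer(min_spine_vertices),
                 min_spine_area = min_spine_area,
                 iou_threshold = iou_threshold,
                 kmeans_seed = as.integer(kmeans_seed),
                 epochs = epochs, lr = lr, l1 = l1, l2 = l2,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Per-mesh cache of expensive intermediates (smoothed mesh, curvature,
# whole-dendrite skeleton) shared across variants and training stages.
mesh_cache <- function() new.env(parent = emptyenv())

cached <- function(cache, key, expr) {
  if (is.null(cache)) return(expr)
  if (is.null(cache[[key]])) cache[[key]] <- expr
  cache[[key]]
}

# curvature field on the smoothed or raw mesh, memoized
variant_curvature <- function(mesh, variant, config, cache = NULL) {
  if (isTRUE(config$smooth[[variant]])) {
    sm <- cached(cache, "smoothed",
                 smooth_mesh(mesh, k_bend = config$k_bend, dt = config$dt,
                             n_iters = config$n_iters)$mesh)
    cached(cache, "curv_smooth", curvature_field(sm))
  } else {
    cached(cache, "curv_raw", curvature_field(mesh))
  }
}

# submesh of the vertices in `set` (faces fully inside the set)
submesh <- function(mesh, set) {
  inset <- logical(nrow(mesh$vertices))
  inset[set] <- TRUE
  fmask <- inset[mesh$faces[, 1]] & inset[mesh$faces[, 2]] &
    inset[mesh$faces[, 3]]
  used <- sort(unique(as.integer(mesh$faces[fmask, ])))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$faces[fmask, ]], ncol = 3),
                validate = FALSE)
}

# stage-1 shaft prediction -> shaft submesh -> skeleton -> D
stage1_distance <- function(mesh, stage1, config, cache = NULL) {
  curv <- variant_curvature(mesh, "dnn1", config, cache)
  Z1 <- assemble_features("dnn1", curv)
  prob <- predict(stage1, Z1)
  lab <- classify_vertices(prob, a = config$a, b = config$b)
  adj <- cached(cache, "adj", vertex_adjacency(mesh))
  comps <- group_components(adj, which(lab == "shaft"))
  shaft <- select_shaft(comps)
  shaft_mesh <- submesh(mesh, shaft)
  skel <- skeletonize_mesh(shaft_mesh, config$voxel_size)
  list(D = distance_to_skeleton(mesh, skel), skeleton = skel,
       shaft = shaft)
}

#' Compute the feature matrix of a mesh for one model variant
#'
#' Runs the variant's preprocessing chain: optional Willmore smoothing,
#' curvature, and the variant-specific extras - the DNN1-predicted shaft
#' skeleton distance for dnn2 (two-stage path), or the whole-dendrite
#' skeleton distance plus K-means region labels for dnn3.
#'
#' @param mesh a `triangle_mesh`.
#' @param variant `"dnn1"`, `"dnn2"` or `"dnn3"`.
#' @param config a [pipeline_config()].
#' @param stage1 fitted dnn1 `spine_mlp` (required for dnn2).
#' @param cache optional per-mesh cache environment reusing smoothed
#'   meshes, curvature fields and skeletons across variants.
#' @return feature matrix; the skeleton used (if any) is attached as
#'   attribute `"skeleton"`.
#' @export
compute_variant_features <- function(mesh, variant, config = pipeline_config(),
                                     stage1 = NULL, cache = NULL) {
  variant <- match.arg(variant, c("dnn1", "dnn2", "dnn3"))
  curv <- variant_curvature(mesh, variant, config, cache)
  if (variant == "dnn1") {
    return(assemble_features("dnn1", curv))
  }
  if (variant == "dnn2") {
    if (is.null(stage1))
      stop("dnn2 is two-stage: a fitted dnn1 model is required to ",
           "segment the shaft whose skeleton provides D")
    s1 <- stage1_distance(mesh, stage1, config, cache)
    Z <- assemble_features("dnn2", curv, D = s1$D)
    attr(Z, "skeleton") <- s1$skeleton
    return(Z)
  }
  skel <- cached(cache, "skeleton",
                 skeletonize_mesh(mesh, config$voxel_size))
  D <- cached(cache, "D", distance_to_skeleton(mesh, skel))
  regions <- region_label_set(D, ks = 2:10, seed = config$kmeans_seed)
  Z <- assemble_features("dnn3", curv, D = D, regions = regions)
  attr(Z, "skeleton") <- skel
  Z
}

#' Train a segmentation model on labeled meshes
#'
#' Orchestrates per-variant feature assembly over a training set and fits
#' the MLP classifier. For dnn2 the two-stage dependency is honored: a
#' dnn1 model is trained first (or taken from `stage1`) and used to
#' segment each training mesh's shaft, whose skeleton provides the
#' distance feature.
#'
#' @param variant `"dnn1"`, `"dnn2"` or `"dnn3"`.
#' @param meshes list of `triangle_mesh`.
#' @param labels list of per-vertex label vectors (`spine`/`shaft`).
#' @param config a [pipeline_config()].
#' @param stage1 optional pre-trained dnn1 model for the dnn2 path.
#' @param weights per-mesh training weights (see [spine_mlp()]).
#' @param caches optional list of per-mesh cache environments (one per
#'   mesh), reused across variants trained on the same set.
#' @param max_rows_per_mesh training-vertex cap per mesh (see
#'   [spine_mlp()]).
#' @return a fitted `spine_mlp`; for dnn2 the stage-1 model rides along in
#'   `$stage1`.
#' @export
train_spine_model <- function(variant, meshes, labels,
                              config = pipeline_config(), stage1 = NULL,
                              weights = NULL, caches = NULL,
                              max_rows_per_mesh = 8000L) {
  variant <- match.arg(variant, c("dnn1", "dnn2", "dnn3"))
  stopifnot(length(meshes) == length(labels), length(meshes) >= 1)
  if (is.null(caches))
    caches <- replicate(length(meshes), mesh_cache(), simplify = FALSE)
  if (variant == "dnn2" && is.null(stage1)) {
    stage1 <- train_spine_model("dnn1", meshes, labels, config,
                                weights = weights, caches = caches,
                                max_rows_per_mesh = max_rows_per_mesh)
  }
  feats <- Map(function(m, ch) {
    compute_variant_features(m, variant, config, stage1 = stage1,
                             cache = ch)
  }, meshes, caches)
  model <- spine_mlp(unname(feats), labels, variant = variant,
                     epochs = config$epochs, lr = config$lr,
                     l1 = config$l1, l2 = config$l2, weights = weights,
                     max_rows_per_mesh = max_rows_per_mesh,
                     seed = config$seed)
  if (variant == "dnn2") model$stage1 <- stage1
  model
}

#' Segment a dendrite mesh with a trained model
#'
#' Full inference chain: variant features, class probabilities, Eq.-style
#' thresholding (spine iff `a * p_spine > b * p_shaft`), connected
#' components, largest-component shaft selection, and spine extraction
#' with dust suppression. When the predicted shaft is a minority of the
#' mesh a warning reports the shaft ratio (the largest-component heuristic
#' can then pick a spine on pathological inputs).
#'
#' @param model a fitted `spine_mlp` (dnn2 models carry their stage-1
#'   model).
#' @param mesh a `triangle_mesh`.
#' @param config a [pipeline_config()].
#' @param cache optional per-mesh cache environment (see
#'   [compute_variant_features()]).
#' @return a `spine_segmentation`; the skeleton used by the features (if
#'   any) is attached as attribute `"skeleton"`.
#' @export
segment_dendrite <- function(model, mesh, config = pipeline_config(),
                             cache = NULL) {
  if (is.null(cache)) cache <- mesh_cache()
  Z <- compute_variant_features(mesh, model$variant, config,
                                stage1 = model$stage1, cache = cache)
  prob <- predict(model, Z)
  lab <- classify_vertices(prob, a = config$a, b = config$b)
  adj <- cached(cache, "adj", vertex_adjacency(mesh))
  shaft_comps <- group_components(adj, which(lab == "shaft"))
  shaft0 <- select_shaft(shaft_comps)
  if (length(shaft0) < 0.2 * adj$n)
    warning(sprintf("predicted shaft covers only %.1f%% of vertices",
                    100 * length(shaft0) / adj$n))
  ex <- extract_spines(adj, shaft0, config$min_spine_vertices,
                       mesh = mesh, min_spine_area = config$min_spine_area)
  seg <- segmentation_result(mesh, adj, ex$shaft, ex$spines, prob = prob,
                             variant = model$variant)
  attr(seg, "skeleton") <- attr(Z, "skeleton")
  seg
}
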