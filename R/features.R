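#' Clip curvature features to the training ranges
#'
#' Gaussian curvature is clipped to `[-45, 45]` and its square to
#' `[0, 45]`; mean curvature to `[-15, 15]` and its square to `[0, 15]`.
#' The squared-term clip is applied exactly as stated even though a clipped
#' K alone could reach K^2 = 2025 - extreme curvatures carry no extra
#' information for classification and destabilize training. `NaN` entries
#' are first replaced by the mean of the finite entries of that vector.
#'
#' @param H per-vertex mean curvature (1/um).
#' @param K per-vertex Gaussian curvature (1/um^2).
#' @return list with `H`, `H2`, `K`, `K2`, all finite and clipped.
#' @export
clip_curvature_features <- function(H, K) {
  stopifnot(length(H) == length(K))
  fill_nan <- function(x, what) {
    bad <- !is.finite(x)
    if (all(bad)) stop("all-", what, " vector: no finite mean exists")
    if (any(bad)) x[bad] <- mean(x[!bad])
    x
  }
  H <- fill_nan(H, "NaN H")
  K <- fill_nan(K, "NaN K")
  Kc <- pmin(pmax(K, -45), 45)
  K2 <- pmin(pmax(Kc^2, 0), 45)
  Hc <- pmin(pmax(H, -15), 15)
  H2 <- pmin(pmax(Hc^2, 0), 15)
  list(H = Hc, H2 = H2, K = Kc, K2 = K2)
}

#' 1-D K-means region labels from skeleton distances
#'
#' Clusters the per-vertex distance-to-skeleton D into k strata by exact
#' 1-D k-means: the optimum is always a contiguous partition of the sorted
#' values, found by dynamic programming over the (weighted) distinct
#' values. Labels are assigned so cluster centers ascend: label 0 is
#' always the stratum nearest the skeleton, making S_k an ordinal
#' quantization of D. The solver is exact and deterministic, so the seed
#' has no influence on the result; it is accepted for interface stability.
#' Inputs with more than `max_support` distinct values are binned to that
#' many weighted support points first.
#'
#' @param D per-vertex distances (um).
#' @param k number of clusters (>= 2).
#' @param seed accepted for call compatibility; the exact solver ignores
#'   it.
#' @param max_support largest exact support size before binning.
#' @return list with `labels` (integers in `0..k-1`) and `centers`
#'   (ascending, um).
#' @export
kmeans_region_labels <- function(D, k, seed = 1L, max_support = 1024L) {
  if (k < 2) stop("k must be >= 2")
  ux <- sort(unique(D))
  if (length(ux) < k)
    stop("fewer than k = ", k, " distinct distance values")
  if (length(ux) <= max_support) {
    w <- as.numeric(table(factor(D, levels = ux)))
    sup <- ux
  } else {
    br <- seq(min(D), max(D), length.out = max_support + 1L)
    bin <- pmin(findInterval(D, br, rightmost.closed = TRUE),
                max_support)
    sup <- as.numeric(tapply(D, bin, mean))
    w <- as.numeric(table(bin))
  }
  r <- .cpp_kmeans1d_dp(sup, w, as.integer(k))
  # map each value back to its support point's cluster
  if (length(ux) <= max_support) {
    lab <- r$assign[match(D, sup)]
  } else {
    lab <- r$assign[match(bin, sort(unique(bin)))]
  }
  list(labels = as.integer(lab), centers = unname(r$centers))
}

#' Region-label stack S_k for k = 2..10
#'
#' @param D per-vertex distances (um).
#' @param ks cluster counts (default 2:10).
#' @param seed RNG seed.
#' @return object of class `region_labels`: a list with `S` (matrix, one
#'   column per k, values `0..k-1`), `centers` (list), `ks`.
#' @export
region_label_set <- function(D, ks = 2:10, seed = 1L) {
  S <- matrix(0L, length(D), length(ks))
  centers <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    r <- kmeans_region_labels(D, ks[i], seed = seed + i)
    S[, i] <- r$labels
    centers[[i]] <- r$centers
  }
  colnames(S) <- paste0("S", ks)
  structure(list(S = S, centers = centers, ks = ks),
            class = "region_labels")
}

# evaluate an expression with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-variant feature column schemas
variant_schema <- function(variant) {
  switch(variant,
         dnn1 = c("H", "H2", "K", "K2"),
         dnn2 = c("H", "H2", "K", "K2", "D"),
         dnn3 = c("K", "K2", paste0("S", 2:10)),
         stop("unknown variant: ", variant))
}

#' Assemble the per-vertex feature matrix for a model variant
#'
#' Column schemas: `dnn1` uses the clipped curvatures and their squares
#' `(H, H2, K, K2)`; `dnn2` appends the distance-to-skeleton `D`; `dnn3`
#' uses `(K, K2, S2, ..., S10)` - mean curvature is deliberately excluded
#' there because it promotes dome-like false positives, and D enters only
#' through the region labels. Raw (unstandardized) features are returned;
#' the classifier stores the training-set standardization and applies it on
#' both fit and predict.
#'
#' @param variant `"dnn1"`, `"dnn2"` or `"dnn3"`.
#' @param curvatures a `curvature_field` (or list with `H`, `K`).
#' @param D per-vertex distance to the shaft skeleton (dnn2), or to the
#'   dendrite skeleton (ignored by dnn1; required to build `regions` for
#'   dnn3 if `regions` is not supplied).
#' @param regions a `region_labels` object with k = 2..10 (dnn3).
#' @return numeric matrix with the variant's column schema, free of
#'   NaN/Inf; attribute `"variant"` records the variant.
#' @export
assemble_features <- function(variant, curvatures, D = NULL,
                              regions = NULL) {
  variant <- match.arg(variant, c("dnn1", "dnn2", "dnn3"))
  cc <- clip_curvature_features(curvatures$H, curvatures$K)
  n <- length(cc$H)
  Z <- switch(variant,
    dnn1 = cbind(H = cc$H, H2 = cc$H2, K = cc$K, K2 = cc$K2),
    dnn2 = {
      if (is.null(D))
        stop("dnn2 needs D; schema is (H, H2, K, K2, D)")
      stopifnot(length(D) == n)
      cbind(H = cc$H, H2 = cc$H2, K = cc$K, K2 = cc$K2, D = D)
    },
    dnn3 = {
      if (is.null(regions))
        stop("dnn3 needs region labels; schema is (K, K2, S2..S10)")
      if (!identical(as.integer(regions$ks), 2:10))
        stop("dnn3 regions must cover k = 2..10")
      stopifnot(nrow(regions$S) == n)
      cbind(K = cc$K, K2 = cc$K2, regions$S)
    })
  if (any(!is.finite(Z))) stop("non-finite entries after feature assembly")
  attr(Z, "variant") <- variant
  Z
}

#' Export a feature matrix to CSV with its schema header
#' @param Z a feature matrix from [assemble_features()].
#' @param path output path.
#' @export
write_features_csv <- function(Z, path) {
  utils::write.csv(as.data.frame(Z), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
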