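#' Triangle mesh objects
#'
#' A `triangle_mesh` is the universal substrate of the package: an `n x 3`
#' numeric matrix of vertex coordinates (micrometres) and an `m x 3` integer
#' matrix of 1-based vertex indices, one row per triangle. Construction
#' validates the core invariants: all face indices in range, no face with a
#' repeated vertex, and no triangle below the degeneracy area tolerance.
#'
#' @param vertices numeric matrix, one 3D point per row (um).
#' @param faces integer matrix, one triangle per row (1-based vertex indices).
#' @param validate check invariants (default `TRUE`).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate triangle-mesh invariants
#'
#' @param mesh a `triangle_mesh`.
#' @param area_tol triangles with area below this are considered degenerate.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L) stop("empty mesh: no vertices")
  if (nrow(f) == 0L) stop("empty mesh: no faces")
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v))
    stop("face index out of range [1, ", nrow(v), "]")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("face with repeated vertex index")
  a <- face_areas(mesh)
  if (any(a <= area_tol))
    stop(sum(a <= area_tol), " degenerate (zero-area) faces")
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [um]: x %.3g..%.3g  y %.3g..%.3g  z %.3g..%.3g\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat("  watertight:", is_watertight(x), "\n")
  invisible(x)
}

# per-face areas (um^2)
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Total surface area of a mesh (um^2)
#' @param mesh a `triangle_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed mesh (um^3)
#'
#' Signed tetrahedron sum (divergence theorem); the absolute value is
#' returned, so face orientation does not matter for closed surfaces.
#' @param mesh a `triangle_mesh`.
#' @param signed return the signed volume instead of its absolute value.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
             a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
             a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
  if (signed) vol else abs(vol)
}

# undirected edge table with incidence counts; key encodes (lo, hi)
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  key <- (lo - 1) * as.double(nv) + (hi - 1)
  tab <- table(key)
  ukey <- as.double(names(tab))
  list(lo = as.integer(ukey %/% nv) + 1L,
       hi = as.integer(ukey %% nv) + 1L,
       count = as.integer(tab))
}

#' Is every edge shared by exactly two faces?
#' @param mesh a `triangle_mesh`.
#' @export
is_watertight <- function(mesh) {
  et <- mesh_edge_table(mesh)
  all(et$count == 2L)
}

# boundary edges (incident to exactly one face), as a 2-column matrix
boundary_edges <- function(mesh) {
  et <- mesh_edge_table(mesh)
  b <- et$count == 1L
  cbind(et$lo[b], et$hi[b])
}

#' Euler characteristic V - E + F
#' @param mesh a `triangle_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  et <- mesh_edge_table(mesh)
  nrow(mesh$vertices) - length(et$lo) + nrow(mesh$faces)
}

#' 1-ring vertex adjacency
#'
#' For every vertex, the set of vertices sharing an edge with it and the set
#' of incident faces. The neighbour relation is symmetric by construction.
#'
#' @param mesh a `triangle_mesh`.
#' @return an object of class `vertex_adjacency` with elements `neighbors`
#'   (list of integer vectors) and `faces` (list of incident face indices).
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  from <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  to <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  o <- order(from, to)
  from <- from[o]
  to <- to[o]
  dup <- c(FALSE, from[-1] == from[-length(from)] & to[-1] == to[-length(to)])
  from <- from[!dup]
  to <- to[!dup]
  nb <- split(to, factor(from, levels = seq_len(nv)))
  names(nb) <- NULL
  fid <- rep(seq_len(nrow(f)), 3L)
  vid <- c(f[, 1], f[, 2], f[, 3])
  o2 <- order(vid, fid)
  vf <- split(fid[o2], factor(vid[o2], levels = seq_len(nv)))
  names(vf) <- NULL
  structure(list(neighbors = nb, faces = vf, n = nv),
            class = "vertex_adjacency")
}

# CSR form (0-based) of a vertex_adjacency, for the C++ component search
adjacency_csr <- function(adj) {
  lens <- lengths(adj$neighbors)
  ptr <- c(0L, cumsum(lens))
  idx <- unlist(adj$neighbors, use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  list(ptr = as.integer(ptr), idx = as.integer(idx) - 1L)
}

#' Merge duplicate vertices, drop degenerate faces, repair orientation
#'
#' Load-time repair: vertices closer than `tol` (default 1e-8 of the
#' bounding-box diagonal) are fused, faces that become degenerate are
#' dropped, face orientation is made consistent across shared edges by
#' breadth-first propagation, and closed meshes are re-oriented outward
#' (positive signed volume).
#'
#' @param mesh a `triangle_mesh` (not yet validated).
#' @param tol vertex merge tolerance; `NULL` for the default.
#' @return a repaired, validated `triangle_mesh`.
#' @export
repair_mesh <- function(mesh, tol = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  if (is.null(tol)) {
    diag <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
    tol <- 1e-8 * max(diag, .Machine$double.eps)
  }
  # fuse near-duplicate vertices on a tol grid
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  keep_idx <- which(first)
  v2 <- v[keep_idx, , drop = FALSE]
  f2 <- matrix(map[f], ncol = 3)
  # drop faces with repeated vertices or ~zero area
  bad <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  f2 <- f2[!bad, , drop = FALSE]
  if (nrow(f2) == 0L) stop("empty mesh after repair")
  m2 <- triangle_mesh(v2, f2, validate = FALSE)
  a <- face_areas(m2)
  f2 <- f2[a > 1e-12 * stats::median(a), , drop = FALSE]
  # drop exact duplicate faces (same vertex set)
  fs <- t(apply(f2, 1, sort))
  f2 <- f2[!duplicated(fs), , drop = FALSE]
  m2 <- triangle_mesh(v2, f2, validate = FALSE)
  # drop unreferenced vertices
  used <- sort(unique(as.integer(f2)))
  remap <- integer(nrow(v2))
  remap[used] <- seq_along(used)
  m2 <- triangle_mesh(v2[used, , drop = FALSE],
                      matrix(remap[f2], ncol = 3), validate = FALSE)
  # collapse residual slivers whose near-coincident vertices straddled the
  # merge grid: fuse the shortest edge of any ~zero-area face
  for (pass in 1:5) {
    a <- face_areas(m2)
    bad <- which(a <= 1e-12)
    if (length(bad) == 0) break
    v3 <- m2$vertices
    f3 <- m2$faces
    hmed <- median_edge_length(m2)
    vmap <- seq_len(nrow(v3))
    for (bf in bad) {
      tri <- f3[bf, ]
      el <- c(sum((v3[tri[1], ] - v3[tri[2], ])^2),
              sum((v3[tri[2], ] - v3[tri[3], ])^2),
              sum((v3[tri[3], ] - v3[tri[1], ])^2))
      pair <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])[
        which.min(el), ]
      if (min(el) > (1e-3 * hmed)^2) next  # genuinely collinear: leave it
      keep <- min(vmap[pair])
      vmap[vmap == vmap[pair[1]]] <- keep
      vmap[vmap == vmap[pair[2]]] <- keep
    }
    f3 <- matrix(vmap[f3], ncol = 3)
    degen <- f3[, 1] == f3[, 2] | f3[, 2] == f3[, 3] | f3[, 1] == f3[, 3]
    f3 <- f3[!degen, , drop = FALSE]
    used <- sort(unique(as.integer(f3)))
    remap <- integer(nrow(v3))
    remap[used] <- seq_along(used)
    m2 <- triangle_mesh(v3[used, , drop = FALSE],
                        matrix(remap[f3], ncol = 3), validate = FALSE)
  }
  # consistent orientation
  flip <- .cpp_orient_faces(m2$faces, nrow(m2$vertices))
  if (any(flip)) {
    ff <- m2$faces
    ff[flip, c(2, 3)] <- ff[flip, c(3, 2)]
    m2$faces <- ff
  }
  # outward orientation for closed meshes
  if (is_watertight(m2) && mesh_volume(m2, signed = TRUE) < 0) {
    m2$faces <- m2$faces[, c(1, 3, 2)]
  }
  validate_mesh(m2)
  m2
}
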