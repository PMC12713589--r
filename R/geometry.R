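#' @useDynLib spineseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Per-face geometry shared by the curvature operators: corner cotangents,
# face areas and corner angles. Degenerate faces give zero cotangents.
face_corner_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cross_len <- function(a, b) {
    sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
         (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
         (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)
  }
  e12 <- p2 - p1; e13 <- p3 - p1
  e21 <- p1 - p2; e23 <- p3 - p2
  e31 <- p1 - p3; e32 <- p2 - p3
  wl <- cross_len(e12, e13)        # = 2 * face area, same at every corner
  d1 <- rowSums(e12 * e13)
  d2 <- rowSums(e21 * e23)
  d3 <- rowSums(e31 * e32)
  safe <- pmax(wl, 1e-300)
  list(
    area = 0.5 * wl,
    cot = cbind(d1 / safe, d2 / safe, d3 / safe),
    angle = cbind(atan2(wl, d1), atan2(wl, d2), atan2(wl, d3))
  )
}

# scatter-add vals into an n-vector at idx (handles absent vertices)
accum_at <- function(vals, idx, n) {
  out <- numeric(n)
  tmp <- rowsum(vals, group = idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

# barycentric vertex areas: one third of incident face areas
vertex_areas <- function(mesh, fg = face_corner_geometry(mesh)) {
  f <- mesh$faces
  accum_at(rep(fg$area / 3, 3L), c(f[, 1], f[, 2], f[, 3]),
           nrow(mesh$vertices))
}

# area-weighted outward vertex normals (assumes consistently oriented faces)
vertex_normals <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  fn <- face_normals(mesh, normalize = FALSE)  # length = 2 * area
  idx <- c(f[, 1], f[, 2], f[, 3])
  acc <- cbind(accum_at(rep(fn[, 1], 3L), idx, n),
               accum_at(rep(fn[, 2], 3L), idx, n),
               accum_at(rep(fn[, 3], 3L), idx, n))
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

#' Per-vertex mean curvature
#'
#' Discrete mean curvature via the cotangent mean-curvature-normal
#' construction with barycentric vertex areas:
#' `|H_i| = ||M_i|| / (2 A_i)` where
#' `M_i = 1/2 sum_j (cot a_ij + cot b_ij)(X_i - X_j)`.
#' The sign follows the convention used for dendritic surfaces: convex
#' regions (a sphere seen from outside, a spine head) have negative H,
#' concave regions (the shaft-to-neck transition) positive H. The sign is
#' taken from the projection of the mean-curvature normal onto the outward
#' vertex normal.
#'
#' Isolated vertices (no incident face) get `NaN`; downstream feature
#' assembly replaces those by the finite mean.
#'
#' @param mesh a `triangle_mesh` with consistently oriented faces.
#' @return numeric vector of signed mean curvature (1/um).
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  fg <- face_corner_geometry(mesh)
  # corner c of each face is opposite edge (c+1, c+2): the cotangent at c
  # weights the term (X_p - X_q) added to M_p (and subtracted from M_q)
  M <- matrix(0, n, 3)
  for (c in 1:3) {
    p <- f[, (c %% 3) + 1L]
    q <- f[, ((c + 1) %% 3) + 1L]
    w <- 0.5 * fg$cot[, c]
    term <- (v[p, , drop = FALSE] - v[q, , drop = FALSE]) * w
    for (d in 1:3) {
      M[, d] <- M[, d] + accum_at(term[, d], p, n) - accum_at(term[, d], q, n)
    }
  }
  A <- vertex_areas(mesh, fg)
  nrm <- vertex_normals(mesh)
  H <- -rowSums(M * nrm) / (2 * A)
  H[A <= 0] <- NaN
  H
}

#' Per-vertex Gaussian curvature
#'
#' Angle-deficit estimator over the barycentric vertex area:
#' `K_i = (2*pi - sum of incident angles) / A_i`; boundary vertices use the
#' `pi` deficit. Positive on domes (spine heads), negative at saddles
#' (neck-shaft junctions), ~0 on the cylindrical shaft.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of Gaussian curvature (1/um^2).
#' @export
gaussian_curvature <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  fg <- face_corner_geometry(mesh)
  angsum <- numeric(n)
  for (c in 1:3) {
    angsum <- angsum + accum_at(fg$angle[, c], f[, c], n)
  }
  A <- vertex_areas(mesh, fg)
  be <- boundary_edges(mesh)
  on_boundary <- logical(n)
  on_boundary[as.integer(be)] <- TRUE
  deficit <- ifelse(on_boundary, pi, 2 * pi) - angsum
  K <- deficit / A
  K[A <= 0] <- NaN
  K
}

#' Curvature field: H, K and barycentric area per vertex
#'
#' @param mesh a `triangle_mesh`.
#' @return a list of class `curvature_field` with `H` (1/um), `K` (1/um^2)
#'   and `A` (um^2), each of length `nrow(mesh$vertices)`.
#' @export
curvature_field <- function(mesh) {
  fg <- face_corner_geometry(mesh)
  structure(list(H = mean_curvature(mesh),
                 K = gaussian_curvature(mesh),
                 A = vertex_areas(mesh, fg)),
            class = "curvature_field")
}

#' Export a curvature field to CSV (`vertex_index,H,K,area`, 0-based)
#' @param field a `curvature_field`.
#' @param path output path.
#' @export
write_curvature_csv <- function(field, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(field$H) - 1L,
                              H = field$H, K = field$K, area = field$A),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discrete bending (Willmore) energy
#'
#' `W = (k_bend / 2) * sum_i H_i^2 A_i` over the mesh vertices.
#'
#' @param mesh a closed `triangle_mesh`.
#' @param k_bend bending coefficient (energy units).
#' @return scalar energy.
#' @export
willmore_energy <- function(mesh, k_bend = 1) {
  if (k_bend == 0) return(0)
  H <- mean_curvature(mesh)
  if (any(is.nan(H)))
    stop("NaN curvature at vertices: ",
         paste(utils::head(which(is.nan(H)), 10), collapse = ", "))
  res <- .cpp_willmore_energy_grad(mesh$vertices, mesh$faces, k_bend, FALSE)
  res$energy
}

#' Smooth a mesh by gradient descent on the bending energy
#'
#' Evolves vertex positions by explicit steps `X <- X + dt * F_bend(X)`,
#' where `F_bend` is the discrete bending force density: the exact analytic
#' gradient of the discrete energy divided by the barycentric vertex area
#' (`F_i = -grad_i W / A_i`). The area division makes the velocity a
#' pointwise quantity - the consistent discretization of the continuum
#' flow `dX/dt = F_bend(X)` - so one global step size serves fine and
#' coarse vertices alike. Bending flow is fourth-order stiff, so the step
#' is controlled by a backtracking line search: a step that would increase
#' the energy is retried with half the step, and the step grows again
#' after three clean accepts. The recorded energy history is therefore
#' non-increasing by construction. After each accepted step the mesh is
#' rescaled about its centroid to the initial enclosed volume, preventing
#' the shrinkage curvature flows otherwise exhibit. Boundary vertices of
#' open meshes are held fixed.
#'
#' @param mesh a `triangle_mesh` (closed preferred).
#' @param k_bend bending coefficient.
#' @param dt initial time step; `NULL` for the default
#'   `1e-4 * (median edge length)^2`.
#' @param n_iters number of descent steps (0 returns the input unchanged).
#' @param renormalize_volume rescale to the initial volume each step
#'   (closed meshes only).
#' @param grow_every accepted steps between step-size doublings.
#' @return a list of class `flow_state`: `mesh` (smoothed), `energy`
#'   (per-iteration history, first entry = initial energy), `dt` (final
#'   step), `k_bend`, `converged`.
#' @export
smooth_mesh <- function(mesh, k_bend = 1, dt = NULL, n_iters = 500,
                        renormalize_volume = TRUE, grow_every = 3L) {
  h <- median_edge_length(mesh)
  if (is.null(dt)) dt <- 1e-4 * h^2
  stopifnot(dt > 0, n_iters >= 0)
  closed <- is_watertight(mesh)
  fixed <- integer(0)
  if (!closed) {
    fixed <- unique(as.integer(boundary_edges(mesh)))
    renormalize_volume <- FALSE
  }
  V <- mesh$vertices
  F0 <- mesh$faces
  vol0 <- if (closed) mesh_volume(mesh) else NA_real_
  eg <- .cpp_willmore_energy_grad(V, F0, k_bend, TRUE)
  energy <- eg$energy
  hist <- energy
  if (n_iters == 0L) {
    return(structure(list(mesh = mesh, energy = hist, dt = dt,
                          k_bend = k_bend, converged = FALSE),
                     class = "flow_state"))
  }
  dt_cur <- dt
  accepts <- 0L
  converged <- FALSE
  mesh_cur <- mesh
  # cap the force density so near-degenerate corners (huge H over tiny
  # area) cannot pin the global step size: at the initial dt no vertex
  # moves more than 0.3 edge lengths. Row-wise positive scaling keeps the
  # direction a descent direction, and backtracking still shrinks every
  # row with dt.
  force_cap <- 0.3 * h / dt
  for (it in seq_len(n_iters)) {
    A <- vertex_areas(mesh_cur)
    G <- eg$gradient / pmax(A, 1e-12)
    G[!is.finite(G)] <- 0
    gn <- sqrt(rowSums(G^2))
    over <- gn > force_cap
    if (any(over)) G[over, ] <- G[over, , drop = FALSE] *
        (force_cap / gn[over])
    if (length(fixed)) G[fixed, ] <- 0
    accepted <- FALSE
    for (try in 1:30) {
      Vt <- V - dt_cur * G
      if (renormalize_volume) {
        vt <- mesh_volume(triangle_mesh(Vt, F0, validate = FALSE))
        if (vt > 0) {
          ctr <- colMeans(Vt)
          s <- (vol0 / vt)^(1 / 3)
          Vt <- sweep(sweep(Vt, 2, ctr) * s, 2, ctr, FUN = "+")
        }
      }
      egt <- .cpp_willmore_energy_grad(Vt, F0, k_bend, TRUE)
      if (is.finite(egt$energy) && egt$energy <= energy) {
        V <- Vt
        energy <- egt$energy
        eg <- egt
        mesh_cur <- triangle_mesh(V, F0, validate = FALSE)
        accepted <- TRUE
        accepts <- accepts + 1L
        if (accepts %% grow_every == 0L) dt_cur <- dt_cur * 2
        break
      }
      dt_cur <- dt_cur / 2
      accepts <- 0L
    }
    if (!accepted) {  # line search bottomed out: at a discrete minimum
      converged <- TRUE
      break
    }
    hist <- c(hist, energy)
  }
  structure(list(mesh = triangle_mesh(V, F0, validate = FALSE),
                 energy = hist, dt = dt_cur, k_bend = k_bend,
                 converged = converged),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat("flow_state:", length(x$energy) - 1, "accepted steps, energy",
      sprintf("%.6g -> %.6g", x$energy[1], x$energy[length(x$energy)]),
      if (x$converged) "(converged)" else "", "\n")
  invisible(x)
}
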