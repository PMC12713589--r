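#' Voxel volumes
#'
#' A `voxel_volume` wraps a binary 3D occupancy grid with its voxel size and
#' world origin (the coordinate of the center of voxel (1,1,1)).
#'
#' @param grid logical 3D array.
#' @param voxel_size edge length of a voxel (um).
#' @param origin world coordinate of the first voxel center.
#' @export
voxel_volume <- function(grid, voxel_size, origin) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L, voxel_size > 0)
  if (!any(grid)) stop("empty voxel volume: no filled voxel")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$grid), collapse = " x "),
      "voxels of", x$voxel_size, "um,", sum(x$grid), "filled\n")
  invisible(x)
}

# grid frame for a mesh: origin and dims with `pad` voxels of margin
grid_frame <- function(mesh, voxel_size, pad = 3L) {
  lo <- apply(mesh$vertices, 2, min) - pad * voxel_size
  hi <- apply(mesh$vertices, 2, max) + pad * voxel_size
  dims <- pmax(as.integer(ceiling((hi - lo) / voxel_size)) + 1L, 2L)
  list(origin = lo, dims = dims)
}

#' Voxelize a watertight mesh
#'
#' A voxel is filled iff its center lies inside the mesh (ray-crossing
#' parity test); the interior is solid by construction.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param voxel_size voxel edge length (um).
#' @return a `voxel_volume`.
#' @export
voxelize <- function(mesh, voxel_size) {
  stopifnot(voxel_size > 0)
  be <- boundary_edges(mesh)
  if (nrow(be) > 0) {
    stop("mesh is not watertight; ", nrow(be), " boundary edges, e.g. (",
         paste(be[1, ], collapse = ","), ")")
  }
  gf <- grid_frame(mesh, voxel_size)
  occ <- .cpp_voxelize_parity(mesh$vertices, mesh$faces, gf$origin,
                              voxel_size, gf$dims)
  grid <- array(occ, dim = gf$dims)
  if (!any(grid)) {
    # degenerate: mesh thinner than a voxel; fall back to the shell
    shell <- .cpp_rasterize_shell(mesh$vertices, mesh$faces, gf$origin,
                                  voxel_size, gf$dims)
    grid <- array(shell, dim = gf$dims)
  }
  voxel_volume(grid, voxel_size, gf$origin)
}

# Occupancy of the solid region (shell + interior) for any mesh, including
# open ones: rasterize the triangle shell, morphologically close it
# (dilate by `closing` voxels so the exterior flood cannot leak through
# holes, flood, erode back), and complement the exterior.
solid_occupancy <- function(mesh, voxel_size, closing = 2L) {
  gf <- grid_frame(mesh, voxel_size, pad = 3L + closing)
  shell <- .cpp_rasterize_shell(mesh$vertices, mesh$faces, gf$origin,
                                voxel_size, gf$dims)
  if (closing > 0) {
    dshell <- .cpp_chamfer_dt(!shell, gf$dims)   # distance to the shell
    grown <- dshell <= 3L * closing
    ext <- .cpp_flood_exterior(grown, gf$dims)
    din <- .cpp_chamfer_dt(!ext, gf$dims)        # depth inside the solid
    occ <- din > 3L * closing | (shell & !ext)
  } else {
    ext <- .cpp_flood_exterior(shell, gf$dims)
    occ <- !ext
  }
  list(occ = array(occ, dim = gf$dims), origin = gf$origin,
       dims = gf$dims)
}

#' Wrap a mesh into a watertight surface
#'
#' Rasterizes the surface into a voxel shell, flood-fills the exterior,
#' takes the complement as a solid, lightly smooths the occupancy field and
#' extracts the 0.5-isosurface with marching tetrahedra. The output is
#' watertight by construction (every edge borders exactly two faces) and
#' lies within about one voxel of the input surface.
#'
#' @param mesh a `triangle_mesh` (holes and disconnected parts allowed).
#' @param voxel_size wrap resolution (um); `NULL` for 1/100 of the
#'   bounding-box diagonal.
#' @return a watertight `triangle_mesh`.
#' @export
make_watertight <- function(mesh, voxel_size = NULL) {
  if (nrow(mesh$vertices) < 4) stop("need at least 4 vertices to wrap")
  ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
  if (sum(ext > 1e-12) < 3)
    stop("wrap failure: input points are coplanar")
  if (is.null(voxel_size)) voxel_size <- sqrt(sum(ext^2)) / 100
  so <- solid_occupancy(mesh, voxel_size)
  field <- .cpp_box_smooth3(as.numeric(so$occ), so$dims)
  # the rasterized shell spans the surface +- half a voxel, so the solid
  # boundary sits half a voxel outside the true surface; for a flat
  # interface the box-smoothed occupancy crosses 2/3 there, hence the
  # isolevel (field is passed inverted: inside iff 1 - f < 1/3)
  iso <- .cpp_marching_tetrahedra(1 - field, so$dims, so$origin,
                                  voxel_size, 1 / 3)
  if (nrow(iso$vertices) == 0) stop("wrap failure: empty isosurface")
  out <- triangle_mesh(iso$vertices, iso$faces, validate = FALSE)
  out <- repair_mesh(out)
  if (!is_watertight(out)) stop("wrap failure: output not watertight")
  out
}

#' Skeletons
#'
#' A `skeleton` is a 1-voxel-wide centerline: a point set (voxel centers in
#' world/mesh coordinates) plus the 26-connectivity edges between skeleton
#' voxels.
#'
#' @param points numeric matrix of 3D points (um).
#' @param edges 2-column integer matrix of point-index pairs.
#' @param voxel_size source voxel size (um).
#' @export
skeleton <- function(points, edges, voxel_size) {
  structure(list(points = points, edges = edges, voxel_size = voxel_size),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("skeleton:", nrow(x$points), "points,", nrow(x$edges),
      "edges, voxel", x$voxel_size, "um\n")
  invisible(x)
}

#' Skeletonize a voxel volume by 3D thinning
#'
#' Topology-preserving sequential thinning: voxels are deleted in order of
#' increasing chamfer distance to the background, only while they are simple
#' points (one 26-connected object component in the 26-neighbourhood, one
#' 6-connected background component in the 18-neighbourhood) and not curve
#' endpoints. The result is a thin (no 2x2x2 block), medial centerline with
#' the same number of 26-connected components as the input.
#'
#' @param vol a `voxel_volume`.
#' @return a `skeleton` with points in world coordinates.
#' @export
skeletonize_volume <- function(vol) {
  if (!any(vol$grid)) stop("empty volume")
  dims <- dim(vol$grid)
  occ <- as.logical(vol$grid)
  dt <- .cpp_chamfer_dt(occ, dims)
  thin <- .cpp_thin_volume(occ, dims, dt)
  skeleton_from_grid(array(thin, dims), vol$voxel_size, vol$origin)
}

skeleton_from_grid <- function(grid, voxel_size, origin) {
  idx <- which(grid)
  if (length(idx) == 0) stop("thinning produced an empty skeleton")
  dims <- dim(grid)
  ijk <- arrayInd(idx, dims)
  pts <- cbind(origin[1] + (ijk[, 1] - 1) * voxel_size,
               origin[2] + (ijk[, 2] - 1) * voxel_size,
               origin[3] + (ijk[, 3] - 1) * voxel_size)
  # 26-connectivity edges between skeleton voxels
  pos <- array(0L, dims)
  pos[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs %*% c(1, 3, 9)) > 0, ,
               drop = FALSE]  # half the offsets: each pair once
  ei <- integer(0); ej <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[r, 1]
    nj <- ijk[, 2] + offs[r, 2]
    nk <- ijk[, 3] + offs[r, 3]
    ok <- ni >= 1 & nj >= 1 & nk >= 1 &
      ni <= dims[1] & nj <= dims[2] & nk <= dims[3]
    if (!any(ok)) next
    lin <- (ni[ok] - 1L) + dims[1] * ((nj[ok] - 1L) +
                                      dims[2] * (nk[ok] - 1L)) + 1L
    nb <- pos[lin]
    hit <- nb > 0L
    ei <- c(ei, which(ok)[hit])
    ej <- c(ej, nb[hit])
  }
  skeleton(pts, cbind(ei, ej), voxel_size)
}

#' Skeletonize a mesh directly
#'
#' Convenience path used by the segmentation pipeline: rasterizes the mesh
#' shell, flood-fills the exterior to obtain the solid, and thins. Works for
#' open meshes (e.g. a predicted shaft submesh) without an intermediate
#' wrap-to-mesh round trip.
#'
#' @param mesh a `triangle_mesh`.
#' @param voxel_size thinning resolution (um).
#' @return a `skeleton`.
#' @export
skeletonize_mesh <- function(mesh, voxel_size) {
  so <- solid_occupancy(mesh, voxel_size)
  dims <- so$dims
  occ <- as.logical(so$occ)
  dt <- .cpp_chamfer_dt(occ, dims)
  thin <- .cpp_thin_volume(occ, dims, dt)
  skeleton_from_grid(array(thin, dims), voxel_size, so$origin)
}

#' Distance from every mesh vertex to the skeleton
#'
#' `D_l = min_j || V_j - X_l ||` over skeleton points `V_j`.
#'
#' @param mesh a `triangle_mesh`.
#' @param skel a `skeleton`.
#' @param return_index also return the index of the nearest skeleton point
#'   as attribute `"nearest"`.
#' @return numeric vector `D` (um), one entry per vertex.
#' @export
distance_to_skeleton <- function(mesh, skel, return_index = FALSE) {
  if (nrow(skel$points) == 0) stop("empty skeleton")
  nn <- .cpp_min_dist_idx(mesh$vertices, skel$points)
  d <- nn$dist
  if (return_index) attr(d, "nearest") <- nn$index
  d
}

#' Export a skeleton to CSV (`x,y,z` points plus `i,j` edge list)
#' @param skel a `skeleton`.
#' @param points_path CSV path for the points.
#' @param edges_path CSV path for the edge list (optional).
#' @export
write_skeleton_csv <- function(skel, points_path, edges_path = NULL) {
  utils::write.csv(data.frame(x = skel$points[, 1], y = skel$points[, 2],
                              z = skel$points[, 3]),
                   points_path, row.names = FALSE, quote = FALSE)
  if (!is.null(edges_path))
    utils::write.csv(data.frame(i = skel$edges[, 1], j = skel$edges[, 2]),
                     edges_path, row.names = FALSE, quote = FALSE)
  invisible(points_path)
}
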