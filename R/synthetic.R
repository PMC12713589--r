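#' Specification of a synthetic spiny dendrite
#'
#' The generator emulates the geometry the segmentation pipeline is built
#' for: an approximately cylindrical dendritic shaft (flat-cut at both
#' ends, like a clipped EM segment; optionally bent) from which
#' mushroom-shaped spines protrude - a thin
#' neck capsule joined to a spherical head. Default spine dimensions are
#' biologically scaled to hippocampal spine statistics (neck diameter
#' ~0.17 um, head diameter ~0.51 um, base-to-tip length ~1.35 um).
#'
#' @param shaft_radius shaft radius R_s (um).
#' @param shaft_length shaft axis length (um).
#' @param shaft_curvature axis curvature (1/um, 0 = straight).
#' @param n_spines spine count (scalar, or length-2 range to sample).
#' @param neck_radius,neck_length,head_radius length-2 sampling ranges
#'   (um); scalars are fixed values.
#' @param min_separation minimum axial distance between spine bases (um).
#' @param noise surface noise amplitude as a fraction of `shaft_radius`.
#' @param resolution marching-tetrahedra voxel size / target edge length
#'   (um).
#' @param junction_shaft label the ambiguous junction ring (within one
#'   `resolution` of the spine/shaft decision boundary) as shaft,
#'   emulating annotators' shaft-side boundary placement.
#' @param seed RNG seed; the generated mesh is bit-reproducible given the
#'   spec.
#' @return an object of class `dendrite_spec`.
#' @export
dendrite_spec <- function(shaft_radius = 0.4, shaft_length = 8,
                          shaft_curvature = 0, n_spines = 6,
                          neck_radius = c(0.07, 0.10),
                          neck_length = c(0.85, 1.35),
                          head_radius = c(0.21, 0.30),
                          min_separation = 1.1, noise = 0,
                          resolution = 0.06, junction_shaft = TRUE,
                          seed = 1L) {
  rng2 <- function(x) if (length(x) == 1) c(x, x) else sort(x[1:2])
  spec <- list(shaft_radius = shaft_radius, shaft_length = shaft_length,
               shaft_curvature = shaft_curvature,
               n_spines = n_spines,
               neck_radius = rng2(neck_radius),
               neck_length = rng2(neck_length),
               head_radius = rng2(head_radius),
               min_separation = min_separation, noise = noise,
               resolution = resolution, junction_shaft = junction_shaft,
               seed = as.integer(seed))
  stopifnot(spec$shaft_radius > 0, spec$shaft_length > 0,
            all(spec$neck_length > 0), all(spec$head_radius > 0),
            spec$resolution > 0, spec$noise >= 0)
  if (spec$neck_radius[2] >= spec$head_radius[1])
    warning("neck radius range overlaps head radius range; ",
            "mushroom constraint r_n < r_h may be violated")
  structure(spec, class = "dendrite_spec")
}

# axis point, tangent and the two cross-section normals at arc length t
# (t in [0, L]; straight axes run along x, bent axes arc in the xy-plane)
dendrite_axis <- function(spec, t) {
  L <- spec$shaft_length
  kap <- spec$shaft_curvature
  if (kap == 0) {
    cbind(t - L / 2, 0, 0)
  } else {
    rho <- 1 / kap
    th <- (t - L / 2) / rho
    cbind(rho * sin(th), rho * (1 - cos(th)), 0)
  }
}

dendrite_frame <- function(spec, t) {
  kap <- spec$shaft_curvature
  if (kap == 0) {
    list(n1 = c(0, 1, 0), n2 = c(0, 0, 1))
  } else {
    rho <- 1 / kap
    th <- (t - spec$shaft_length / 2) / rho
    list(n1 = c(sin(th), -cos(th), 0), n2 = c(0, 0, 1))
  }
}

# signed distance to the flat-capped shaft cylinder. EM dendritic segments
# are clipped pieces of longer dendrites, so the generator ends the shaft
# in cut planes rather than bulbous caps (a dome end would be geometrically
# indistinguishable from a spine head).
shaft_sdf <- function(spec, px, py, pz) {
  L <- spec$shaft_length
  kap <- spec$shaft_curvature
  if (kap == 0) {
    dr <- sqrt(py^2 + pz^2) - spec$shaft_radius   # radial excess
    da <- abs(px) - L / 2                          # axial overshoot
    pmin(pmax(dr, da), 0) +
      sqrt(pmax(dr, 0)^2 + pmax(da, 0)^2)
  } else {
    rho <- 1 / kap
    qx <- px
    qy <- py - rho
    # closest point on the full axis circle (no angular clamp)
    rad <- sqrt(qx^2 + qy^2)
    dr <- sqrt((rad - rho)^2 + pz^2) - spec$shaft_radius
    phi <- atan2(qx, -qy)
    da <- (abs(phi) - L / (2 * rho)) * rho
    pmin(pmax(dr, da), 0) +
      sqrt(pmax(dr, 0)^2 + pmax(da, 0)^2)
  }
}

# distance from points to segment ab (vectorized over points)
segment_distance <- function(px, py, pz, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]; abz <- b[3] - a[3]
  len2 <- abx^2 + aby^2 + abz^2
  tt <- ((px - a[1]) * abx + (py - a[2]) * aby + (pz - a[3]) * abz) /
    max(len2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (a[1] + tt * abx))^2 + (py - (a[2] + tt * aby))^2 +
       (pz - (a[3] + tt * abz))^2)
}

# per-spine primitive SDF (neck capsule united with head sphere)
spine_sdf <- function(sp, px, py, pz) {
  dn <- segment_distance(px, py, pz, sp$P0in, sp$P1) - sp$r_n
  dh <- sqrt((px - sp$P1[1])^2 + (py - sp$P1[2])^2 +
             (pz - sp$P1[3])^2) - sp$r_h
  pmin(dn, dh)
}

# deterministic spine placement; errors when the density is infeasible
place_spines <- function(spec) {
  n <- if (length(spec$n_spines) == 2)
    sample(spec$n_spines[1]:spec$n_spines[2], 1) else spec$n_spines
  if (n == 0) return(list())
  L <- spec$shaft_length
  pad <- max(0.5, spec$head_radius[2])
  usable <- L - 2 * pad
  maxfit <- if (usable < 0) 0 else floor(usable / spec$min_separation) + 1
  if (n > maxfit)
    stop("cannot place ", n, " spines at separation ",
         spec$min_separation, " um; maximum feasible count is ", maxfit)
  # uniform draw over valid configurations: place the mandatory
  # separations, then distribute the leftover slack as sorted uniforms
  slack <- usable - (n - 1) * spec$min_separation
  u <- sort(stats::runif(n, 0, slack))
  t <- pad + (seq_len(n) - 1) * spec$min_separation + u
  phi <- stats::runif(n, 0, 2 * pi)
  spines <- vector("list", n)
  for (i in seq_len(n)) {
    r_n <- stats::runif(1, spec$neck_radius[1], spec$neck_radius[2])
    l_n <- stats::runif(1, spec$neck_length[1], spec$neck_length[2])
    r_h <- stats::runif(1, spec$head_radius[1], spec$head_radius[2])
    ax <- dendrite_axis(spec, t[i])[1, ]
    fr <- dendrite_frame(spec, t[i])
    d <- cos(phi[i]) * fr$n1 + sin(phi[i]) * fr$n2
    P0 <- ax + spec$shaft_radius * d
    spines[[i]] <- list(
      t = t[i], phi = phi[i], r_n = r_n, l_n = l_n, r_h = r_h,
      dir = d, P0 = P0,
      P0in = P0 - 0.15 * d,             # extend into the shaft to fuse
      P1 = P0 + l_n * d,
      length = l_n + r_h                # shaft surface to spine tip
    )
  }
  spines
}

#' Generate a labeled synthetic spiny dendrite
#'
#' Builds the signed-distance field of the shaft/spine union, extracts the
#' surface with marching tetrahedra at the requested resolution, labels
#' each vertex by its nearest primitive (with the junction ring assigned to
#' the shaft), optionally displaces vertices with smooth radial noise, and
#' records analytic/Monte-Carlo ground truth per spine. Deterministic given
#' the spec seed.
#'
#' @param spec a [dendrite_spec()].
#' @return list with `mesh` (watertight `triangle_mesh`), `truth` (list:
#'   `labels`, `spine_sets`, `params` data frame with per-spine
#'   neck/head radii, length, Monte-Carlo area and volume with standard
#'   errors), and `spec`.
#' @export
generate_dendrite <- function(spec) {
  stopifnot(inherits(spec, "dendrite_spec"))
  with_seed(spec$seed, {
    spines <- place_spines(spec)
    h <- spec$resolution

    # grid bounds from primitive extents
    probe <- dendrite_axis(spec, seq(0, spec$shaft_length, length.out = 64))
    pts <- rbind(probe + spec$shaft_radius, probe - spec$shaft_radius)
    for (sp in spines) {
      pts <- rbind(pts, sp$P1 + sp$r_h, sp$P1 - sp$r_h)
    }
    # the irrational origin offset keeps flat SDF facets (the cut ends)
    # off exact grid planes, which would create zero-area triangles
    lo <- apply(pts, 2, min) - 4 * h - 0.0137731 * h
    hi <- apply(pts, 2, max) + 4 * h
    dims <- as.integer(ceiling((hi - lo) / h)) + 1L
    xs <- lo[1] + (seq_len(dims[1]) - 1) * h
    ys <- lo[2] + (seq_len(dims[2]) - 1) * h
    zs <- lo[3] + (seq_len(dims[3]) - 1) * h
    N <- prod(dims)
    px <- rep(xs, times = dims[2] * dims[3])
    py <- rep(rep(ys, each = dims[1]), times = dims[3])
    pz <- rep(zs, each = dims[1] * dims[2])

    field <- shaft_sdf(spec, px, py, pz)
    for (sp in spines) field <- pmin(field, spine_sdf(sp, px, py, pz))

    iso <- .cpp_marching_tetrahedra(field + 1e-9, dims, lo, h, 0)
    # fuse sliver vertices and drop the resulting degenerate faces (an
    # edge collapse, so watertightness is preserved) before labeling
    mesh <- repair_mesh(triangle_mesh(iso$vertices, iso$faces,
                                      validate = FALSE))

    # labels by nearest primitive at the clean (pre-noise) positions
    vx <- mesh$vertices[, 1]; vy <- mesh$vertices[, 2]
    vz <- mesh$vertices[, 3]
    dshaft <- shaft_sdf(spec, vx, vy, vz)
    labels <- rep("shaft", nrow(mesh$vertices))
    owner <- integer(nrow(mesh$vertices))
    if (length(spines)) {
      dsp <- vapply(spines, function(sp) spine_sdf(sp, vx, vy, vz),
                    numeric(length(vx)))
      best <- max.col(-dsp, ties.method = "first")
      dbest <- dsp[cbind(seq_along(best), best)]
      margin <- if (spec$junction_shaft) h else 0
      is_spine <- dbest < dshaft - margin
      labels[is_spine] <- "spine"
      owner[is_spine] <- best[is_spine]
    }

    if (spec$noise > 0) {
      amp <- spec$noise * spec$shaft_radius
      nwav <- 6L
      kmag <- 2 * pi / (8 * h)
      dirs <- matrix(stats::rnorm(3 * nwav), nwav, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2)) * kmag
      phase <- stats::runif(nwav, 0, 2 * pi)
      disp <- numeric(nrow(mesh$vertices))
      for (wv in seq_len(nwav))
        disp <- disp + as.numeric(sin(mesh$vertices %*% dirs[wv, ] +
                                      phase[wv]))
      disp <- amp * disp / nwav
      nrm <- vertex_normals(mesh)
      mesh$vertices <- mesh$vertices + nrm * disp
    }

    spine_sets <- lapply(seq_along(spines), function(i) which(owner == i))
    params <- spine_truth_table(spec, spines)
    validate_mesh(mesh)
    list(mesh = mesh,
         truth = list(labels = labels, spine_sets = spine_sets,
                      params = params),
         spec = spec)
  })
}

# Monte-Carlo ground-truth area and volume per spine: volume by rejection
# sampling in the primitive bounding box (excluding shaft interior), area
# by sampling the primitive surfaces and keeping the exposed fraction
spine_truth_table <- function(spec, spines, n_mc = 40000L) {
  if (length(spines) == 0) {
    return(data.frame(spine = integer(0), neck_radius = numeric(0),
                      neck_length = numeric(0), head_radius = numeric(0),
                      length = numeric(0), area = numeric(0),
                      area_se = numeric(0), volume = numeric(0),
                      volume_se = numeric(0)))
  }
  rows <- lapply(seq_along(spines), function(i) {
    sp <- spines[[i]]
    with_seed(spec$seed + 7919L * i, {
      rmax <- max(sp$r_n, sp$r_h)
      lo <- pmin(sp$P0in, sp$P1) - rmax
      hi <- pmax(sp$P0in, sp$P1) + rmax
      qx <- stats::runif(n_mc, lo[1], hi[1])
      qy <- stats::runif(n_mc, lo[2], hi[2])
      qz <- stats::runif(n_mc, lo[3], hi[3])
      inside <- spine_sdf(sp, qx, qy, qz) < 0 &
        shaft_sdf(spec, qx, qy, qz) > 0
      fr <- mean(inside)
      boxv <- prod(hi - lo)
      vol <- fr * boxv
      vol_se <- boxv * sqrt(fr * (1 - fr) / n_mc)

      # exposed neck lateral surface
      e1 <- dendrite_frame(spec, sp$t)$n1
      if (abs(sum(e1 * sp$dir)) > 0.9) e1 <- c(0, 0, 1)
      e1 <- e1 - sum(e1 * sp$dir) * sp$dir
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(sp$dir[2] * e1[3] - sp$dir[3] * e1[2],
              sp$dir[3] * e1[1] - sp$dir[1] * e1[3],
              sp$dir[1] * e1[2] - sp$dir[2] * e1[1])
      ns <- 8000L
      s <- stats::runif(ns)
      psi <- stats::runif(ns, 0, 2 * pi)
      base <- matrix(sp$P0, ns, 3, byrow = TRUE) +
        outer(s * sp$l_n, sp$dir) +
        sp$r_n * (outer(cos(psi), e1) + outer(sin(psi), e2))
      keep_n <- shaft_sdf(spec, base[, 1], base[, 2], base[, 3]) > 0 &
        sqrt(rowSums(sweep(base, 2, sp$P1)^2)) > sp$r_h
      a_neck <- 2 * pi * sp$r_n * sp$l_n
      # exposed head sphere surface
      u <- stats::rnorm(ns); v <- stats::rnorm(ns); w <- stats::rnorm(ns)
      nn <- sqrt(u^2 + v^2 + w^2)
      hx <- sp$P1[1] + sp$r_h * u / nn
      hy <- sp$P1[2] + sp$r_h * v / nn
      hz <- sp$P1[3] + sp$r_h * w / nn
      keep_h <- (segment_distance(hx, hy, hz, sp$P0in, sp$P1) > sp$r_n) &
        shaft_sdf(spec, hx, hy, hz) > 0
      a_head <- 4 * pi * sp$r_h^2
      area <- a_neck * mean(keep_n) + a_head * mean(keep_h)
      area_se <- sqrt(a_neck^2 * stats::var(keep_n) / ns +
                      a_head^2 * stats::var(keep_h) / ns)
      data.frame(spine = i, neck_radius = sp$r_n, neck_length = sp$l_n,
                 head_radius = sp$r_h, length = sp$length,
                 area = area, area_se = area_se,
                 volume = vol, volume_se = vol_se)
    })
  })
  do.call(rbind, rows)
}

#' Generate an independent dataset of synthetic dendrites
#'
#' Derives an independent sub-seed per mesh from the master seed, so any
#' two datasets built from different master seeds (or different mesh
#' indices) are independent draws from the spec's parameter ranges. The
#' manifest records every resolved spec; re-running it reproduces the
#' dataset byte for byte.
#'
#' @param n_meshes number of meshes.
#' @param spec template [dendrite_spec()]; per-mesh seeds are derived.
#' @param seed master seed.
#' @param dir optional output directory; when given, each mesh is written
#'   as PLY + labels CSV + truth JSON, plus a `manifest.json`.
#' @return list of `generate_dendrite()` results, with the manifest as
#'   attribute `"manifest"`.
#' @export
generate_dataset <- function(n_meshes, spec = dendrite_spec(), seed = 1L,
                             dir = NULL) {
  stopifnot(n_meshes >= 1)
  out <- vector("list", n_meshes)
  manifest <- vector("list", n_meshes)
  for (i in seq_len(n_meshes)) {
    sp <- spec
    sp$seed <- as.integer((as.double(seed) * 10007 + i * 97) %% 2147483647)
    out[[i]] <- generate_dendrite(sp)
    manifest[[i]] <- unclass(sp)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      base <- file.path(dir, sprintf("dendrite_%03d", i))
      write_mesh(out[[i]]$mesh, paste0(base, ".ply"))
      write_labels(out[[i]]$truth$labels, paste0(base, "_labels.csv"))
      jsonlite::write_json(out[[i]]$truth$params,
                           paste0(base, "_truth.json"), digits = NA)
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(out, "manifest") <- manifest
  out
}
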