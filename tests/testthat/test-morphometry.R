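test_that("spline arc length is exact on analytic curves", {
  # collinear points
  path <- cbind(0:2, 0, 0)
  expect_equal(spine_length(path, presmooth = 1), 2, tolerance = 1e-3)
  # quarter circle of radius 1
  th <- seq(0, pi / 2, length.out = 20)
  qc <- cbind(cos(th), sin(th), 0)
  expect_equal(spine_length(qc, presmooth = 1), pi / 2, tolerance = 0.02)
  # resampling convergence
  l50 <- spine_length(qc, n_samples = 50, presmooth = 1)
  l500 <- spine_length(qc, n_samples = 500, presmooth = 1)
  expect_lt(abs(l500 - l50) / l50, 0.01)
})

test_that("arc length is rigid-motion invariant and scales linearly", {
  set.seed(3)
  th <- seq(0, 1, length.out = 15)
  path <- cbind(th, th^2, sin(th))
  L0 <- spine_length(path, presmooth = 1)
  ang <- 0.9
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  expect_equal(spine_length(path %*% t(R) + 5, presmooth = 1), L0,
               tolerance = 1e-9)
  expect_equal(spine_length(path * 3, presmooth = 1), 3 * L0,
               tolerance = 1e-9)
})

test_that("single-point paths degrade with a warning", {
  expect_warning(l <- spine_length(cbind(1, 1, 1), voxel_size = 0.05),
                 "single-point")
  expect_equal(l, 0.05)
})

test_that("thickness profile recovers tube radii", {
  # synthetic cylinder around a known axis
  cyl <- open_cylinder(r = 0.1, len = 2, nu = 24, nv = 30)
  path <- cbind(0, 0, seq(-1, 1, by = 0.05))
  prof <- thickness_profile(seq_len(nrow(cyl$vertices)), cyl, path)
  expect_equal(median(prof, na.rm = TRUE), 0.1, tolerance = 0.15)
  # single path point: mean of all distances
  prof1 <- thickness_profile(seq_len(nrow(cyl$vertices)), cyl,
                             cbind(0, 0, 0))
  expect_equal(prof1,
               mean(sqrt(rowSums(sweep(cyl$vertices, 2, c(0, 0, 0))^2))))
})

test_that("neck/head diameters read the profile extrema", {
  prof <- c(0.2, 0.1, 0.08, 0.1, 0.2, 0.3, 0.25)
  d <- neck_head_diameters(prof, smooth_window = 1)
  expect_equal(unname(d["neck_diameter"]), 2 * 0.08)
  expect_equal(unname(d["head_diameter"]), 2 * 0.3)
  # constant profile: neck == head
  dc <- neck_head_diameters(rep(0.12, 10), smooth_window = 1)
  expect_equal(unname(dc["neck_diameter"]), unname(dc["head_diameter"]))
  # single value
  d1 <- neck_head_diameters(0.3)
  expect_equal(unname(d1), c(0.6, 0.6))
})

test_that("area and volume are analytic on closed sphere patches", {
  s <- icosphere(3, 0.3)
  av <- spine_area_volume(s, seq_len(nrow(s$vertices)))
  expect_equal(unname(av["area"]), 4 * pi * 0.3^2, tolerance = 0.03)
  expect_equal(unname(av["volume"]), 4 * pi * 0.3^3 / 3, tolerance = 0.03)
  # area/volume ratio of a sphere ~ 3/r
  expect_equal(unname(av["area"] / av["volume"]), 3 / 0.3,
               tolerance = 0.05)
  # disjoint spheres: volumes add
  s2 <- icosphere(2, 0.2)
  s2$vertices[, 1] <- s2$vertices[, 1] + 2
  both <- triangle_mesh(rbind(s$vertices, s2$vertices),
                        rbind(s$faces, s2$faces + nrow(s$vertices)))
  av2 <- spine_area_volume(both, seq_len(nrow(both$vertices)))
  expect_equal(unname(av2["volume"]),
               4 * pi * (0.3^3 + 0.2^3) / 3, tolerance = 0.03)
})

test_that("open spine patches are capped before volume integration", {
  # half sphere: open equator loop, true enclosed volume 2/3 pi r^3
  s <- icosphere(3)
  upper <- which(s$vertices[, 3] > -1e-9)
  av <- spine_area_volume(s, upper)
  expect_equal(unname(av["area"]), 2 * pi, tolerance = 0.05)
  expect_equal(unname(av["volume"]), 2 * pi / 3, tolerance = 0.05)
})

test_that("spine paths run base to tip along the skeleton", {
  g <- small_dendrite()
  sk <- small_dendrite_skeleton()
  shaft <- which(g$truth$labels == "shaft")
  for (i in seq_along(g$truth$spine_sets)) {
    sv <- g$truth$spine_sets[[i]]
    path <- spine_skeleton_path(sv, g$mesh, sk, shaft)
    expect_gte(nrow(path), 2)
    # base is closer to the shaft than the tip
    dshaft <- function(p) min(bf_min_dist(rbind(p),
                                          g$mesh$vertices[shaft, ]))
    expect_lt(dshaft(path[1, ]), dshaft(path[nrow(path), ]))
    # path length close to the true spine length
    tr <- g$truth$params[i, ]
    L <- spine_length(path, voxel_size = sk$voxel_size)
    expect_equal(L + tr$head_radius, tr$length, tolerance = 0.35)
  }
})

test_that("full morphometry recovers generator ground truth", {
  g <- small_dendrite()
  sk <- small_dendrite_skeleton()
  shaft <- which(g$truth$labels == "shaft")
  mo <- spine_morphometry(g$mesh, g$truth$spine_sets, sk, shaft)
  tr <- g$truth$params
  expect_equal(nrow(mo), nrow(tr))
  relerr <- function(a, b) abs(a - b) / b
  expect_lt(median(relerr(mo$neck_diameter_um, 2 * tr$neck_radius)), 0.2)
  expect_lt(median(relerr(mo$head_diameter_um, 2 * tr$head_radius)), 0.2)
  expect_lt(median(relerr(mo$length_um, tr$length)), 0.2)
  # mushroom constraint propagates to the estimates
  expect_true(all(mo$head_diameter_um >= mo$neck_diameter_um))
  # morphometry is robust to moderate decimation of the mesh
  md <- decimate(g$mesh, round(nrow(g$mesh$vertices) / 2))
  nn <- spineseg:::.cpp_min_dist_idx(md$vertices, g$mesh$vertices)
  lab2 <- g$truth$labels[nn$index]
  vol_full <- spine_area_volume(g$mesh, g$truth$spine_sets[[1]])["volume"]
  sets2 <- which(lab2 == "spine")
  adj2 <- vertex_adjacency(md)
  comp2 <- group_components(adj2, sets2)
  vol_half <- spine_area_volume(md, comp2[[1]])["volume"]
  # compare the matching component (largest may differ in order)
  vols_full <- sort(vapply(g$truth$spine_sets, function(sv)
    spine_area_volume(g$mesh, sv)["volume"], 0))
  vols_half <- sort(vapply(comp2[seq_along(g$truth$spine_sets)],
                           function(sv)
                             spine_area_volume(md, sv)["volume"], 0))
  expect_equal(vols_half, vols_full, tolerance = 0.05)
})

test_that("empty spine lists produce an empty morphometry table", {
  g <- small_dendrite()
  sk <- small_dendrite_skeleton()
  mo <- spine_morphometry(g$mesh, list(), sk,
                          which(g$truth$labels == "shaft"))
  expect_equal(nrow(mo), 0)
  expect_named(mo, c("spine_id", "neck_diameter_um", "head_diameter_um",
                     "length_um", "area_um2", "volume_um3", "n_vertices"))
})
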