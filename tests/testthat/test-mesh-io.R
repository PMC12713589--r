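test_that("OBJ read/write round-trips a tetrahedron", {
  m <- tetrahedron()
  p <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, p)
  m2 <- read_mesh(p)
  expect_equal(nrow(m2$vertices), 4)
  expect_equal(nrow(m2$faces), 4)
  expect_true(is_watertight(m2))
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-9)
})

test_that("OBJ with out-of-range face index errors", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 9"), p)
  expect_error(read_mesh(p), "out of range")
})

test_that("empty OBJ errors", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines("# nothing here", p)
  expect_error(read_mesh(p), "empty mesh")
})

test_that("PLY round-trips in ascii and binary within 1e-6", {
  m <- icosphere(1)
  for (bin in c(FALSE, TRUE)) {
    p <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, p, binary = bin)
    m2 <- read_mesh(p, repair = FALSE)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
    expect_equal(m2$faces, m$faces)
  }
})

test_that("vertex adjacency matches the brute-force face scan", {
  m <- tetrahedron()
  adj <- vertex_adjacency(m)
  expect_true(all(lengths(adj$neighbors) == 3))

  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  adj1 <- vertex_adjacency(tri)
  expect_equal(adj1$neighbors[[1]], c(2L, 3L))

  d <- small_dendrite()$mesh
  sub <- decimate(d, 800)           # small but irregular mesh
  got <- vertex_adjacency(sub)$neighbors
  want <- bf_adjacency(sub)
  expect_equal(lapply(got, sort), want)
  # symmetry
  for (i in seq_along(got)) {
    for (j in got[[i]]) expect_true(i %in% got[[j]])
  }
})

test_that("label CSV round-trips and validates", {
  labs <- c("spine", "shaft", "shaft", "spine")
  p <- withr::local_tempfile(fileext = ".csv")
  write_labels(labs, p)
  expect_equal(read_labels(p, 4), labs)
  expect_error(read_labels(p, 3), "out of range")
  oh <- label_onehot(labs)
  expect_equal(dim(oh), c(4L, 2L))
  expect_true(all(rowSums(oh) == 1))
  expect_equal(oh[1, ], c(spine = 1, shaft = 0))
})

test_that("map_labels_by_radius obeys its contract and the scan oracle", {
  m <- icosphere(2)
  # a single exact vertex with a tiny radius
  expect_equal(map_labels_by_radius(m$vertices[5, , drop = FALSE], m,
                                    r_th = 1e-6), 5L)
  # radius larger than the diameter captures everything
  expect_equal(map_labels_by_radius(m$vertices[1, , drop = FALSE], m,
                                    r_th = 10),
               seq_len(nrow(m$vertices)))
  # empty source set
  expect_equal(map_labels_by_radius(matrix(0, 0, 3), m, 0.5), integer(0))
  # random points vs brute-force distance scan, and monotonicity in r
  set.seed(31)
  pts <- matrix(runif(30, -1, 1), ncol = 3)
  prev <- integer(0)
  for (r in c(0.1, 0.3, 0.6)) {
    got <- map_labels_by_radius(pts, m, r)
    want <- which(bf_min_dist(m$vertices, pts) <= r)
    expect_equal(got, want)
    expect_true(all(prev %in% got))
    prev <- got
  }
})

test_that("make_watertight wraps clean, holey and disjoint inputs", {
  s <- icosphere(3)
  w <- make_watertight(s, voxel_size = 0.06)
  expect_true(is_watertight(w))
  expect_equal(mesh_volume(w), mesh_volume(s), tolerance = 0.05)

  # delete 10% of the faces, wrap, compare to the analytic ball volume
  set.seed(5)
  holey <- triangle_mesh(s$vertices,
                         s$faces[-sample(nrow(s$faces),
                                         round(0.1 * nrow(s$faces))), ],
                         validate = FALSE)
  expect_false(is_watertight(holey))
  w2 <- make_watertight(holey, voxel_size = 0.06)
  expect_true(is_watertight(w2))
  expect_equal(mesh_volume(w2), 4 * pi / 3, tolerance = 0.1)

  # two disjoint spheres: output passes the edge-manifold audit
  s2 <- icosphere(2, 0.5)
  s2$vertices[, 1] <- s2$vertices[, 1] + 3
  both <- triangle_mesh(rbind(s$vertices, s2$vertices),
                        rbind(s$faces, s2$faces + nrow(s$vertices)))
  w3 <- make_watertight(both, voxel_size = 0.06)
  expect_true(is_watertight(w3))

  # coplanar degenerate input
  flat <- flat_grid(5)
  expect_error(make_watertight(flat), "coplanar")
})

test_that("decimate honours target, validity and volume", {
  s <- icosphere(4)           # 2562 vertices
  d <- decimate(s, 642)
  expect_lte(nrow(d$vertices), ceiling(1.05 * 642))
  expect_true(is_watertight(d))
  expect_equal(mesh_volume(d), 4 * pi / 3, tolerance = 0.1)
  expect_error(decimate(s, 3), ">= 4")
  expect_identical(decimate(s, nrow(s$vertices) + 10), s)
})

test_that("repair merges duplicate vertices and fixes orientation", {
  m <- tetrahedron()
  # duplicate every vertex and use the duplicates in half the faces
  v2 <- rbind(m$vertices, m$vertices + 1e-12)
  f2 <- m$faces
  f2[c(1, 3), ] <- f2[c(1, 3), ] + 4L
  # flip one face's orientation
  f2[2, ] <- f2[2, c(1, 3, 2)]
  r <- repair_mesh(triangle_mesh(v2, f2, validate = FALSE))
  expect_equal(nrow(r$vertices), 4)
  expect_true(is_watertight(r))
  expect_gt(mesh_volume(r, signed = TRUE), 0)
})
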