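test_that("parity voxelization recovers analytic volumes", {
  cube <- cube_mesh(1)
  vol <- voxelize(cube, 0.1)
  expect_equal(sum(vol$grid) * 0.1^3, 1, tolerance = 0.05)

  s <- icosphere(3)
  vs <- voxelize(s, 0.05)
  expect_equal(sum(vs$grid) * 0.05^3, 4 * pi / 3, tolerance = 0.03)
})

test_that("voxelize refuses non-watertight input, naming the edges", {
  cyl <- open_cylinder()
  expect_error(voxelize(cyl, 0.1), "boundary edges")
})

test_that("oversized voxels degrade to a tiny but non-empty volume", {
  s <- icosphere(1, 0.3)
  v <- voxelize(s, 5)
  expect_gte(sum(v$grid), 1)
})

test_that("thinning a solid cylinder yields a centered chain", {
  # axis along x: length 20 voxels, radius 4 voxels
  dims <- c(28L, 13L, 13L)
  grid <- array(FALSE, dims)
  for (i in 5:24) {
    for (j in 1:13) for (k in 1:13) {
      if ((j - 7)^2 + (k - 7)^2 <= 16) grid[i, j, k] <- TRUE
    }
  }
  vol <- voxel_volume(grid, 1, c(0, 0, 0))
  sk <- skeletonize_volume(vol)
  # all skeleton points within 1.5 voxels of the true axis (j = k = 7)
  dev <- sqrt((sk$points[, 2] - 6)^2 + (sk$points[, 3] - 6)^2)
  expect_lte(max(dev), 1.5)
  # a chain: two endpoints, everything else degree 2
  deg <- tabulate(c(sk$edges[, 1], sk$edges[, 2]), nrow(sk$points))
  expect_equal(sum(deg == 1), 2)
  # spans most of the cylinder length
  expect_gt(diff(range(sk$points[, 1])), 12)
})

test_that("a single voxel is its own skeleton", {
  grid <- array(FALSE, c(3L, 3L, 3L))
  grid[2, 2, 2] <- TRUE
  sk <- skeletonize_volume(voxel_volume(grid, 1, c(0, 0, 0)))
  expect_equal(nrow(sk$points), 1)
})

test_that("thinning preserves the topology of a solid torus", {
  n <- 25
  grid <- array(FALSE, c(n, n, 9L))
  for (i in 1:n) for (j in 1:n) for (k in 1:9) {
    u <- i - 13; v <- j - 13; w <- k - 5
    if ((sqrt(u^2 + v^2) - 8)^2 + w^2 <= 9) grid[i, j, k] <- TRUE
  }
  sk <- skeletonize_volume(voxel_volume(grid, 1, c(0, 0, 0)))
  # at least one cycle: edge count reaches vertex count (connected input)
  expect_gte(nrow(sk$edges), nrow(sk$points))
})

test_that("skeletons are thin: no 2x2x2 block of skeleton voxels", {
  for (fix in list(small_dendrite_skeleton())) {
    # reconstruct voxel occupancy from the points
    vs <- fix$voxel_size
    ijk <- round(sweep(fix$points, 2,
                       apply(fix$points, 2, min)) / vs) + 1
    dims <- apply(ijk, 2, max) + 1
    occ <- array(FALSE, dims)
    occ[ijk] <- TRUE
    full <- 0
    it <- which(occ, arr.ind = TRUE)
    for (r in seq_len(nrow(it))) {
      i <- it[r, 1]; j <- it[r, 2]; k <- it[r, 3]
      if (i < dims[1] && j < dims[2] && k < dims[3] &&
          all(occ[i:(i + 1), j:(j + 1), k:(k + 1)])) full <- full + 1
    }
    expect_equal(full, 0)
  }
})

test_that("distance to skeleton matches the brute-force double loop", {
  m <- icosphere(1)
  skel_pts <- matrix(rnorm(30), ncol = 3)
  sk <- skeleton(skel_pts, cbind(integer(0), integer(0)), 0.1)
  D <- distance_to_skeleton(m, sk)
  expect_equal(D, bf_min_dist(m$vertices, skel_pts), tolerance = 1e-12)
  # invariant to skeleton point ordering
  sk2 <- skeleton(skel_pts[sample(nrow(skel_pts)), ],
                  cbind(integer(0), integer(0)), 0.1)
  expect_equal(distance_to_skeleton(m, sk2), D, tolerance = 1e-12)
  # coincident point
  sk3 <- skeleton(m$vertices[7, , drop = FALSE],
                  cbind(integer(0), integer(0)), 0.1)
  expect_equal(distance_to_skeleton(m, sk3)[7], 0)
})

test_that("cylinder surface distance to its axis recovers the radius", {
  cyl <- open_cylinder(r = 0.5, len = 4)
  axis_pts <- cbind(0, 0, seq(-2, 2, by = 0.02))
  sk <- skeleton(axis_pts, cbind(integer(0), integer(0)), 0.02)
  D <- distance_to_skeleton(cyl, sk)
  expect_true(all(abs(D - 0.5) / 0.5 < 0.05))
})

test_that("dendrite shaft distances recover the shaft radius", {
  g <- small_dendrite()
  sk <- small_dendrite_skeleton()
  D <- distance_to_skeleton(g$mesh, sk)
  shaft <- which(g$truth$labels == "shaft")
  # exclude cut ends, where the skeleton legitimately stops short
  core <- shaft[abs(g$mesh$vertices[shaft, 1]) <
                  g$spec$shaft_length / 2 - 0.5]
  expect_lt(mean(abs(D[core] - g$spec$shaft_radius)) / g$spec$shaft_radius,
            0.1)
})

test_that("skeleton CSV export round-trips points", {
  sk <- small_dendrite_skeleton()
  p <- withr::local_tempfile(fileext = ".csv")
  pe <- withr::local_tempfile(fileext = ".csv")
  write_skeleton_csv(sk, p, pe)
  d <- read.csv(p)
  expect_equal(nrow(d), nrow(sk$points))
  e <- read.csv(pe)
  expect_named(e, c("i", "j"))
})
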