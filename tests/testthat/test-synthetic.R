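test_that("generation is bit-reproducible given the spec", {
  spec <- dendrite_spec(shaft_length = 4, n_spines = 2,
                        resolution = 0.08, seed = 77L)
  a <- generate_dendrite(spec)
  b <- generate_dendrite(spec)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$params, b$truth$params)
})

test_that("a spineless spec gives a closed all-shaft tube", {
  g <- generate_dendrite(dendrite_spec(shaft_length = 3, n_spines = 0,
                                       resolution = 0.08, seed = 2L))
  expect_true(all(g$truth$labels == "shaft"))
  expect_true(is_watertight(g$mesh))
  cf <- curvature_field(g$mesh)
  expect_equal(sum(cf$K * cf$A), 4 * pi, tolerance = 0.01)
})

test_that("spine sets are disjoint, connected and labeled consistently", {
  g <- small_dendrite()
  expect_true(is_watertight(g$mesh))
  validate_mesh(g$mesh)
  sets <- g$truth$spine_sets
  expect_length(sets, 3)
  expect_equal(anyDuplicated(unlist(sets)), 0L)
  expect_equal(sort(unlist(sets)), which(g$truth$labels == "spine"))
  adj <- vertex_adjacency(g$mesh)
  for (sv in sets) expect_length(group_components(adj, sv), 1)
  # truth values finite and positive, mushroom constraint honored
  tr <- g$truth$params
  expect_true(all(unlist(tr[-1]) > 0))
  expect_true(all(tr$neck_radius < tr$head_radius))
  expect_equal(tr$length, tr$neck_length + tr$head_radius)
})

test_that("spine vertex fraction grows with spine count", {
  frac <- vapply(c(2, 5), function(k) {
    g <- generate_dendrite(dendrite_spec(n_spines = k, resolution = 0.08,
                                         seed = 5L))
    mean(g$truth$labels == "spine")
  }, 0)
  expect_gt(frac[2], frac[1])
})

test_that("infeasible spine density errors with the feasible maximum", {
  spec <- dendrite_spec(shaft_length = 3, n_spines = 12,
                        min_separation = 1.0, resolution = 0.08,
                        seed = 1L)
  expect_error(generate_dendrite(spec), "maximum feasible count")
})

test_that("curvature semantics: domes positive K, junction saddles negative", {
  g <- small_dendrite()
  cf <- curvature_field(g$mesh)
  adj <- vertex_adjacency(g$mesh)
  tr <- g$truth$params
  for (i in seq_along(g$truth$spine_sets)) {
    sv <- g$truth$spine_sets[[i]]
    # head: spine vertices within the head sphere
    v <- g$mesh$vertices[sv, , drop = FALSE]
    # distal third of the spine by distance from the shaft axis
    d_ax <- sqrt(v[, 2]^2 + v[, 3]^2)
    head_v <- sv[d_ax > quantile(d_ax, 2 / 3)]
    expect_gt(median(cf$K[head_v]), 0)
    expect_lt(median(cf$H[head_v]), 0)   # convex => negative H
    # junction ring: shaft vertices adjacent to the spine set
    ring <- setdiff(unique(unlist(adj$neighbors[sv])), sv)
    ring <- ring[g$truth$labels[ring] == "shaft"]
    expect_lt(median(cf$K[ring]), 0)     # saddle => negative K
  }
})

test_that("surface noise perturbs geometry but keeps the mesh valid", {
  gn <- generate_dendrite(dendrite_spec(shaft_length = 3, n_spines = 1,
                                        resolution = 0.08, noise = 0.05,
                                        seed = 9L))
  g0 <- generate_dendrite(dendrite_spec(shaft_length = 3, n_spines = 1,
                                        resolution = 0.08, noise = 0,
                                        seed = 9L))
  expect_true(is_watertight(gn$mesh))
  expect_gt(max(abs(gn$mesh$vertices - g0$mesh$vertices)), 0.005)
})

test_that("datasets derive independent per-mesh seeds and a manifest", {
  spec <- dendrite_spec(shaft_length = 3, n_spines = 1,
                        resolution = 0.08)
  ds <- generate_dataset(2, spec, seed = 31)
  expect_false(identical(ds[[1]]$mesh$vertices, ds[[2]]$mesh$vertices))
  man <- attr(ds, "manifest")
  expect_length(man, 2)
  expect_false(man[[1]]$seed == man[[2]]$seed)
  # byte-identical re-run
  ds2 <- generate_dataset(2, spec, seed = 31)
  expect_identical(ds[[1]]$mesh$vertices, ds2[[1]]$mesh$vertices)
  # disk output round-trips
  dir <- withr::local_tempdir()
  generate_dataset(1, spec, seed = 31, dir = dir)
  expect_true(file.exists(file.path(dir, "dendrite_001.ply")))
  expect_true(file.exists(file.path(dir, "dendrite_001_labels.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m <- read_mesh(file.path(dir, "dendrite_001.ply"), repair = FALSE)
  expect_equal(m$vertices, ds[[1]]$mesh$vertices, tolerance = 1e-6)
})

test_that("Monte-Carlo truth areas and volumes carry small standard errors", {
  tr <- small_dendrite()$truth$params
  expect_true(all(tr$volume_se / tr$volume < 0.05))
  expect_true(all(tr$area_se / tr$area < 0.05))
})
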