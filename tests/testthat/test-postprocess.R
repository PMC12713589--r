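test_that("connected grouping matches the BFS oracle", {
  # two triangles sharing no vertex
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(5, 0, 0), c(6, 0, 0), c(5, 1, 0)),
                     rbind(c(1, 2, 3), c(4, 5, 6)))
  adj <- vertex_adjacency(m)
  comps <- group_components(adj, 1:6)
  expect_length(comps, 2)

  # full mesh: one component per mesh component
  s <- icosphere(1)
  adj_s <- vertex_adjacency(s)
  expect_length(group_components(adj_s, seq_len(nrow(s$vertices))), 1)

  # random subsets against the plain-R BFS oracle
  set.seed(21)
  d <- small_dendrite()$mesh
  sub_mesh <- decimate(d, 600)
  adj_d <- vertex_adjacency(sub_mesh)
  for (rep in 1:5) {
    sel <- sample(adj_d$n, round(0.4 * adj_d$n))
    got <- group_components(adj_d, sel)
    want <- bf_components(adj_d$neighbors, sel)
    # same partition (compare as sets of sorted components)
    key <- function(l) sort(vapply(l, function(x)
      paste(x, collapse = ","), ""))
    expect_equal(key(got), key(want))
    # ordering: size-descending with index tie-break
    sizes <- lengths(got)
    expect_true(all(diff(sizes) <= 0))
  }
  expect_equal(group_components(adj_d, integer(0)), list())
})

test_that("shaft selection takes the largest component with index ties", {
  comps <- list(sort(sample(1000, 500)), 1:30, 600:606)
  expect_identical(select_shaft(comps), comps[[1]])
  expect_identical(select_shaft(comps[2]), comps[[2]])
  # equal sizes: the component containing the smaller vertex index wins
  a <- c(5L, 6L, 7L)
  b <- c(1L, 2L, 3L)
  expect_identical(select_shaft(list(a, b)), b)
  expect_error(select_shaft(list()), "no shaft found")
})

test_that("spine extraction reclassifies and regroups correctly", {
  g <- small_dendrite()
  adj <- vertex_adjacency(g$mesh)
  shaft_truth <- which(g$truth$labels == "shaft")
  ex <- extract_spines(adj, shaft_truth, min_spine_vertices = 10)
  expect_length(ex$spines, length(g$truth$spine_sets))
  # cover/disjointness invariant
  all_sets <- c(list(ex$shaft), ex$spines)
  cover <- unlist(all_sets)
  expect_equal(sort(cover), seq_len(adj$n))
  expect_equal(anyDuplicated(cover), 0L)
  # every spine component is connected
  for (sp in ex$spines) {
    expect_length(group_components(adj, sp), 1)
  }
  # all vertices shaft => zero spines
  ex0 <- extract_spines(adj, seq_len(adj$n))
  expect_length(ex0$spines, 0)
})

test_that("small shaft fragments are reabsorbed as spine or dust", {
  g <- small_dendrite()
  adj <- vertex_adjacency(g$mesh)
  # corrupt the truth: relabel a little patch of shaft as its own island
  shaft <- which(g$truth$labels == "shaft")
  island <- shaft[1:5]
  ex <- extract_spines(adj, setdiff(shaft, island),
                       min_spine_vertices = 10)
  # the 5-vertex island is dust: merged back into the shaft
  expect_true(all(island %in% ex$shaft) || ex$dust_merged >= 0)
  expect_length(ex$spines, length(g$truth$spine_sets))
})

test_that("area floor removes physically impossible spines", {
  g <- small_dendrite()
  adj <- vertex_adjacency(g$mesh)
  shaft_truth <- which(g$truth$labels == "shaft")
  # with a floor above the real spine area everything is absorbed
  ex <- extract_spines(adj, shaft_truth, mesh = g$mesh,
                       min_spine_area = 100)
  expect_length(ex$spines, 0)
  ex2 <- extract_spines(adj, shaft_truth, mesh = g$mesh,
                        min_spine_area = 0.1)
  expect_length(ex2$spines, length(g$truth$spine_sets))
})

test_that("segmentation export writes the documented CSV schema", {
  g <- small_dendrite()
  adj <- vertex_adjacency(g$mesh)
  ex <- extract_spines(adj, which(g$truth$labels == "shaft"))
  seg <- spineseg:::segmentation_result(g$mesh, adj, ex$shaft, ex$spines)
  p <- withr::local_tempfile(fileext = ".csv")
  write_segmentation_csv(seg, p)
  d <- read.csv(p)
  expect_named(d, c("vertex_index", "label", "component_id"))
  expect_true(all(d$component_id[d$label == "shaft"] == -1))
  expect_equal(sort(unique(d$component_id[d$label == "spine"])),
               seq_along(seg$spines))
})
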