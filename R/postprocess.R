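#' Connected components of a vertex subset
#'
#' Partitions `vertex_set` into maximal groups connected by paths that stay
#' inside the set (1-ring adjacency). Components are returned sorted by size
#' descending, ties broken by smallest contained vertex index.
#'
#' @param adj a `vertex_adjacency`.
#' @param vertex_set integer vector of vertex indices (1-based).
#' @return list of integer vectors (sorted within each component).
#' @export
group_components <- function(adj, vertex_set) {
  if (length(vertex_set) == 0) return(list())
  csr <- adjacency_csr(adj)
  mask <- logical(adj$n)
  mask[vertex_set] <- TRUE
  comp <- .cpp_components_subset(csr$ptr, csr$idx, mask)
  ids <- comp[vertex_set]
  parts <- split(sort(vertex_set), ids[order(vertex_set)])
  parts <- unname(parts)
  sizes <- lengths(parts)
  firsts <- vapply(parts, min, 0L)
  parts[order(-sizes, firsts)]
}

#' Select the shaft component
#'
#' The largest connected component classified as shaft is designated the
#' entire shaft; all remaining shaft-classified components are assumed to
#' belong to spines. Ties go to the component containing the smallest
#' vertex index.
#'
#' @param shaft_components list of integer vectors from
#'   [group_components()].
#' @return integer vector: the shaft vertex set.
#' @export
select_shaft <- function(shaft_components) {
  if (length(shaft_components) == 0 ||
      sum(lengths(shaft_components)) == 0)
    stop("no shaft found: no shaft-classified vertices")
  sizes <- lengths(shaft_components)
  firsts <- vapply(shaft_components, min, 0L)
  shaft_components[[order(-sizes, firsts)[1]]]
}

#' Extract spine components given the shaft
#'
#' Every vertex outside the shaft set - including members of small
#' components originally classified as shaft - is reclassified as spine and
#' regrouped into connected components. Components smaller than
#' `min_spine_vertices`, or (when the mesh is supplied) with surface area
#' below `min_spine_area`, are dust from boundary noise rather than
#' spines - no real spine is anywhere near 0.1 um^2 - and are merged back
#' into the shaft (the merged count is reported).
#'
#' @param adj a `vertex_adjacency`.
#' @param shaft_set integer vector from [select_shaft()].
#' @param min_spine_vertices smallest believable spine, in vertices
#'   (default 10).
#' @param mesh optional `triangle_mesh` enabling the area floor.
#' @param min_spine_area smallest believable spine surface area (um^2);
#'   only used when `mesh` is given.
#' @return list with `spines` (list of integer vectors, size-descending),
#'   `shaft` (possibly grown by merged dust), `dust_merged` (count of
#'   dissolved components).
#' @export
extract_spines <- function(adj, shaft_set, min_spine_vertices = 10L,
                           mesh = NULL, min_spine_area = 0.1) {
  rest <- setdiff(seq_len(adj$n), shaft_set)
  comps <- group_components(adj, rest)
  small <- lengths(comps) < min_spine_vertices
  if (!is.null(mesh) && min_spine_area > 0 && length(comps)) {
    fa <- face_areas(mesh)
    areas <- vapply(comps, function(cc) {
      inset <- logical(adj$n)
      inset[cc] <- TRUE
      sum(fa[inset[mesh$faces[, 1]] & inset[mesh$faces[, 2]] &
             inset[mesh$faces[, 3]]])
    }, 0)
    small <- small | areas < min_spine_area
  }
  shaft <- sort(unique(c(shaft_set, unlist(comps[small], use.names = FALSE))))
  list(spines = comps[!small], shaft = shaft,
       dust_merged = sum(small))
}

# assemble and check a SegmentationResult
segmentation_result <- function(mesh, adj, shaft, spines, prob = NULL,
                                variant = NULL, check = TRUE) {
  n <- adj$n
  labels <- rep("shaft", n)
  comp <- rep(-1L, n)
  for (i in seq_along(spines)) {
    labels[spines[[i]]] <- "spine"
    comp[spines[[i]]] <- i
  }
  if (check) {
    all_sets <- c(list(shaft), spines)
    cover <- unlist(all_sets, use.names = FALSE)
    stopifnot(!anyDuplicated(cover), length(cover) == n)
  }
  structure(list(labels = labels, shaft = shaft, spines = spines,
                 component = comp, prob = prob, variant = variant,
                 n_vertices = n),
            class = "spine_segmentation")
}

#' @export
print.spine_segmentation <- function(x, ...) {
  cat("spine_segmentation:", x$n_vertices, "vertices,",
      length(x$spines), "spines,", length(x$shaft), "shaft vertices\n")
  if (length(x$spines)) {
    cat("  spine sizes:",
        paste(utils::head(lengths(x$spines), 10), collapse = ", "),
        if (length(x$spines) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.spine_segmentation <- function(object, ...) {
  print(object)
  cat("  spine vertex fraction:",
      sprintf("%.3f", mean(object$labels == "spine")), "\n")
  invisible(object)
}

#' Export a segmentation to CSV
#'
#' Writes `vertex_index,label,component_id` with 0-based vertex indices;
#' component -1 is the shaft.
#' @param seg a `spine_segmentation`.
#' @param path output path.
#' @export
write_segmentation_csv <- function(seg, path) {
  utils::write.csv(data.frame(vertex_index = seq_len(seg$n_vertices) - 1L,
                              label = seg$labels,
                              component_id = seg$component),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a segmentation as a colored PLY for visual inspection
#' @param seg a `spine_segmentation`.
#' @param mesh the segmented `triangle_mesh`.
#' @param path output `.ply` path.
#' @export
write_segmentation_ply <- function(seg, mesh, path) {
  pal <- grDevices::hcl.colors(max(1L, length(seg$spines)), "Dark 3")
  cols <- matrix(120L, seg$n_vertices, 3)  # grey shaft
  for (i in seq_along(seg$spines)) {
    rgb <- grDevices::col2rgb(pal[(i - 1) %% length(pal) + 1])
    cols[seg$spines[[i]], ] <- matrix(as.integer(rgb),
                                      length(seg$spines[[i]]), 3,
                                      byrow = TRUE)
  }
  write_ply(mesh, path, binary = FALSE, colors = cols)
  invisible(path)
}
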