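#' Simplify a mesh by quadric edge collapse
#'
#' Garland-Heckbert quadric error simplification: edges are collapsed in
#' order of increasing quadric cost, skipping collapses that would break the
#' link condition, flip a face normal or create a degenerate face. Used to
#' bring very large dendritic reconstructions down to a tractable size
#' before segmentation.
#'
#' @param mesh a `triangle_mesh`.
#' @param target_vertex_count requested vertex count (>= 4). If the target
#'   is not below the current count the mesh is returned unchanged.
#' @return a simplified, validated `triangle_mesh`.
#' @export
decimate <- function(mesh, target_vertex_count) {
  if (target_vertex_count < 4) stop("target_vertex_count must be >= 4")
  n <- nrow(mesh$vertices)
  if (target_vertex_count >= n) return(mesh)
  res <- .cpp_decimate_qec(mesh$vertices, mesh$faces,
                           as.integer(target_vertex_count))
  out <- triangle_mesh(res$vertices, res$faces, validate = FALSE)
  repair_mesh(out)
}
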