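#' Read a triangle mesh from OBJ or PLY
#'
#' Supports ASCII OBJ (`v`/`f` records, 1-based indices, `f` entries may use
#' the `v/vt/vn` slash syntax) and PLY in both `ascii` and
#' `binary_little_endian` form. After parsing, the mesh goes through
#' [repair_mesh()]: duplicate vertices are fused, degenerate faces dropped
#' and orientation repaired.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, or `NULL` to infer from the extension.
#' @param repair run load-time repair (default `TRUE`).
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path, format = NULL, repair = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format, c("obj", "ply"))
  mesh <- switch(format, obj = read_obj(path), ply = read_ply(path))
  if (nrow(mesh$vertices) == 0L) stop("empty mesh: no vertices in ", path)
  if (nrow(mesh$faces) == 0L) stop("empty mesh: no faces in ", path)
  if (min(mesh$faces) < 1L || max(mesh$faces) > nrow(mesh$vertices))
    stop("face index out of range in ", path)
  if (repair) repair_mesh(mesh) else validate_mesh(mesh)
}

#' Write a triangle mesh to OBJ or PLY
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"obj"`, `"ply"`, or `NULL` to infer from the extension.
#' @param binary for PLY, write `binary_little_endian` instead of ASCII.
#' @param colors optional `n x 3` integer matrix of per-vertex RGB (0-255),
#'   PLY only.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE,
                       colors = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply"))
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, binary = binary, colors = colors))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("empty mesh: OBJ has no vertices")
  vparts <- strsplit(sub("^v\\s+", "", vl), "\\s+")
  v <- matrix(as.numeric(unlist(lapply(vparts, `[`, 1:3))),
              ncol = 3, byrow = TRUE)
  if (anyNA(v)) stop("OBJ parse failure: malformed vertex record")
  if (length(fl) == 0L) stop("empty mesh: OBJ has no faces")
  fparts <- strsplit(sub("^f\\s+", "", fl), "\\s+")
  if (any(lengths(fparts) != 3L))
    stop("only triangular faces are supported")
  # keep the vertex index before any '/'
  fidx <- vapply(unlist(fparts), function(s) {
    as.integer(strsplit(s, "/", fixed = TRUE)[[1]][1])
  }, integer(1))
  if (anyNA(fidx)) stop("OBJ parse failure: malformed face record")
  f <- matrix(fidx, ncol = 3, byrow = TRUE)
  f[f < 0] <- nrow(v) + f[f < 0] + 1L  # negative = relative indices
  triangle_mesh(v, f, validate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spineseg OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character(0)
  repeat {
    line <- read_ascii_line(con)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000) stop("PLY parse failure: runaway header")
  }
  if (!grepl("^ply", header[1])) stop("PLY parse failure: missing magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("PLY parse failure: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse element/property declarations
  elems <- list()
  cur <- NULL
  for (line in header) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) == 0) next
    if (toks[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]),
                  props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <- toks[-1]
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY parse failure: need vertex and face elements")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "double", n = n, size = sz, endian = "little")
    } else {
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    nv <- elems$vertex$count
    nf <- elems$face$count
    vprops <- vapply(elems$vertex$props, function(p) p[2], "")
    vtab <- strsplit(trimws(rest[seq_len(nv)]), "\\s+")
    vm <- matrix(as.numeric(unlist(vtab)), nrow = nv, byrow = TRUE)
    xyz <- match(c("x", "y", "z"), vprops)
    if (anyNA(xyz)) stop("PLY parse failure: vertex x/y/z not found")
    v <- vm[, xyz, drop = FALSE]
    ftab <- strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+")
    f <- t(vapply(ftab, function(tk) {
      cnt <- as.integer(tk[1])
      if (cnt != 3) stop("only triangular PLY faces are supported")
      as.integer(tk[2:4])
    }, integer(3)))
  } else {
    nv <- elems$vertex$count
    vprops <- elems$vertex$props
    ncolv <- length(vprops)
    types <- vapply(vprops, function(p) p[1], "")
    names_v <- vapply(vprops, function(p) p[2], "")
    if (length(unique(types)) == 1L) {
      vm <- matrix(read_scalar(types[1], nv * ncolv), nrow = nv,
                   byrow = TRUE)
    } else {
      vm <- matrix(0, nrow = nv, ncol = ncolv)
      for (i in seq_len(nv))
        for (j in seq_len(ncolv)) vm[i, j] <- read_scalar(types[j], 1)
    }
    xyz <- match(c("x", "y", "z"), names_v)
    if (anyNA(xyz)) stop("PLY parse failure: vertex x/y/z not found")
    v <- vm[, xyz, drop = FALSE]
    fp <- elems$face$props[[1]]
    if (fp[1] != "list") stop("PLY parse failure: face property not a list")
    cnt_type <- fp[2]
    idx_type <- fp[3]
    nf <- elems$face$count
    f <- matrix(0L, nrow = nf, ncol = 3)
    for (i in seq_len(nf)) {
      cnt <- read_scalar(cnt_type, 1)
      if (cnt != 3) stop("only triangular PLY faces are supported")
      f[i, ] <- read_scalar(idx_type, 3)
    }
  }
  triangle_mesh(v, f + 1L, validate = FALSE)  # PLY indices are 0-based
}

# read one LF-terminated ASCII line from a binary connection
read_ascii_line <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("PLY parse failure: unexpected end of file")
    if (b == as.raw(10)) break
    chars <- c(chars, b)
  }
  sub("\r$", "", rawToChar(chars))
}

write_ply <- function(mesh, path, binary = FALSE, colors = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_col <- !is.null(colors)
  header <- c(
    "ply",
    paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
    "comment spineseg PLY export",
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    if (has_col) {
      for (i in seq_len(nv)) {
        writeBin(as.double(mesh$vertices[i, ]), con, size = 8,
                 endian = "little")
        writeBin(as.raw(colors[i, ]), con)
      }
    } else {
      writeBin(as.double(t(mesh$vertices)), con, size = 8, endian = "little")
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (has_col) {
      writeLines(sprintf("%.9g %.9g %.9g %d %d %d",
                         mesh$vertices[, 1], mesh$vertices[, 2],
                         mesh$vertices[, 3], colors[, 1], colors[, 2],
                         colors[, 3]), con)
    } else {
      writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                         mesh$vertices[, 2], mesh$vertices[, 3]), con)
    }
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read per-vertex labels from CSV
#'
#' Expects a header `vertex_index,label` with 0-based vertex indices and
#' labels in `{spine, shaft}`.
#'
#' @param path CSV path.
#' @param n_vertices expected vertex count; indices must be in
#'   `[0, n_vertices)` and every vertex must be labeled.
#' @return character vector of labels, one per vertex.
#' @export
read_labels <- function(path, n_vertices) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "label") %in% names(d)))
    stop("label CSV must have columns vertex_index,label")
  if (any(d$vertex_index < 0 | d$vertex_index >= n_vertices))
    stop("vertex_index out of range [0, ", n_vertices, ")")
  if (!all(d$label %in% c("spine", "shaft")))
    stop("labels must be 'spine' or 'shaft'")
  out <- rep(NA_character_, n_vertices)
  out[d$vertex_index + 1L] <- d$label
  if (anyNA(out)) stop("label CSV does not cover every vertex")
  out
}

#' Write per-vertex labels to CSV (0-based indices)
#' @param labels character vector in `{spine, shaft}`.
#' @param path output CSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(labels) - 1L,
                              label = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-hot view of a label vector
#'
#' Column 1 is spine, column 2 is shaft: a spine vertex maps to (1, 0).
#' @param labels character vector in `{spine, shaft}`.
#' @return `n x 2` numeric matrix with columns `spine`, `shaft`.
#' @export
label_onehot <- function(labels) {
  if (!all(labels %in% c("spine", "shaft")))
    stop("labels must be 'spine' or 'shaft'")
  cbind(spine = as.numeric(labels == "spine"),
        shaft = as.numeric(labels == "shaft"))
}

#' Transfer labels by radius query
#'
#' Returns every target-mesh vertex lying within Euclidean distance `r_th`
#' of at least one source point (the KD-tree radius-query labeling used to
#' map separately stored spine meshes onto a wrapped dendrite mesh).
#'
#' @param source_points numeric matrix of 3D points.
#' @param target_mesh a `triangle_mesh`.
#' @param r_th radius threshold (um); `NULL` for the default 1.5 x median
#'   edge length of the target mesh.
#' @return sorted integer vector of target vertex indices (1-based),
#'   deduplicated; empty source set gives an empty result.
#' @export
map_labels_by_radius <- function(source_points, target_mesh, r_th = NULL) {
  if (is.null(r_th)) r_th <- 1.5 * median_edge_length(target_mesh)
  if (r_th <= 0) stop("r_th must be positive")
  if (is.null(source_points) || NROW(source_points) == 0L) return(integer(0))
  source_points <- matrix(as.numeric(source_points), ncol = 3)
  nn <- .cpp_min_dist_idx(target_mesh$vertices, source_points)
  sort(which(nn$dist <= r_th))
}

#' Median edge length of a mesh (um)
#' @param mesh a `triangle_mesh`.
#' @export
median_edge_length <- function(mesh) {
  et <- mesh_edge_table(mesh)
  v <- mesh$vertices
  stats::median(sqrt(rowSums((v[et$lo, , drop = FALSE] -
                              v[et$hi, , drop = FALSE])^2)))
}
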