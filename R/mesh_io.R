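#' Read and write triangle meshes (ASCII PLY / OBJ)
#'
#' Minimal readers/writers for the two interchange formats used by the
#' pipeline. PLY files are ASCII with `x y z` vertex properties and
#' triangular (or polygonal) faces.
#'
#' @param mesh a `triangle_mesh`.
#' @param path file path ending in `.ply` or `.obj`.
#' @return `path` invisibly (writers); a `triangle_mesh` (readers).
#' @export
write_triangle_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (grepl("\\.ply$", path)) {
    write_ply(mesh$vertices, lapply(seq_len(nrow(mesh$faces)),
                                    function(i) mesh$faces[i, ]), path)
  } else if (grepl("\\.obj$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  } else {
    stop("unsupported mesh format: ", path)
  }
  invisible(path)
}

#' @rdname write_triangle_mesh
#' @export
read_triangle_mesh <- function(path) {
  if (grepl("\\.ply$", path)) {
    p <- read_ply(path)
    if (any(lengths(p$faces) != 3L)) stop("PLY file contains non-triangular faces")
    triangle_mesh(p$vertices, do.call(rbind, p$faces))
  } else if (grepl("\\.obj$", path)) {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    triangle_mesh(verts, faces)
  } else {
    stop("unsupported mesh format: ", path)
  }
}

write_ply <- function(vertices, face_list, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", length(face_list)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  writeLines(vapply(face_list, function(f) {
    paste(c(length(f), f - 1L), collapse = " ")
  }, ""), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vl <- lines[end + seq_len(nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[1:3])))
  fl <- lines[end + nv + seq_len(nf)]
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    n <- as.integer(x[1])
    as.integer(x[1 + seq_len(n)]) + 1L
  })
  list(vertices = verts, faces = faces)
}

#' Read and write simplex meshes
#'
#' A simplex mesh is serialized as an ASCII PLY carrying the vertex
#' positions and polygonal dual faces, plus a JSON sidecar
#' (`<path>.neighbors.json`) holding the ordered per-vertex neighbor table
#' (1-based, schema `{"format": "ssmesh-neighbors-v1", "neighbors": [[i1,
#' i2, i3], ...]}`), which preserves the orientation convention.
#'
#' @param mesh a `simplex_mesh`.
#' @param path file path ending in `.ply`.
#' @return `path` invisibly (writer); a `simplex_mesh` (reader).
#' @export
write_simplex_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "simplex_mesh"), grepl("\\.ply$", path))
  faces <- mesh$faces %||% list()
  write_ply(mesh$vertices, faces, path)
  jsonlite::write_json(
    list(format = "ssmesh-neighbors-v1",
         neighbors = unname(split(mesh$neighbors, seq_len(nrow(mesh$neighbors))))),
    paste0(path, ".neighbors.json"), digits = NA)
  invisible(path)
}

#' @rdname write_simplex_mesh
#' @export
read_simplex_mesh <- function(path) {
  p <- read_ply(path)
  side <- jsonlite::read_json(paste0(path, ".neighbors.json"),
                              simplifyVector = TRUE)
  if (!identical(side$format, "ssmesh-neighbors-v1")) {
    stop("missing or invalid neighbor sidecar for ", path)
  }
  nb <- if (is.list(side$neighbors)) do.call(rbind, side$neighbors) else side$neighbors
  simplex_mesh(p$vertices, nb, faces = if (length(p$faces)) p$faces else NULL)
}
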