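#' Triangle surface meshes
#'
#' A `triangle_mesh` is a closed, orientable triangulated surface: an
#' `n x 3` matrix of vertex positions in millimetres and an `m x 3` integer
#' matrix of faces (1-based vertex indices, counter-clockwise when seen from
#' outside, so face normals point outward).
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm).
#' @param faces integer `m x 3` matrix of vertex indices (1-based).
#' @param validate check manifoldness and face sanity (default `TRUE`).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  if (ncol(faces) != 3L) stop("'faces' must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) assert_closed_manifold(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Undirected edge list of a triangle mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return Integer `e x 2` matrix, each row an undirected edge (`v1 < v2`),
#'   each edge listed once.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Stop unless every edge is shared by exactly two faces and faces are
# non-degenerate; reports an offending edge in the diagnostic.
assert_closed_manifold <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 4L) stop("mesh has fewer than 4 faces; not a closed surface")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("degenerate face (repeated vertex index) present")
  }
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- edge_key(e[, 1], e[, 2])
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad) > 0) {
    k <- as.numeric(bad[1])
    hi <- k %/% 2^26
    lo <- k - hi * 2^26
    stop(sprintf(
      "mesh is not a closed 2-manifold: edge (%d, %d) is shared by %d face(s), expected 2",
      lo, hi, cnt[bad[1]]))
  }
  # orientability: each undirected edge must appear once in each direction
  dkey <- e[, 1] + e[, 2] * 2^26
  if (anyDuplicated(dkey)) {
    stop("mesh is not consistently oriented: a directed edge appears twice")
  }
  areas <- triangle_areas(mesh)
  if (any(areas <= 0 | !is.finite(areas))) {
    stop("degenerate (zero-area) face present")
  }
  invisible(TRUE)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  0.5 * rownorms(cross3(b - a, c_ - a))
}

# Outward face normals (unit), from counter-clockwise winding.
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  normalize_rows(cross3(b - a, c_ - a))
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed meshes.
#'
#' @param mesh a `triangle_mesh`.
#' @return Scalar volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

#' Icosphere triangle mesh
#'
#' Subdivided icosahedron: the standard genus-0 test surface. Subdivision
#' level `k` gives `20 * 4^k` faces; vertices are projected to the sphere
#' after every subdivision.
#'
#' @param subdiv non-negative integer subdivision level.
#' @param radius sphere radius (mm).
#' @param center sphere centre (mm).
#' @return A `triangle_mesh` with outward orientation.
#' @export
icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(1 + phi^2)
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edges <- unique(rbind(
      cbind(pmin(faces[, 1], faces[, 2]), pmax(faces[, 1], faces[, 2])),
      cbind(pmin(faces[, 2], faces[, 3]), pmax(faces[, 2], faces[, 3])),
      cbind(pmin(faces[, 3], faces[, 1]), pmax(faces[, 3], faces[, 1]))))
    key <- edge_key(edges[, 1], edges[, 2])
    mid <- (verts[edges[, 1], , drop = FALSE] + verts[edges[, 2], , drop = FALSE]) / 2
    mid <- normalize_rows(mid)
    midx <- nrow(verts) + seq_len(nrow(edges))
    verts <- rbind(verts, mid)
    lut <- function(a, b) midx[match(edge_key(a, b), key)]
    m12 <- lut(faces[, 1], faces[, 2])
    m23 <- lut(faces[, 2], faces[, 3])
    m31 <- lut(faces[, 3], faces[, 1])
    faces <- rbind(
      cbind(faces[, 1], m12, m31),
      cbind(faces[, 2], m23, m12),
      cbind(faces[, 3], m31, m23),
      cbind(m12, m23, m31))
  }
  verts <- verts * radius
  verts <- sweep(verts, 2, as_point3(center, "center"), "+")
  triangle_mesh(verts, faces)
}
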