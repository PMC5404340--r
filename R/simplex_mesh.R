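#' 2-simplex surface meshes
#'
#' A 2-simplex mesh is a closed polygonal surface mesh in which every vertex
#' has exactly three distinct neighbors; it is the topological dual of a
#' triangle mesh. All deformation in this package is carried by simplex
#' meshes. The per-vertex neighbor triple is ordered so that the neighbor
#' triangle `(N1, N2, N3)` winds counter-clockwise when seen from outside:
#' its plane normal is the outward vertex normal and fixes the sign
#' convention of the simplex angle.
#'
#' @param vertices numeric `n x 3` matrix of vertex positions (mm).
#' @param neighbors integer `n x 3` matrix; row `i` holds the three neighbor
#'   indices of vertex `i`.
#' @param faces optional list of integer vectors: polygonal faces (used for
#'   rendering, dual-area and Euler-characteristic checks only).
#' @param validate check the exactly-3-neighbors and symmetry invariants.
#' @return An object of class `simplex_mesh`.
#' @export
simplex_mesh <- function(vertices, neighbors, faces = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  neighbors <- as.matrix(neighbors)
  storage.mode(neighbors) <- "integer"
  if (ncol(vertices) != 3L || ncol(neighbors) != 3L) {
    stop("'vertices' and 'neighbors' must have 3 columns")
  }
  if (nrow(vertices) != nrow(neighbors)) {
    stop("'vertices' and 'neighbors' must have the same number of rows")
  }
  mesh <- structure(list(vertices = vertices, neighbors = neighbors,
                         faces = faces),
                    class = "simplex_mesh")
  if (validate) assert_simplex_invariants(mesh)
  mesh
}

#' @export
print.simplex_mesh <- function(x, ...) {
  cat(sprintf("simplex_mesh: %d vertices (3 neighbors each), %d dual faces\n",
              nrow(x$vertices), length(x$faces %||% list())))
  invisible(x)
}

assert_simplex_invariants <- function(mesh) {
  nb <- mesh$neighbors
  n <- nrow(nb)
  if (any(nb < 1L) || any(nb > n)) stop("neighbor index out of range")
  if (any(nb[, 1] == nb[, 2] | nb[, 2] == nb[, 3] | nb[, 1] == nb[, 3])) {
    stop("a vertex has repeated neighbors")
  }
  rows <- rep(seq_len(n), 3L)
  cols <- as.vector(nb)
  # symmetry: i in neighbors(j) <=> j in neighbors(i)
  fwd <- rows + cols * 2^26
  rev <- cols + rows * 2^26
  if (!all(fwd %in% rev)) {
    stop("neighbor relation is not symmetric")
  }
  invisible(TRUE)
}

#' Number of undirected simplex edges
#' @param mesh a `simplex_mesh`.
#' @return Integer edge count (`3V/2` for a valid 2-simplex mesh).
#' @export
simplex_edge_count <- function(mesh) {
  nrow(unique(cbind(pmin(rep(seq_len(nrow(mesh$neighbors)), 3L),
                         as.vector(mesh$neighbors)),
                    pmax(rep(seq_len(nrow(mesh$neighbors)), 3L),
                         as.vector(mesh$neighbors)))))
}

#' Dual 2-simplex mesh of a triangle mesh
#'
#' One simplex vertex per triangle, placed at the triangle centroid; two
#' simplex vertices are neighbors iff their triangles share an edge. The
#' polygonal dual faces (one per primal vertex) are retained for Euler and
#' area computations. Neighbor ordering is fixed so the neighbor-triangle
#' normal points outward (inherited from the primal winding).
#'
#' @param tri a closed, oriented `triangle_mesh`.
#' @return A `simplex_mesh`.
#' @export
dual_simplex_from_triangles <- function(tri) {
  stopifnot(inherits(tri, "triangle_mesh"))
  assert_closed_manifold(tri)
  f <- tri$faces
  nf <- nrow(f)
  v <- tri$vertices
  centroids <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                  v[f[, 3], , drop = FALSE]) / 3
  # adjacency across shared edges, in primal edge order (1-2, 2-3, 3-1)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), 3L)
  key <- edge_key(e[, 1], e[, 2])
  ord <- order(key, fid)
  key_s <- key[ord]
  fid_s <- fid[ord]
  # edges come in pairs after sorting by key
  first <- seq(1L, length(key_s), by = 2L)
  if (any(key_s[first] != key_s[first + 1L])) {
    stop("internal error: unpaired edge in manifold mesh")
  }
  mate <- integer(length(key_s))
  mate[ord[first]] <- fid_s[first + 1L]
  mate[ord[first + 1L]] <- fid_s[first]
  neighbors <- matrix(mate, nrow = nf, ncol = 3L)  # column k: across edge k
  # orient neighbor triple so its winding gives an outward normal: compare to
  # the primal face normal and swap two neighbors where needed
  fn <- face_normals(tri)
  p1 <- centroids[neighbors[, 1], , drop = FALSE]
  p2 <- centroids[neighbors[, 2], , drop = FALSE]
  p3 <- centroids[neighbors[, 3], , drop = FALSE]
  nn <- cross3(p2 - p1, p3 - p1)
  flip <- rowSums(nn * fn) < 0
  if (any(flip)) {
    tmp <- neighbors[flip, 2]
    neighbors[flip, 2] <- neighbors[flip, 3]
    neighbors[flip, 3] <- tmp
  }
  faces <- dual_faces(tri)
  simplex_mesh(centroids, neighbors, faces = faces)
}

# Ordered polygonal dual faces: for each primal vertex, the ring of incident
# primal faces walked edge-to-edge.
dual_faces <- function(tri) {
  f <- tri$faces
  nf <- nrow(f)
  nv <- nrow(tri$vertices)
  inc <- split(rep(seq_len(nf), 3L), as.vector(f))
  # within face (a,b,c) and around vertex a, the next face CCW shares edge (a,b)
  out <- vector("list", nv)
  for (vi in seq_len(nv)) {
    fs <- inc[[as.character(vi)]]
    ring <- integer(length(fs))
    cur <- fs[1]
    for (s in seq_along(fs)) {
      ring[s] <- cur
      tri_v <- f[cur, ]
      pos <- which(tri_v == vi)
      nxt_v <- tri_v[c(2, 3, 1)[pos]]  # edge (vi, nxt_v) leads to next face
      cand <- fs[fs != cur]
      nxt <- cand[vapply(cand, function(ff) {
        tv <- f[ff, ]
        p <- which(tv == vi)
        tv[c(3, 1, 2)[p]] == nxt_v  # face containing directed edge (nxt_v, vi)
      }, logical(1))]
      if (length(nxt) != 1L) stop("non-manifold fan at vertex ", vi)
      cur <- nxt
    }
    out[[vi]] <- ring
  }
  out
}

# --- per-vertex geometry -----------------------------------------------------

# Circumcenter and radius of triangle (p1, p2, p3) given as 1 x 3 rows of
# matrices; fully vectorized over rows.
circumcircle3 <- function(p1, p2, p3) {
  a <- p2 - p1
  b <- p3 - p1
  axb <- cross3(a, b)
  d2 <- rowSums(axb * axb)           # |a x b|^2
  aa <- rowSums(a * a)
  bb <- rowSums(b * b)
  # C = p1 + (|a|^2 (b x (a x b)) + |b|^2 ((a x b) x a)) / (2 |a x b|^2)
  t1 <- cross3(b, axb) * aa
  t2 <- cross3(axb, a) * bb
  C <- p1 + (t1 + t2) / (2 * d2)
  r <- rownorms(C - p1)
  list(C = C, r = r, degenerate = d2 <= 0 | !is.finite(d2))
}

#' Vertex height from its simplex parameters
#'
#' Signed distance of a simplex vertex from its neighbor plane, as a function
#' of the neighbor circumcircle radius `r`, the projection offset
#' `d = ||F - C||` and the simplex angle `phi`. This is the classical closed
#' form `L = (r^2 - d^2) tan(phi) / (eps sqrt(r^2 + (r^2 - d^2) tan^2(phi)) +
#' r)` (with `eps = +1` for `|phi| < pi/2`, `-1` beyond), evaluated through
#' the equivalent sine/cosine rearrangement that stays finite and exact at
#' `|phi| = pi/2` and avoids cancellation on the outer branch.
#'
#' @param r circumcircle radius (mm), vectorized.
#' @param d tangent-plane offset `||F - C||` (mm), vectorized.
#' @param phi simplex angle in `[-pi, pi]`, vectorized.
#' @return Height(s) in mm; `0` where `sin(phi) == 0`.
#' @export
simplex_height <- function(r, d, phi) {
  s <- sin(phi)
  cphi <- cos(phi)
  n <- max(length(r), length(d), length(phi))
  r <- rep_len(r, n); d <- rep_len(d, n)
  s <- rep_len(s, n); cphi <- rep_len(cphi, n)
  out <- numeric(n)
  nz <- abs(s) > 1e-14
  if (any(nz)) {
    rr <- r[nz]; dd <- d[nz]; ss <- s[nz]; cc <- cphi[nz]
    rad <- sqrt(pmax(rr^2 * cc^2 + (rr^2 - dd^2) * ss^2, 0))
    y <- numeric(sum(nz))
    pos <- cc >= 0
    # cos >= 0: denominator rad + r cos never cancels
    y[pos] <- (rr[pos]^2 - dd[pos]^2) * ss[pos] / (rad[pos] + rr[pos] * cc[pos])
    # cos < 0 (outer branch): rationalized twin avoids rad - r|cos| cancellation
    y[!pos] <- (rad[!pos] - rr[!pos] * cc[!pos]) / ss[!pos]
    out[nz] <- y
  }
  out
}

#' Local geometry of a simplex-mesh vertex
#'
#' Computes the full set of per-vertex quantities of simplex-mesh geometry:
#' metric (barycentric) parameters of the tangent-plane projection, the
#' circumscribed circle of the neighbor triangle, the circumscribed sphere of
#' the vertex tetrahedron, the signed simplex angle, the height over the
#' tangent plane and the mean curvature `H = sin(phi) / r`.
#'
#' @param mesh a `simplex_mesh`.
#' @param i vertex index (scalar).
#' @return A list of class `vertex_geometry` with fields `eps` (length-3,
#'   sums to 1), `F` (projection point, mm), `n` (unit tangent-plane normal),
#'   `C`, `r` (circumcircle, mm), `O`, `R` (circumsphere, mm), `d` (mm),
#'   `phi` (radians, in `[-pi, pi]`), `L` (height, mm) and `H` (1/mm).
#' @export
vertex_geometry <- function(mesh, i) {
  stopifnot(inherits(mesh, "simplex_mesh"), length(i) == 1L)
  nb <- mesh$neighbors[i, ]
  P <- mesh$vertices[i, ]
  p1 <- mesh$vertices[nb[1], , drop = FALSE]
  p2 <- mesh$vertices[nb[2], , drop = FALSE]
  p3 <- mesh$vertices[nb[3], , drop = FALSE]
  cc <- circumcircle3(p1, p2, p3)
  if (cc$degenerate) {
    stop(sprintf("degenerate geometry at vertex %d: neighbors are collinear", i))
  }
  nrm <- normalize_rows(cross3(p2 - p1, p3 - p1))
  y <- sum((P - cc$C[1, ]) * nrm[1, ])
  Fp <- P - y * nrm[1, ]
  d <- vnorm(Fp - cc$C[1, ])
  r <- cc$r[1]
  # barycentric coordinates of F by signed sub-areas against the plane normal
  denom <- sum(cross3(p2 - p1, p3 - p1)[1, ] * nrm[1, ])
  e1 <- sum(cross3(p2 - rbind(Fp), p3 - rbind(Fp))[1, ] * nrm[1, ]) / denom
  e2 <- sum(cross3(p3 - rbind(Fp), p1 - rbind(Fp))[1, ] * nrm[1, ]) / denom
  e3 <- sum(cross3(p1 - rbind(Fp), p2 - rbind(Fp))[1, ] * nrm[1, ]) / denom
  if (abs(y) > 1e-14) {
    z <- (d^2 + y^2 - r^2) / (2 * y)
    O <- cc$C[1, ] + z * nrm[1, ]
    Rs <- sqrt(r^2 + z^2)
    # sign convention: the angle is continuous through flat configurations
    # (shallow vertices have |phi| < pi/2 with the sign of the height)
    phi <- sign(y) * atan2(r, -z * sign(y))
  } else {
    # coplanar tetrahedron: phi = 0 by convention
    z <- NA_real_
    O <- cc$C[1, ]
    Rs <- Inf
    phi <- 0
  }
  structure(list(
    eps = unname(c(e1, e2, e3)), F = unname(Fp), n = unname(nrm[1, ]),
    C = unname(cc$C[1, ]), r = unname(r), O = unname(O), R = unname(Rs),
    d = unname(d), phi = unname(phi),
    # the signed height; equals simplex_height(r, d, phi) wherever the
    # closed form is single-valued (d < r)
    L = unname(y), H = unname(sin(phi) / r),
    neighbors = nb), class = "vertex_geometry")
}

#' Reconstruct a vertex position from its simplex parameters
#'
#' Inverse of [vertex_geometry()]: the vertex position is determined by its
#' metric parameters, its height `L` and its three neighbors. In every
#' regular configuration (tangent-plane projection inside the neighbor
#' circumcircle, `d < r`) the stored height equals the closed form
#' [simplex_height()] evaluated at the simplex angle; in the rare `d > r`
#' configurations the angle parametrization is two-valued and only the
#' stored height identifies the vertex, so it is used directly.
#'
#' @param geom a `vertex_geometry`.
#' @param neighbors `3 x 3` matrix, one neighbor position per row (mm).
#' @return Numeric length-3 position (mm).
#' @export
reconstruct_position <- function(geom, neighbors) {
  stopifnot(inherits(geom, "vertex_geometry"))
  neighbors <- as.matrix(neighbors)
  stopifnot(nrow(neighbors) == 3L, ncol(neighbors) == 3L)
  p1 <- neighbors[1, , drop = FALSE]
  p2 <- neighbors[2, , drop = FALSE]
  p3 <- neighbors[3, , drop = FALSE]
  nrm <- normalize_rows(cross3(p2 - p1, p3 - p1))[1, ]
  cc <- circumcircle3(p1, p2, p3)
  L <- if (geom$d < cc$r[1]) {
    simplex_height(cc$r[1], geom$d, geom$phi)
  } else {
    geom$L
  }
  geom$eps[1] * p1[1, ] + geom$eps[2] * p2[1, ] + geom$eps[3] * p3[1, ] +
    L * nrm
}

#' Outward vertex normals of a simplex mesh
#'
#' Unit normals of each vertex's neighbor plane, oriented by the stored
#' neighbor winding (outward for meshes built by
#' [dual_simplex_from_triangles()]).
#'
#' @param mesh a `simplex_mesh`.
#' @return `n x 3` matrix of unit normals.
#' @export
simplex_normals <- function(mesh) {
  v <- mesh$vertices
  nb <- mesh$neighbors
  p1 <- v[nb[, 1], , drop = FALSE]
  p2 <- v[nb[, 2], , drop = FALSE]
  p3 <- v[nb[, 3], , drop = FALSE]
  normalize_rows(cross3(p2 - p1, p3 - p1))
}

#' Simplex angles of all vertices
#'
#' Vectorized signed simplex angle per vertex (`0` for coplanar
#' configurations).
#'
#' @param mesh a `simplex_mesh`.
#' @return Numeric vector of angles in `[-pi, pi]`.
#' @export
simplex_angles <- function(mesh) {
  v <- mesh$vertices
  nb <- mesh$neighbors
  p1 <- v[nb[, 1], , drop = FALSE]
  p2 <- v[nb[, 2], , drop = FALSE]
  p3 <- v[nb[, 3], , drop = FALSE]
  cc <- circumcircle3(p1, p2, p3)
  nrm <- normalize_rows(cross3(p2 - p1, p3 - p1))
  y <- rowSums((v - cc$C) * nrm)
  Fp <- v - y * nrm
  d <- rownorms(Fp - cc$C)
  phi <- numeric(nrow(v))
  nz <- abs(y) > 1e-14
  z <- (d[nz]^2 + y[nz]^2 - cc$r[nz]^2) / (2 * y[nz])
  sg <- sign(y[nz])
  phi[nz] <- sg * atan2(cc$r[nz], -z * sg)
  phi
}
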