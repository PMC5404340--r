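#' Isosurface extraction from a binary volume
#'
#' Extracts the closed triangle mesh of the `level` isosurface of a binary
#' volume, in world coordinates (spacing and origin applied). The
#' implementation marches a consistent 6-tetrahedra (Kuhn) decomposition of
#' every voxel cell, which yields a watertight, consistently outward-oriented
#' 2-manifold for any binary input; surface vertices are linearly
#' interpolated along cell edges. The volume is padded internally by one
#' background voxel so the surface is always closed.
#'
#' @param vol a [label_volume()].
#' @param level iso-level, strictly between the background and foreground
#'   values (default `0.5`).
#' @return A `triangle_mesh` with vertices in mm.
#' @export
extract_surface <- function(vol, level = 0.5) {
  stopifnot(inherits(vol, "label_volume"))
  d <- vol$data
  if (sum(d) == 0) stop("empty foreground: volume contains no object voxel")
  dims0 <- dim(d)
  if (any(d[1, , ] > level) || any(d[dims0[1], , ] > level) ||
      any(d[, 1, ] > level) || any(d[, dims0[2], ] > level) ||
      any(d[, , 1] > level) || any(d[, , dims0[3]] > level)) {
    stop("foreground touches the volume border; pad the volume with background first")
  }
  dp <- array(0, dims0 + 2L)
  dp[2:(dims0[1] + 1), 2:(dims0[2] + 1), 2:(dims0[3] + 1)] <- d
  origin <- vol$origin - vol$spacing
  march_tetrahedra(dp, level, vol$spacing, origin)
}

# Cube corner offsets, fixed labelling 1..8.
mt_corner_offsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# Kuhn decomposition of the unit cube into 6 tetrahedra around the main
# diagonal (corners 1 and 7); shared faces match across neighboring cells.
mt_tets <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

perm4_even <- function(p) {
  inv <- 0L
  for (a in 1:3) for (b in (a + 1):4) if (p[a] > p[b]) inv <- inv + 1L
  inv %% 2L == 0L
}

# Triangulation of one tetrahedron case: local tet vertices 1..4, `inside`
# a logical 4-vector (value > level). Returns a list of triangles, each a
# 3 x 2 matrix of local tet-vertex pairs (the cut edges), wound so the
# normal points away from the inside region for a positively oriented tet.
mt_case_triangles <- function(inside) {
  n_in <- sum(inside)
  if (n_in == 0L || n_in == 4L) return(list())
  even_arrange <- function(a, rest) {
    p <- c(a, rest)
    if (!perm4_even(p)) p[3:4] <- p[4:3]
    p
  }
  if (n_in == 1L) {
    p <- even_arrange(which(inside), which(!inside))
    a <- p[1]; b <- p[2]; c_ <- p[3]; d <- p[4]
    list(rbind(c(a, b), c(a, c_), c(a, d)))
  } else if (n_in == 3L) {
    p <- even_arrange(which(!inside), which(inside))
    a <- p[1]; b <- p[2]; c_ <- p[3]; d <- p[4]
    list(rbind(c(a, b), c(a, d), c(a, c_)))
  } else {
    ins <- which(inside); outs <- which(!inside)
    p <- c(ins, outs)
    if (!perm4_even(p)) p[3:4] <- p[4:3]
    a <- p[1]; b <- p[2]; c_ <- p[3]; d <- p[4]
    list(rbind(c(a, c_), c(a, d), c(b, d)),
         rbind(c(a, c_), c(b, d), c(b, c_)))
  }
}

# Precomputed case table: tables[[tet]][[mask + 1]] is a list of triangles,
# each a 3 x 2 matrix of CUBE corner labels (1..8). Tet orientation in index
# space is normalized to positive at build time.
mt_case_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    out <- vector("list", nrow(mt_tets))
    for (t in seq_len(nrow(mt_tets))) {
      tet <- mt_tets[t, ]
      m <- mt_corner_offsets[tet, ]
      if (det(rbind(m[2, ] - m[1, ], m[3, ] - m[1, ], m[4, ] - m[1, ])) < 0) {
        tet <- tet[c(1, 2, 4, 3)]
      }
      cases <- vector("list", 16L)
      for (mask in 0:15) {
        inside <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
        tris <- mt_case_triangles(inside)
        cases[[mask + 1L]] <- lapply(tris, function(tr) {
          matrix(tet[tr], nrow = 3L)
        })
      }
      out[[t]] <- cases
    }
    tbl <<- out
    tbl
  }
})

march_tetrahedra <- function(dp, level, spacing, origin) {
  n <- dim(dp)
  nc <- n - 1L
  # corner linear indices (1-based) and values for candidate cells
  base <- array(seq_len(prod(n)), n)
  lin0 <- as.vector(base[seq_len(nc[1]), seq_len(nc[2]), seq_len(nc[3])])
  stride <- c(1L, n[1], n[1] * n[2])
  corner_off <- as.integer(mt_corner_offsets %*% stride)
  vals1 <- dp[lin0]
  vmin <- vals1; vmax <- vals1
  for (k in 2:8) {
    vk <- dp[lin0 + corner_off[k]]
    vmin <- pmin(vmin, vk); vmax <- pmax(vmax, vk)
  }
  active <- which(vmin <= level & vmax > level)
  if (length(active) == 0L) stop("no surface crossing found at this level")
  lin <- lin0[active]
  cidx <- outer(lin, corner_off, "+")       # ncell x 8 global voxel indices
  cval <- matrix(dp[cidx], ncol = 8L)
  ins <- cval > level
  tbl <- mt_case_table()

  tri_a <- vector("list", 0); tri_b <- vector("list", 0)
  for (t in seq_len(nrow(mt_tets))) {
    tet <- mt_tets[t, ]
    mask <- ins[, tet[1]] + 2L * ins[, tet[2]] + 4L * ins[, tet[3]] +
      8L * ins[, tet[4]]
    for (m in 1:14) {
      sel <- which(mask == m)
      if (length(sel) == 0L) next
      for (tr in tbl[[t]][[m + 1L]]) {
        # tr: 3 x 2 cube-corner labels; emit one triangle row per cell
        tri_a[[length(tri_a) + 1L]] <-
          cbind(cidx[sel, tr[1, 1]], cidx[sel, tr[2, 1]], cidx[sel, tr[3, 1]])
        tri_b[[length(tri_b) + 1L]] <-
          cbind(cidx[sel, tr[1, 2]], cidx[sel, tr[2, 2]], cidx[sel, tr[3, 2]])
      }
    }
  }
  A <- do.call(rbind, tri_a)   # ntri x 3 global voxel id (edge endpoint 1)
  B <- do.call(rbind, tri_b)   # ntri x 3 global voxel id (edge endpoint 2)
  # canonical undirected-edge keys as complex pairs: exact for any volume a
  # double can index (packed integer keys would overflow 2^53 on CT-scale
  # grids)
  keys <- complex(real = pmin(as.vector(A), as.vector(B)),
                  imaginary = pmax(as.vector(A), as.vector(B)))
  uk <- unique(keys)
  vid <- match(keys, uk)
  faces <- matrix(vid, ncol = 3L)
  # one interpolated vertex per unique cut edge
  firsts <- which(!duplicated(keys))
  ga <- as.vector(A)[firsts]; gb <- as.vector(B)[firsts]
  va <- dp[ga]; vb <- dp[gb]
  tt <- (level - va) / (vb - va)
  pa <- voxel_world(ga, n, spacing, origin)
  pb <- voxel_world(gb, n, spacing, origin)
  verts <- pa + tt * (pb - pa)
  triangle_mesh(verts, faces)
}

# World coordinates of voxel centres from 1-based linear indices.
voxel_world <- function(lin, dims, spacing, origin) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(origin[1] + i * spacing[1],
        origin[2] + j * spacing[2],
        origin[3] + k * spacing[3])
}

#' Low-pass (Taubin) mesh smoothing
#'
#' Alternating lambda/mu uniform-Laplacian steps: a low-pass filter on mesh
#' geometry that smooths without the volume shrinkage of plain Laplacian
#' smoothing. Topology is unchanged.
#'
#' @param tri a `triangle_mesh`.
#' @param iterations number of lambda+mu passes (0 returns the input).
#' @param passband filter pass-band `k_pb` in (0, 2); smaller is smoother.
#' @param lambda positive shrink step (< 1).
#' @return The smoothed `triangle_mesh`.
#' @export
smooth_mesh <- function(tri, iterations = 20, passband = 0.1, lambda = 0.5) {
  stopifnot(inherits(tri, "triangle_mesh"), iterations >= 0)
  if (iterations == 0) return(tri)
  mu <- 1 / (passband - 1 / lambda)
  stopifnot(mu < 0)
  e <- mesh_edges(tri)
  n <- nrow(tri$vertices)
  ii <- c(e[, 1], e[, 2])
  jj <- c(e[, 2], e[, 1])
  deg <- tabulate(ii, nbins = n)
  v <- tri$vertices
  avg <- function(v) {
    s <- cbind(
      rowsum(v[jj, 1], ii, reorder = TRUE),
      rowsum(v[jj, 2], ii, reorder = TRUE),
      rowsum(v[jj, 3], ii, reorder = TRUE))
    s / deg
  }
  for (it in seq_len(iterations)) {
    v <- v + lambda * (avg(v) - v)
    v <- v + mu * (avg(v) - v)
  }
  triangle_mesh(v, tri$faces, validate = FALSE)
}

#' Edge-collapse mesh decimation
#'
#' Reduces the face count of a closed manifold triangle mesh to approximately
#' `target_faces` by repeated shortest-edge collapses (collapse to the edge
#' midpoint), restricted by the manifold link condition so the result remains
#' a closed 2-manifold. Greedy independent collapses are applied in sorted
#' passes.
#'
#' @param tri a closed manifold `triangle_mesh`.
#' @param target_faces requested face count (`>= 4`).
#' @return A decimated `triangle_mesh` with face count within a few faces of
#'   the target (collapses remove two faces at a time).
#' @export
decimate_mesh <- function(tri, target_faces) {
  stopifnot(inherits(tri, "triangle_mesh"))
  if (target_faces < 4) stop("'target_faces' must be at least 4")
  assert_closed_manifold(tri)
  mesh <- tri
  repeat {
    excess <- nrow(mesh$faces) - target_faces
    if (excess < 2L) break
    res <- decimate_pass(mesh, excess %/% 2L)
    if (!res$changed) break
    mesh <- res$mesh
  }
  mesh
}

decimate_pass <- function(mesh, max_collapses) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  e <- mesh_edges(mesh)
  len <- rownorms(v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])
  ord <- order(len)
  # every vertex of a closed manifold has degree >= 3, so positions 1..n of
  # the split are exactly the vertex ids
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  nbr <- function(i) adj[[i]]
  touched <- logical(n)
  mapto <- seq_len(n)
  newpos <- v
  done <- 0L
  for (ei in ord) {
    if (done >= max_collapses) break
    a <- e[ei, 1]; b <- e[ei, 2]
    if (touched[a] || touched[b]) next
    na <- nbr(a); nb <- nbr(b)
    common <- intersect(na, nb)
    if (length(common) != 2L) next              # link condition
    if (length(union(na, nb)) <= 4L) next       # would pinch a tetrahedron
    mapto[b] <- a
    newpos[a, ] <- (v[a, ] + v[b, ]) / 2
    touched[c(a, b, na, nb)] <- TRUE
    done <- done + 1L
  }
  if (done == 0L) return(list(changed = FALSE, mesh = mesh))
  f2 <- matrix(mapto[f], ncol = 3L)
  keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  f2 <- f2[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  remap <- integer(n)
  remap[used] <- seq_along(used)
  out <- triangle_mesh(newpos[used, , drop = FALSE],
                       matrix(remap[f2], ncol = 3L), validate = FALSE)
  ok <- tryCatch({ assert_closed_manifold(out); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(list(changed = FALSE, mesh = mesh))
  list(changed = TRUE, mesh = out)
}
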