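test_that("dual of a tetrahedron is the self-dual 4-vertex simplex mesh", {
  sm <- dual_simplex_from_triangles(tetra_mesh())
  expect_equal(nrow(sm$vertices), 4L)
  expect_true(all(apply(sm$neighbors, 1, function(x) length(unique(x))) == 3L))
  expect_equal(simplex_edge_count(sm), 6L)
})

test_that("dual of the icosahedron has 20 vertices, 30 edges, 12 pentagons", {
  sm <- dual_simplex_from_triangles(icosphere(0))
  expect_equal(nrow(sm$vertices), 20L)
  expect_equal(simplex_edge_count(sm), 30L)
  expect_equal(length(sm$faces), 12L)
  expect_true(all(lengths(sm$faces) == 5L))
  # Euler characteristic of the genus-0 dual
  expect_equal(nrow(sm$vertices) - simplex_edge_count(sm) + length(sm$faces), 2L)
})

test_that("dual of a subdivided sphere satisfies all structural invariants", {
  tri <- icosphere(2)  # 320 faces
  sm <- dual_simplex_from_triangles(tri)
  expect_equal(nrow(sm$vertices), 320L)
  expect_silent(ssmesh:::assert_simplex_invariants(sm))
  expect_equal(nrow(sm$vertices) - simplex_edge_count(sm) + length(sm$faces), 2L)
  # dual vertices lie within one primal edge length of the unit sphere
  e <- mesh_edges(tri)
  elen <- max(sqrt(rowSums((tri$vertices[e[, 1], ] - tri$vertices[e[, 2], ])^2)))
  expect_lt(max(abs(sqrt(rowSums(sm$vertices^2)) - 1)), elen)
  # normals point outward
  nrm <- simplex_normals(sm)
  u <- sm$vertices / sqrt(rowSums(sm$vertices^2))
  expect_true(all(rowSums(nrm * u) > 0.9))
})

test_that("open or non-manifold input is rejected with the offending edge", {
  tri <- icosphere(0)
  open_mesh <- triangle_mesh(tri$vertices, tri$faces[-1, , drop = FALSE],
                             validate = FALSE)
  expect_error(dual_simplex_from_triangles(open_mesh), "edge \\(")
  expect_error(triangle_mesh(tri$vertices, tri$faces[-1, , drop = FALSE]),
               "shared by 1 face")
})

test_that("vertex in the plane of an equilateral neighbor triangle is flat", {
  # neighbors on the unit circle, vertex at the centroid (in plane)
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  nbrs <- cbind(cos(ang), sin(ang), 0)
  verts <- rbind(c(0, 0, 0), nbrs)
  nb <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  sm <- simplex_mesh(verts, nb, validate = FALSE)
  g <- vertex_geometry(sm, 1)
  expect_equal(g$eps, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(g$phi, 0)
  expect_equal(g$L, 0)
  expect_equal(g$H, 0)
  p <- reconstruct_position(g, nbrs)
  expect_lt(max(abs(p)), 1e-12)
})

test_that("vertex geometry matches an explicit circumcircle/sphere solve", {
  nbrs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  P <- c(1, 1, 1) / sqrt(3)
  sm <- simplex_mesh(rbind(P, nbrs),
                     rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3)),
                     validate = FALSE)
  g <- vertex_geometry(sm, 1)
  cc <- oracle_circumcircle(nbrs[1, ], nbrs[2, ], nbrs[3, ])
  sp <- oracle_circumsphere(P, nbrs[1, ], nbrs[2, ], nbrs[3, ])
  expect_equal(g$C, cc$C, tolerance = 1e-12)
  expect_equal(g$r, cc$r, tolerance = 1e-12)
  expect_equal(g$O, sp$O, tolerance = 1e-10)
  expect_equal(g$R, sp$R, tolerance = 1e-10)
  expect_equal(g$phi, oracle_simplex_angle(P, nbrs[1, ], nbrs[2, ], nbrs[3, ]),
               tolerance = 1e-12)
  expect_equal(g$L, oracle_height(g$r, g$d, g$phi), tolerance = 1e-12)
  expect_equal(sum(g$eps), 1, tolerance = 1e-12)
  expect_equal(reconstruct_position(g, nbrs), P, tolerance = 1e-9)
})

test_that("stable height expression equals the printed closed form", {
  set.seed(11)
  for (rep in 1:200) {
    r <- runif(1, 0.5, 3)
    d <- runif(1, 0, r * 0.95)
    phi <- runif(1, -pi + 0.01, pi - 0.01)
    expect_equal(simplex_height(r, d, phi), oracle_height(r, d, phi),
                 tolerance = 1e-10)
  }
  # finite and exact through the tan singularity
  expect_equal(simplex_height(2, 1, pi / 2), sqrt(3), tolerance = 1e-12)
  expect_equal(simplex_height(2, 1, -pi / 2), -sqrt(3), tolerance = 1e-12)
})

test_that("mean curvature recovers 1/rho on spherical simplex meshes", {
  rho <- 7
  sm <- dual_simplex_from_triangles(icosphere(3, radius = rho))
  # inscribed in the sphere, every circumsphere IS the sphere: H exact
  on_sphere <- sm
  on_sphere$vertices <- sm$vertices /
    sqrt(rowSums(sm$vertices^2)) * rho
  H <- vapply(seq_len(nrow(sm$vertices)),
              function(i) vertex_geometry(on_sphere, i)$H, 0)
  expect_equal(H, rep(1 / rho, length(H)), tolerance = 1e-9)
  # centroid-placed dual vertices are slightly off-sphere: the per-vertex
  # estimate scatters but its mean is unbiased
  Hc <- vapply(seq_len(nrow(sm$vertices)),
               function(i) vertex_geometry(sm, i)$H, 0)
  expect_lt(abs(mean(Hc) * rho - 1), 0.05)
})

test_that("geometry round-trips on random perturbed meshes", {
  sm <- perturbed_sphere_simplex()
  err <- vapply(seq_len(nrow(sm$vertices)), function(i) {
    g <- vertex_geometry(sm, i)
    expect_equal(sum(g$eps), 1, tolerance = 1e-12)
    max(abs(reconstruct_position(g, sm$vertices[g$neighbors, ]) -
              sm$vertices[i, ]))
  }, 0)
  expect_lt(max(err), 1e-6)
})

test_that("orientation flip flips phi and L but preserves the round trip", {
  sm <- perturbed_sphere_simplex()
  i <- 17
  g <- vertex_geometry(sm, i)
  flipped <- sm
  flipped$neighbors[i, ] <- sm$neighbors[i, c(1, 3, 2)]
  gf <- vertex_geometry(flipped, i)
  expect_equal(gf$phi, -g$phi, tolerance = 1e-12)
  expect_equal(gf$L, -g$L, tolerance = 1e-12)
  expect_equal(gf$n, -g$n, tolerance = 1e-12)
  expect_equal(reconstruct_position(gf, flipped$vertices[gf$neighbors, ]),
               sm$vertices[i, ], tolerance = 1e-9)
})

test_that("degenerate (collinear) neighbors are reported", {
  verts <- rbind(c(0, 0, 1), c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  nb <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  sm <- simplex_mesh(verts, nb, validate = FALSE)
  expect_error(vertex_geometry(sm, 1), "collinear")
})
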