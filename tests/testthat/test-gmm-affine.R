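test_that("mesh_to_gmm builds uniform-weight isotropic mixtures", {
  sm <- dual_simplex_from_triangles(tetra_mesh())
  g <- mesh_to_gmm(sm, scale = 1)
  expect_equal(nrow(g$means), 4L)
  expect_equal(g$weights, rep(0.25, 4))
  expect_equal(sum(g$weights), 1)
  expect_error(mesh_to_gmm(sm, scale = 0), "> 0")
  expect_error(mesh_to_gmm(sm, scale = -1), "> 0")
  # default scale is the mean edge length
  expect_equal(mesh_to_gmm(sm)$scale, ssmesh:::mean_edge_length(sm))
  # deterministic stride subsampling caps component count
  big <- dual_simplex_from_triangles(icosphere(2))
  expect_lte(nrow(mesh_to_gmm(big, scale = 1, max_components = 100)$means), 100)
})

test_that("identical mixtures at identity have zero L2 distance", {
  sm <- perturbed_sphere_simplex(subdiv = 0)
  f <- mesh_to_gmm(sm, scale = 1.5)
  obj <- l2_objective(f, f, affine_transform())
  int_g2 <- ssmesh:::gmm_cross_integral(f$means, f$weights, f$means,
                                        f$weights, 2 * f$scale^2)
  expect_equal(obj + int_g2, 0, tolerance = 1e-12)
})

test_that("single-component cross term matches the Gaussian product integral", {
  f <- structure(list(means = matrix(0, 1, 3), weights = 1, scale = 1),
                 class = "gmm_shape")
  val <- ssmesh:::gmm_cross_integral(f$means, 1, f$means, 1, 2)
  expect_equal(val, (4 * pi)^-1.5, tolerance = 1e-12)
})

test_that("closed-form objective matches 3-D numerical quadrature", {
  set.seed(3)
  for (rep in 1:3) {
    f <- structure(list(means = matrix(rnorm(9, 0, 2), 3),
                        weights = c(0.5, 0.3, 0.2), scale = runif(1, 0.8, 1.5)),
                   class = "gmm_shape")
    g <- structure(list(means = matrix(rnorm(15, 1, 2), 5),
                        weights = rep(0.2, 5), scale = runif(1, 0.8, 1.5)),
                   class = "gmm_shape")
    T <- affine_transform(
      Q = ssmesh:::rotvec_to_Q(rnorm(3, 0, 0.3)),
      S = ssmesh:::theta_to_S(c(rnorm(3, 0, 0.1), rnorm(3, 0, 0.1))),
      t = rnorm(3))
    cf <- l2_objective(f, g, T)
    nq <- oracle_l2_quadrature(f, g, T, h = 0.4)
    expect_equal(cf, nq, tolerance = 1e-6)
  }
})

test_that("objective is invariant under a common rigid motion", {
  sm <- perturbed_sphere_simplex(subdiv = 0)
  f <- mesh_to_gmm(sm, scale = 1)
  sm2 <- perturbed_sphere_simplex(subdiv = 0, seed = 7)
  g <- mesh_to_gmm(sm2, scale = 1)
  T <- affine_transform(t = c(1, 2, 3))
  base <- l2_objective(f, g, T)
  R <- ssmesh:::rotvec_to_Q(c(0.4, -0.2, 0.6))
  shift <- c(-2, 5, 1)
  fr <- f; fr$means <- sweep(f$means %*% t(R), 2, shift, "+")
  gr <- g; gr$means <- sweep(g$means %*% t(R), 2, shift, "+")
  # conjugate the transform by the common motion
  A2 <- R %*% T$A %*% t(R)
  t2 <- as.vector(shift + R %*% T$t - A2 %*% shift)
  T2 <- ssmesh:::affine_from_A(A2, t2)
  expect_equal(l2_objective(fr, gr, T2), base, tolerance = 1e-10)
})

test_that("registration recovers identity for identical shapes", {
  sm <- perturbed_sphere_simplex(subdiv = 1, radius = 10)
  f <- mesh_to_gmm(sm, scale = 2)
  reg <- register_affine(f, f)
  expect_lt(norm(reg$transform$A - diag(3), "F"), 1e-3)
  expect_lt(sqrt(sum(reg$transform$t^2)), 1e-3)
  expect_lte(reg$objective, reg$initial_objective)
})

test_that("registration recovers a known affine map on noiseless points", {
  sm <- perturbed_sphere_simplex(subdiv = 1, radius = 10)
  Astar <- ssmesh:::rotvec_to_Q(c(0.3, -0.15, 0.2)) %*%
    diag(c(1.25, 1.0, 0.85))          # condition number 1.47
  tstar <- c(4, -2, 3)
  target <- sm
  target$vertices <- sweep(sm$vertices %*% t(Astar), 2, tstar, "+")
  f <- mesh_to_gmm(sm, scale = 2)
  g <- mesh_to_gmm(target, scale = 2)
  reg <- register_affine(f, g)
  expect_lt(norm(reg$transform$A - Astar, "F") / norm(Astar, "F"), 1e-2)
  expect_lt(sqrt(sum((reg$transform$t - tstar)^2)) / sqrt(sum(tstar^2)), 1e-2)
})

test_that("registration tolerates vertex jitter", {
  sm <- dual_simplex_from_triangles(icosphere(1, radius = 10))
  Astar <- diag(c(1.1, 0.95, 1.05))
  tstar <- c(2, 1, -3)
  target <- sm
  set.seed(9)
  target$vertices <- sweep(sm$vertices %*% t(Astar), 2, tstar, "+") +
    matrix(rnorm(length(sm$vertices), 0, 0.5), ncol = 3)
  reg <- register_affine(mesh_to_gmm(sm, scale = 2),
                         mesh_to_gmm(target, scale = 2))
  fitted <- apply_affine(sm, reg$transform)
  resid <- sqrt(rowSums((fitted$vertices - target$vertices)^2))
  expect_lt(mean(resid), 1)
})

test_that("apply_affine maps vertices and composes correctly", {
  sm <- dual_simplex_from_triangles(tetra_mesh())
  expect_equal(apply_affine(sm, affine_transform()), sm)
  tr <- affine_transform(t = c(1, 2, 3))
  shifted <- apply_affine(sm, tr)
  expect_equal(shifted$vertices, sweep(sm$vertices, 2, c(1, 2, 3), "+"))
  expect_identical(shifted$neighbors, sm$neighbors)
  T1 <- affine_transform(Q = ssmesh:::rotvec_to_Q(c(0.1, 0.2, -0.3)),
                         S = ssmesh:::theta_to_S(c(0.05, -0.1, 0.2, 0.1, 0, 0.05)),
                         t = c(1, -1, 2))
  T2 <- affine_transform(Q = ssmesh:::rotvec_to_Q(c(-0.2, 0.1, 0.15)),
                         t = c(0.5, 2, -1))
  lhs <- apply_affine(apply_affine(sm, T1), T2)
  rhs <- apply_affine(sm, compose_affine(T2, T1))
  expect_equal(lhs$vertices, rhs$vertices, tolerance = 1e-9)
})

test_that("affine_transform validates its factors", {
  expect_error(affine_transform(Q = diag(c(1, 1, 2))), "orthogonal")
  expect_error(affine_transform(S = matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
  expect_error(affine_transform(S = diag(c(1, -1, 1))), "positive definite")
})

test_that("select_template picks the most central sample", {
  sm <- dual_simplex_from_triangles(icosphere(1, radius = 10))
  expect_error(select_template(list(sm)), "at least 2")
  # identical meshes tie; lowest index wins
  expect_equal(select_template(list(sm, sm, sm), scale = 2), 1L)
  # one clear outlier in a family of similar ellipsoids
  make_m <- function(s) {
    m <- sm
    m$vertices <- sm$vertices %*% diag(s)
    m
  }
  meshes <- list(make_m(c(1.0, 0.9, 1.05)), make_m(c(1.05, 0.95, 1.0)),
                 make_m(c(2.5, 2.4, 2.6)), make_m(c(0.95, 1.0, 1.0)))
  expect_true(select_template(meshes, scale = 2) %in% c(1L, 2L, 4L))
})
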