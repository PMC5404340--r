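# Base landmark set used across the model tests.
base_landmarks <- function(n = 40, seed = 2) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2)) * (5 + runif(n))
}

rigid_motion <- function(X, rotvec, t) {
  sweep(X %*% t(ssmesh:::rotvec_to_Q(rotvec)), 2, t, "+")
}

test_that("GPA superposes rotated and translated copies exactly", {
  X <- base_landmarks()
  x1 <- as_shape_vector(X)
  x2 <- as_shape_vector(rigid_motion(X, c(0, 0, pi / 6), c(0, 0, 0)))
  out <- gpa_align(list(x1, x2))
  d <- sqrt(mean((out$aligned[[1]] - out$aligned[[2]])^2))
  expect_lt(d, 1e-6)
  # pure translations collapse to identical aligned shapes
  x3 <- as_shape_vector(sweep(X, 2, c(4, -2, 9), "+"))
  out2 <- gpa_align(list(x1, x3))
  expect_equal(out2$aligned[[1]], out2$aligned[[2]], tolerance = 1e-9)
})

test_that("GPA recovers a common shape from random rigid motions", {
  X <- base_landmarks()
  set.seed(6)
  shapes <- lapply(1:5, function(i) {
    as_shape_vector(rigid_motion(X, rnorm(3, 0, 0.8), rnorm(3, 0, 10)))
  })
  out <- gpa_align(shapes)
  for (i in 2:5) {
    expect_lt(max(abs(out$aligned[[i]] - out$aligned[[1]])), 1e-6)
  }
  expect_error(gpa_align(shapes[1]), "at least 2")
  expect_error(gpa_align(list(shapes[[1]], shapes[[2]][1:30])), "landmark count")
})

test_that("identical training shapes give a degenerate (mean-only) model", {
  x <- as_shape_vector(base_landmarks())
  model <- build_model(list(x, x, x))
  expect_equal(length(model$eigenvalues), 0L)
  expect_equal(model$c, 0L)
  expect_equal(synthesize(model, numeric(0)), x)
  expect_error(build_model(list(x)), "at least 2")
})

test_that("rank-1 families are recovered exactly", {
  x0 <- as_shape_vector(base_landmarks())
  set.seed(7)
  phi_star <- rnorm(length(x0))
  phi_star <- phi_star / sqrt(sum(phi_star^2))
  b <- c(-2, -1, 0, 1, 2)
  shapes <- lapply(b, function(bi) x0 + bi * phi_star)
  model <- build_model(shapes)
  expect_equal(model$eigenvalues[1], var(b), tolerance = 1e-9)  # 2.5
  expect_lt(sum(model$eigenvalues[-1]), 1e-18)
  # first mode is +/- phi_star
  expect_equal(abs(sum(model$modes[, 1] * phi_star)), 1, tolerance = 1e-9)
  expect_equal(model$c, 1L)
})

test_that("a 2-mode generator is recovered from 30 samples", {
  x0 <- as_shape_vector(base_landmarks(60))
  set.seed(17)
  U <- qr.Q(qr(matrix(rnorm(length(x0) * 2), ncol = 2)))
  B <- cbind(rnorm(30, 0, 3), rnorm(30, 0, 1))  # lambda* = 9, 1
  shapes <- lapply(1:30, function(i) x0 + as.vector(U %*% B[i, ]))
  model <- build_model(shapes)
  # the fitted eigenvalues equal those of the coefficient sample covariance
  # exactly (the data are exactly rank-2 around the mean)
  ref <- eigen(cov(B), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(model$eigenvalues[1:2], ref, tolerance = 1e-9)
  # and sit near the generating variances up to K = 30 sampling error
  expect_lt(abs(model$eigenvalues[1] / 9 - 1), 0.6)
  expect_lt(abs(model$eigenvalues[2] / 1 - 1), 0.6)
  expect_lt(sum(model$eigenvalues[-(1:2)]) / sum(model$eigenvalues), 0.01)
  expect_equal(model$c, 2L)
})

test_that("synthesize obeys the mean, the modes and the 3-sigma clamp", {
  x0 <- as_shape_vector(base_landmarks())
  phi_star <- rep(1 / sqrt(length(x0)), length(x0))
  shapes <- lapply(c(-2, -1, 0, 1, 2), function(bi) x0 + bi * phi_star)
  model <- build_model(shapes)
  expect_equal(synthesize(model, 0), model$mean)
  lim <- 3 * sqrt(model$eigenvalues[1])
  ref <- model$mean + lim * model$modes[, 1]
  expect_equal(synthesize(model, lim), ref, tolerance = 1e-12)
  expect_message(over <- synthesize(model, 10 * sqrt(model$eigenvalues[1])),
                 "clamped")
  expect_equal(over, ref, tolerance = 1e-12)
  expect_error(synthesize(model, c(1, 1)), "exceeds")
})

test_that("projection inverts synthesis and is an orthogonal projector", {
  x0 <- as_shape_vector(base_landmarks(50))
  set.seed(9)
  U <- qr.Q(qr(matrix(rnorm(length(x0) * 3), ncol = 3)))
  shapes <- lapply(1:12, function(i) x0 + as.vector(U %*% rnorm(3, 0, c(3, 2, 1))))
  model <- build_model(shapes)
  expect_equal(project(model, model$mean), rep(0, ncol(model$modes)),
               tolerance = 1e-9)
  b_star <- c(1.5, -0.8, 0.3)
  x <- synthesize(model, b_star)
  expect_equal(project(model, x, 3), b_star, tolerance = 1e-9)
  # residual of a projected arbitrary shape is orthogonal to all modes
  y <- x0 + rnorm(length(x0))
  resid <- y - reconstruct(model, y)
  expect_lt(max(abs(crossprod(model$modes, resid))), 1e-9)
})

test_that("eigenvalues conserve total variance and match the direct solve", {
  set.seed(13)
  shapes <- lapply(1:6, function(i) as_shape_vector(base_landmarks(8, seed = i)))
  model <- build_model(shapes)           # 24-dim, K = 6: dual path
  X <- do.call(rbind, shapes)
  S <- cov(X)
  expect_equal(sum(model$eigenvalues), sum(diag(S)), tolerance = 1e-9)
  direct <- eigen(S, symmetric = TRUE)
  k <- length(model$eigenvalues)
  expect_equal(model$eigenvalues, direct$values[seq_len(k)], tolerance = 1e-9)
  for (m in seq_len(k)) {
    expect_equal(abs(sum(model$modes[, m] * direct$vectors[, m])), 1,
                 tolerance = 1e-6)
  }
  # modes orthonormal
  expect_equal(crossprod(model$modes), diag(k), tolerance = 1e-9)
})

test_that("reconstruction error is non-increasing in the mode count", {
  set.seed(23)
  shapes <- lapply(1:10, function(i) as_shape_vector(base_landmarks(30, seed = i)))
  model <- build_model(shapes)
  y <- as_shape_vector(base_landmarks(30, seed = 99))
  errs <- vapply(0:length(model$eigenvalues), function(M) {
    sqrt(sum((y - reconstruct(model, y, M))^2))
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("shape models round-trip through serialization", {
  x0 <- as_shape_vector(base_landmarks())
  shapes <- lapply(c(-1, 0, 1, 2), function(bi) x0 + bi * sin(seq_along(x0)))
  model <- build_model(shapes)
  path <- tempfile(fileext = ".json")
  write_shape_model(model, path)
  back <- read_shape_model(path)
  expect_equal(back$mean, model$mean, tolerance = 1e-12)
  expect_equal(back$modes, model$modes, tolerance = 1e-12)
  expect_equal(back$eigenvalues, model$eigenvalues, tolerance = 1e-12)
  expect_identical(back$c, model$c)
  unlink(path)
})
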