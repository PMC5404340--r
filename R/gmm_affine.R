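#' Affine transform with orthogonal-SPD factorization
#'
#' Represents `x -> A x + t` with `A = Q S`, `Q` orthogonal (a rotation) and
#' `S` symmetric positive definite — the factorization used by the affine
#' Gaussian-mixture registration.
#'
#' @param Q 3x3 orthogonal matrix (`det = +1`).
#' @param S 3x3 symmetric positive-definite matrix.
#' @param t length-3 translation (mm).
#' @return An object of class `affine3` with fields `Q`, `S`, `t` and the
#'   composed `A`.
#' @export
affine_transform <- function(Q = diag(3), S = diag(3), t = c(0, 0, 0)) {
  Q <- as.matrix(Q); S <- as.matrix(S)
  t <- as_point3(t, "t")
  if (max(abs(crossprod(Q) - diag(3))) > 1e-9) {
    stop("'Q' is not orthogonal")
  }
  if (max(abs(S - t(S))) > 1e-9) stop("'S' is not symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("'S' is not positive definite")
  structure(list(Q = Q, S = S, t = t, A = Q %*% S), class = "affine3")
}

#' @export
print.affine3 <- function(x, ...) {
  cat("affine3 transform A = Q S, t =", format(x$t), "\n")
  print(x$A)
  invisible(x)
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `first` then `second`.
#'
#' @param second,first `affine3` objects.
#' @return The composed `affine3`.
#' @export
compose_affine <- function(second, first) {
  A <- second$A %*% first$A
  t <- as.vector(second$A %*% first$t) + second$t
  affine_from_A(A, t)
}

# Rebuild the Q/S factorization of a general invertible A by polar
# decomposition (Q = U V', S = V D V' from the SVD).
affine_from_A <- function(A, t) {
  sv <- svd(A)
  Q <- sv$u %*% t(sv$v)
  if (det(Q) < 0) {  # keep Q a proper rotation; fold the flip into S's frame
    sv$u[, 3] <- -sv$u[, 3]
    sv$d[3] <- -sv$d[3]
    Q <- sv$u %*% t(sv$v)
  }
  S <- sv$v %*% diag(sv$d) %*% t(sv$v)
  affine_transform(Q, (S + t(S)) / 2, t)
}

#' Apply an affine transform to a mesh
#'
#' Maps every vertex `x -> A x + t`; connectivity is unchanged.
#'
#' @param mesh a `simplex_mesh` or `triangle_mesh`.
#' @param T an `affine3`.
#' @return The transformed mesh (same class).
#' @export
apply_affine <- function(mesh, T) {
  stopifnot(inherits(T, "affine3"))
  v <- mesh$vertices %*% t(T$A)
  v <- sweep(v, 2, T$t, "+")
  mesh$vertices <- v
  mesh
}

#' Gaussian-mixture representation of a mesh
#'
#' One isotropic Gaussian component per vertex with uniform weights `1/m` and
#' a shared scale (standard deviation). The default scale is the mean edge
#' length of the mesh — comparable mixtures for comparable meshes.
#'
#' @param mesh a `simplex_mesh` or `triangle_mesh`.
#' @param scale isotropic standard deviation (mm); `NULL` for mean edge
#'   length.
#' @param max_components deterministic uniform-stride subsampling cap on the
#'   number of components (controls the O(mn) pairwise cost).
#' @return An object of class `gmm_shape` with `means`, `weights`, `scale`.
#' @export
mesh_to_gmm <- function(mesh, scale = NULL, max_components = 1000) {
  v <- mesh$vertices
  if (nrow(v) == 0L) stop("mesh has no vertices")
  if (is.null(scale)) scale <- mean_edge_length(mesh)
  if (!is.numeric(scale) || scale <= 0) stop("'scale' must be > 0")
  if (nrow(v) > max_components) {
    stride <- ceiling(nrow(v) / max_components)
    v <- v[seq(1L, nrow(v), by = stride), , drop = FALSE]
  }
  m <- nrow(v)
  structure(list(means = v, weights = rep(1 / m, m), scale = scale),
            class = "gmm_shape")
}

mean_edge_length <- function(mesh) {
  if (inherits(mesh, "simplex_mesh")) {
    v <- mesh$vertices
    nb <- mesh$neighbors
    mean(rownorms(v[rep(seq_len(nrow(v)), 3L), , drop = FALSE] -
                    v[as.vector(nb), , drop = FALSE]))
  } else {
    e <- mesh_edges(mesh)
    mean(rownorms(mesh$vertices[e[, 1], , drop = FALSE] -
                    mesh$vertices[e[, 2], , drop = FALSE]))
  }
}

# sum_ij a_i b_j N(mu_i - nu_j; 0, s2 I3): closed-form Gaussian-product
# integral for two isotropic mixtures with combined variance s2.
gmm_cross_integral <- function(mu, a, nu, b, s2) {
  d2 <- outer(rowSums(mu^2), rowSums(nu^2), "+") - 2 * (mu %*% t(nu))
  sum((a %o% b) * exp(-d2 / (2 * s2))) * (2 * pi * s2)^(-1.5)
}

#' L2 registration objective between two Gaussian mixtures
#'
#' The transformation-dependent part of the L2 distance between the
#' affinely transformed template mixture `f` and the target mixture `g`:
#' `int f_T^2 - 2 int f_T g` (the `int g^2` term does not depend on the
#' transform and is dropped). Both integrals have closed Gaussian-product
#' forms; with isotropic component covariances the rotated covariance
#' `Q s^2 I Q'` is exactly `s^2 I`, but the `S` factor of the affine map
#' still reshapes the point cloud through the transformed means.
#'
#' @param f template `gmm_shape`.
#' @param g target `gmm_shape`.
#' @param T an `affine3` applied to `f`.
#' @return Scalar objective (add `int g^2` to recover the full L2 distance).
#' @export
l2_objective <- function(f, g, T) {
  stopifnot(inherits(f, "gmm_shape"), inherits(g, "gmm_shape"),
            inherits(T, "affine3"))
  mu <- f$means %*% t(T$A)
  mu <- sweep(mu, 2, T$t, "+")
  ff <- gmm_cross_integral(mu, f$weights, mu, f$weights, 2 * f$scale^2)
  fg <- gmm_cross_integral(mu, f$weights, g$means, g$weights,
                           f$scale^2 + g$scale^2)
  ff - 2 * fg
}

# --- parameterization of the 12 affine parameters ---------------------------

rotvec_to_Q <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

Q_to_rotvec <- function(Q) {
  ct <- (sum(diag(Q)) - 1) / 2
  ct <- min(max(ct, -1), 1)
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  ax <- c(Q[3, 2] - Q[2, 3], Q[1, 3] - Q[3, 1], Q[2, 1] - Q[1, 2])
  if (vnorm(ax) < 1e-12) {
    # th ~ pi: extract axis from Q + I
    M <- (Q + diag(3)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    ax <- ax * sign(c(1, M[1, 2], M[1, 3]) + (c(1, M[1, 2], M[1, 3]) == 0))
    return(th * ax / vnorm(ax))
  }
  th * ax / (2 * sin(th))
}

# S parameterized by log-Cholesky factors: 6-vector (log-diagonal first).
theta_to_S <- function(v) {
  L <- matrix(0, 3, 3)
  diag(L) <- exp(v[1:3])
  L[2, 1] <- v[4]; L[3, 1] <- v[5]; L[3, 2] <- v[6]
  L %*% t(L)
}

S_to_theta <- function(S) {
  L <- t(chol(S))
  c(log(diag(L)), L[2, 1], L[3, 1], L[3, 2])
}

theta_to_affine <- function(th) {
  affine_transform(rotvec_to_Q(th[1:3]), theta_to_S(th[4:9]), th[10:12])
}

affine_to_theta <- function(T) {
  c(Q_to_rotvec(T$Q), S_to_theta(T$S), T$t)
}

# Analytic gradient of the L2 objective with respect to (A, t); the pairwise
# Gaussian weights make this one O(mn) pass instead of 24 finite-difference
# objective evaluations.
l2_objective_gradient_At <- function(f, g, A, t) {
  M <- f$means
  V <- g$means
  a <- f$weights
  b <- g$weights
  mu <- sweep(M %*% t(A), 2, t, "+")
  # template-template term: differences D = A (mu_i - mu_j)
  s1sq <- 2 * f$scale^2
  c1 <- (2 * pi * s1sq)^(-1.5)
  d2_ff <- outer(rowSums(mu^2), rowSums(mu^2), "+") - 2 * (mu %*% t(mu))
  W1 <- (a %o% a) * (c1 / s1sq) * exp(-pmax(d2_ff, 0) / (2 * s1sq))
  r1 <- rowSums(W1)
  G1 <- 2 * (crossprod(M * r1, M) - t(M) %*% W1 %*% M)
  dA <- -(A %*% G1)
  # cross term: D = A mu_i + t - nu_j, with the -2 objective factor
  s2sq <- f$scale^2 + g$scale^2
  c2 <- (2 * pi * s2sq)^(-1.5)
  d2_fg <- outer(rowSums(mu^2), rowSums(V^2), "+") - 2 * (mu %*% t(V))
  W2 <- 2 * (a %o% b) * (c2 / s2sq) * exp(-pmax(d2_fg, 0) / (2 * s2sq))
  r2 <- rowSums(W2)
  cs2 <- colSums(W2)
  dA <- dA + crossprod(mu * r2, M) - t(V) %*% t(W2) %*% M
  dt <- as.vector(colSums(mu * r2) - as.vector(t(V) %*% cs2))
  list(dA = dA, dt = dt)
}

# Gradient in the 12 registration parameters: chain the analytic (A, t)
# gradient through the (cheap) parametrization map by central differences on
# A(theta) only.
l2_objective_gradient <- function(f, g, th) {
  Q <- rotvec_to_Q(th[1:3])
  S <- theta_to_S(th[4:9])
  A <- Q %*% S
  gr <- l2_objective_gradient_At(f, g, A, th[10:12])
  out <- numeric(12)
  h <- 1e-6
  for (k in 1:9) {
    tp <- th; tp[k] <- tp[k] + h
    tm <- th; tm[k] <- tm[k] - h
    dAk <- (rotvec_to_Q(tp[1:3]) %*% theta_to_S(tp[4:9]) -
              rotvec_to_Q(tm[1:3]) %*% theta_to_S(tm[4:9])) / (2 * h)
    out[k] <- sum(gr$dA * dAk)
  }
  out[10:12] <- gr$dt
  out
}

#' Affine registration of two Gaussian-mixture shapes
#'
#' Minimizes [l2_objective()] over the 12 affine parameters (rotation
#' vector, log-Cholesky SPD factors, translation) by quasi-Newton (BFGS)
#' search with numerical gradients. The objective at the result never
#' exceeds the objective at the initial transform.
#'
#' @param template,target `gmm_shape` objects.
#' @param init initial `affine3` (default identity at the centroid offset).
#' @param maxit,reltol optimizer controls.
#' @return A list of class `gmm_registration`: `transform` (`affine3`),
#'   `objective`, `initial_objective`, `counts`, `convergence`.
#' @export
register_affine <- function(template, target, init = NULL, maxit = 200,
                            reltol = 1e-10) {
  stopifnot(inherits(template, "gmm_shape"), inherits(target, "gmm_shape"))
  if (is.null(init)) {
    t0 <- colMeans(target$means) - colMeans(template$means)
    init <- affine_transform(t = t0)
  }
  th0 <- affine_to_theta(init)
  obj <- function(th) {
    A <- rotvec_to_Q(th[1:3]) %*% theta_to_S(th[4:9])
    mu <- sweep(template$means %*% t(A), 2, th[10:12], "+")
    gmm_cross_integral(mu, template$weights, mu, template$weights,
                       2 * template$scale^2) -
      2 * gmm_cross_integral(mu, template$weights, target$means,
                             target$weights,
                             template$scale^2 + target$scale^2)
  }
  grad <- function(th) l2_objective_gradient(template, target, th)
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  f0 <- obj(th0)
  if (fit$value > f0) {  # never worse than the initialization
    fit$par <- th0
    fit$value <- f0
  }
  if (fit$convergence > 1) {
    warning(sprintf(
      "optimizer did not converge (code %d) after %d evaluations; objective %.6g",
      fit$convergence, fit$counts[1], fit$value))
  }
  structure(list(transform = theta_to_affine(fit$par), objective = fit$value,
                 initial_objective = f0, counts = fit$counts,
                 convergence = fit$convergence), class = "gmm_registration")
}

#' Select the most representative template mesh
#'
#' Registers every candidate to every other sample and returns the index
#' minimizing the summed post-registration L2 objectives — the sample most
#' similar, after affine alignment, to the rest of the population. Ties
#' break to the lowest index.
#'
#' @param meshes list of at least two meshes.
#' @param scale,max_components forwarded to [mesh_to_gmm()].
#' @return Integer index of the selected template.
#' @export
select_template <- function(meshes, scale = NULL, max_components = 1000) {
  K <- length(meshes)
  if (K < 2L) stop("need at least 2 meshes to select a template")
  gmms <- lapply(meshes, mesh_to_gmm, scale = scale,
                 max_components = max_components)
  total <- numeric(K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)[-i]) {
      total[i] <- total[i] + register_affine(gmms[[i]], gmms[[j]])$objective
    }
  }
  which.min(total)
}
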