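#' Shape vectors
#'
#' Corresponded shapes are handled as `3N`-dimensional landmark vectors:
#' landmark `k` occupies components `3k-2, 3k-1, 3k` (x, y, z, in mm). A set
#' of shapes shares `N` and the landmark ordering.
#'
#' @param mesh a mesh, or an `n x 3` matrix of landmarks.
#' @return Numeric vector of length `3N`.
#' @export
as_shape_vector <- function(mesh) {
  m <- if (is.list(mesh)) mesh$vertices else mesh
  as.vector(t(as.matrix(m)))
}

#' @rdname as_shape_vector
#' @param x a shape vector.
#' @export
shape_vector_to_landmarks <- function(x) {
  if (length(x) %% 3L != 0L) stop("shape vector length must be divisible by 3")
  matrix(x, ncol = 3L, byrow = TRUE)
}

# Optimal rigid (optionally scaled) alignment of landmark matrix X onto Y:
# rotation by the Kabsch/Procrustes SVD solution, no reflections.
procrustes_fit <- function(X, Y, with_scaling = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  M <- crossprod(X0, Y0)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (with_scaling) sum(sv$d * c(1, 1, d)) / sum(X0^2) else 1
  list(R = R, s = s, cx = cx, cy = cy)
}

apply_procrustes <- function(X, fit) {
  X0 <- sweep(X, 2, fit$cx)
  sweep(fit$s * (X0 %*% fit$R), 2, fit$cy, "+")
}

#' Generalized Procrustes alignment of corresponded shapes
#'
#' Iteratively translates all shapes to a common centroid, rotates (and
#' optionally scales) each onto the current mean, and re-estimates the mean
#' until it moves less than `tol`. Scaling is off by default so the model
#' and all quality metrics stay in millimetres.
#'
#' @param shapes list of shape vectors (equal length, corresponded).
#' @param with_scaling also remove size (default `FALSE`).
#' @param tol convergence threshold on the mean-shape change.
#' @param max_iters iteration cap.
#' @return A list with `aligned` (list of shape vectors in the common
#'   frame) and `mean` (the converged mean shape vector).
#' @export
gpa_align <- function(shapes, with_scaling = FALSE, tol = 1e-8,
                      max_iters = 100) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  lens <- lengths(shapes)
  if (length(unique(lens)) != 1L) {
    stop("all shapes must have the same landmark count")
  }
  lms <- lapply(shapes, shape_vector_to_landmarks)
  # common frame: centroids at the origin
  lms <- lapply(lms, function(X) sweep(X, 2, colMeans(X)))
  mean_lm <- Reduce(`+`, lms) / length(lms)
  for (it in seq_len(max_iters)) {
    lms <- lapply(lms, function(X) {
      fit <- procrustes_fit(X, mean_lm, with_scaling = with_scaling)
      sweep(fit$s * (sweep(X, 2, fit$cx) %*% fit$R), 2, fit$cy, "+")
    })
    new_mean <- Reduce(`+`, lms) / length(lms)
    delta <- sqrt(mean((new_mean - mean_lm)^2))
    mean_lm <- new_mean
    if (delta < tol) break
  }
  list(aligned = lapply(lms, as_shape_vector), mean = as_shape_vector(mean_lm))
}

#' Build a PCA statistical shape model
#'
#' Sample covariance (factor `1/(K-1)`) of the aligned shape vectors,
#' eigen-decomposed through the `K x K` Gram (dual) matrix when `3N > K`.
#' At most `K - 1` eigenvalues are nonzero. The retained-mode count `c` is
#' the smallest `t` whose cumulative eigenvalue fraction strictly exceeds
#' 0.98. Eigenvector signs are fixed by making each mode's
#' largest-magnitude component positive.
#'
#' @param aligned list of aligned shape vectors (e.g. from [gpa_align()]).
#' @return An object of class `shape_model`: `mean`, `modes` (orthonormal
#'   columns), `eigenvalues` (descending), `c`, `K`, `N`.
#' @export
build_model <- function(aligned) {
  K <- length(aligned)
  if (K < 2L) stop("need at least 2 shapes to build a model")
  X <- do.call(rbind, aligned)        # K x 3N
  mean_x <- colMeans(X)
  Xc <- sweep(X, 2, mean_x)
  p <- ncol(X)
  if (p > K) {
    G <- Xc %*% t(Xc) / (K - 1)       # K x K dual
    eg <- eigen(G, symmetric = TRUE)
    keep <- which(eg$values > max(eg$values[1], 0) * 1e-12 & eg$values > 0)
    lambda <- eg$values[keep]
    modes <- t(Xc) %*% eg$vectors[, keep, drop = FALSE]
    modes <- sweep(modes, 2, sqrt(colSums(modes^2)), "/")
  } else {
    S <- crossprod(Xc) / (K - 1)
    eg <- eigen(S, symmetric = TRUE)
    keep <- which(eg$values > max(eg$values[1], 0) * 1e-12 & eg$values > 0)
    lambda <- eg$values[keep]
    modes <- eg$vectors[, keep, drop = FALSE]
  }
  if (length(lambda) == 0L) {
    modes <- matrix(0, p, 0)
  } else {
    # deterministic sign: largest-|component| positive
    for (m in seq_len(ncol(modes))) {
      j <- which.max(abs(modes[, m]))
      if (modes[j, m] < 0) modes[, m] <- -modes[, m]
    }
  }
  total <- sum(lambda)
  c_retained <- if (total > 0) {
    which(cumsum(lambda) / total > 0.98)[1]
  } else 0L
  structure(list(mean = mean_x, modes = modes, eigenvalues = lambda,
                 c = as.integer(c_retained %||% 0L), K = K, N = p %/% 3L),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "shape_model: K = %d training shapes, N = %d landmarks, %d modes (c = %d retained at 98%%)\n",
    x$K, x$N, length(x$eigenvalues), x$c))
  invisible(x)
}

#' Synthesize a shape from mode coefficients
#'
#' `x = mean + sum_m b_m phi_m`, with each `b_m` clamped to the statistically
#' plausible interval `[-3 sqrt(lambda_m), +3 sqrt(lambda_m)]` (clamping is
#' reported with a message).
#'
#' @param model a `shape_model`.
#' @param b numeric coefficients for the leading modes (length `<= c`).
#' @return A shape vector.
#' @export
synthesize <- function(model, b) {
  stopifnot(inherits(model, "shape_model"))
  if (length(b) > model$c) {
    stop(sprintf("length(b) = %d exceeds the retained mode count c = %d",
                 length(b), model$c))
  }
  if (length(b) == 0L) return(model$mean)
  lim <- 3 * sqrt(model$eigenvalues[seq_along(b)])
  clamped <- pmin(pmax(b, -lim), lim)
  if (any(clamped != b)) {
    message(sprintf("synthesize: %d coefficient(s) clamped to +/-3 sd",
                    sum(clamped != b)))
  }
  model$mean + as.vector(model$modes[, seq_along(b), drop = FALSE] %*% clamped)
}

#' Project a shape onto the leading model modes
#'
#' Least-squares coefficients of `x` in the model's first `M` modes:
#' `b_m = phi_m' (x - mean)`. Used to reconstruct held-out shapes.
#'
#' @param model a `shape_model`.
#' @param x a shape vector of matching length.
#' @param M number of modes (defaults to all available; may exceed `c` for
#'   evaluation purposes but not the stored mode count).
#' @return Numeric coefficient vector of length `M`.
#' @export
project <- function(model, x, M = NULL) {
  stopifnot(inherits(model, "shape_model"))
  M <- M %||% ncol(model$modes)
  if (M > ncol(model$modes)) stop("M exceeds the available mode count")
  if (length(x) != length(model$mean)) stop("shape length mismatch")
  if (M == 0L) return(numeric(0))
  as.vector(crossprod(model$modes[, seq_len(M), drop = FALSE], x - model$mean))
}

#' Reconstruct a shape with the leading M modes
#'
#' Orthogonal projection of `x` onto the affine subspace spanned by the
#' first `M` modes around the mean (no clamping; evaluation use).
#'
#' @inheritParams project
#' @return The reconstructed shape vector.
#' @export
reconstruct <- function(model, x, M = NULL) {
  b <- project(model, x, M)
  if (length(b) == 0L) return(model$mean)
  model$mean + as.vector(model$modes[, seq_along(b), drop = FALSE] %*% b)
}

#' Serialize / restore a shape model
#'
#' Single-file JSON representation (mean, modes, eigenvalues, counts).
#'
#' @param model a `shape_model`.
#' @param path file path.
#' @return `path` (write) or the restored `shape_model` (read).
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  obj <- list(mean = model$mean, modes = as.vector(model$modes),
              n_modes = ncol(model$modes), eigenvalues = model$eigenvalues,
              c = model$c, K = model$K, N = model$N,
              format = "ssmesh-shape-model-v1")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ssmesh-shape-model-v1")) {
    stop("not an ssmesh shape model file")
  }
  structure(list(mean = obj$mean,
                 modes = matrix(obj$modes, ncol = obj$n_modes),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 c = as.integer(obj$c), K = as.integer(obj$K),
                 N = as.integer(obj$N)),
            class = "shape_model")
}
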