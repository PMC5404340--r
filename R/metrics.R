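#' Shape-model compactness
#'
#' Cumulative variance captured by the leading `M` modes:
#' `C(M) = sum_{m<=M} lambda_m`. Smaller totals at a given `M` indicate a
#' more compact model.
#'
#' @param model a `shape_model`.
#' @param M number of modes (`0 <= M <=` available modes).
#' @return Scalar cumulative variance (mm^2).
#' @export
compactness <- function(model, M) {
  stopifnot(inherits(model, "shape_model"))
  if (M < 0) stop("'M' must be >= 0")
  if (M > length(model$eigenvalues)) stop("'M' exceeds the available modes")
  if (M == 0) return(0)
  sum(model$eigenvalues[seq_len(M)])
}

# Distance between two shape vectors: root-mean per-landmark distance
# ||x - y|| / sqrt(N) (mm) by default, or the raw squared norm.
shape_distance <- function(x, y, squared = FALSE) {
  if (squared) sum((x - y)^2) else sqrt(sum((x - y)^2) / (length(x) / 3))
}

#' Generalization ability (leave-one-out)
#'
#' For each training shape, a model is rebuilt from the remaining `K - 1`
#' shapes, the held-out shape is rigidly re-aligned to the leave-one-out
#' mean (so the metric measures shape, not pose), reconstructed with the
#' first `M` modes, and the reconstruction error recorded. Reported as the
#' mean and standard deviation over the `K` tests, by default as the
#' root-mean per-landmark distance in mm (`||x - x'|| / sqrt(N)`); set
#' `squared = TRUE` for the raw squared-norm variant.
#'
#' @param shapes list of aligned shape vectors (`K >= 3`).
#' @param M number of modes used in the reconstruction (`<= K - 2`).
#' @param squared report raw squared norms instead of mm.
#' @param align rigidly re-align each held-out shape to the leave-one-out
#'   mean before projection (default `TRUE`; the re-alignment rotation can
#'   carry an exactly-linear family slightly off its own span, so tests of
#'   pure subspace reconstruction set this to `FALSE`).
#' @param with_scaling allow scaling in the held-out re-alignment.
#' @return A list with `mean`, `sd`, `errors` (per-test), `M` and `units`.
#' @export
generalization <- function(shapes, M, squared = FALSE, align = TRUE,
                           with_scaling = FALSE) {
  K <- length(shapes)
  if (K < 3L) stop("need at least 3 shapes for leave-one-out tests")
  if (M > K - 2L) {
    stop(sprintf("M = %d exceeds the K - 2 = %d modes a leave-one-out model can hold",
                 M, K - 2L))
  }
  errors <- numeric(K)
  for (i in seq_len(K)) {
    model <- build_model(shapes[-i])
    xi <- shapes[[i]]
    if (align) {
      Xi <- shape_vector_to_landmarks(xi)
      mean_lm <- shape_vector_to_landmarks(model$mean)
      fit <- procrustes_fit(Xi, mean_lm, with_scaling = with_scaling)
      xi <- as_shape_vector(apply_procrustes(Xi, fit))
    }
    Muse <- min(M, ncol(model$modes))
    xr <- reconstruct(model, xi, Muse)
    errors[i] <- shape_distance(xi, xr, squared = squared)
  }
  list(mean = mean(errors), sd = stats::sd(errors), errors = errors, M = M,
       units = if (squared) "mm^2 (squared norm)" else "mm (rms per landmark)")
}

#' Specificity (Monte-Carlo)
#'
#' Draws `n_samples` synthetic shapes from the model with coefficients
#' `b_m` uniform on `[-3 sqrt(lambda_m), +3 sqrt(lambda_m)]` for the first
#' `M` modes, finds each sample's nearest training shape (exact linear
#' scan) and reports the mean and standard deviation of those distances.
#' Deterministic given `seed`; the caller's RNG state is preserved.
#'
#' @param model a `shape_model`.
#' @param shapes the training shape vectors the model was built from.
#' @param M number of sampled modes.
#' @param n_samples Monte-Carlo sample count (default 10000).
#' @param seed RNG seed.
#' @param squared report raw squared norms instead of mm.
#' @return A list with `mean`, `sd`, `M`, `n_samples` and `units`.
#' @export
specificity <- function(model, shapes, M, n_samples = 10000, seed = 1,
                        squared = FALSE) {
  stopifnot(inherits(model, "shape_model"), n_samples >= 1)
  if (length(shapes) == 0L) stop("empty training set")
  if (M > length(model$eigenvalues)) stop("'M' exceeds the available modes")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  lim <- if (M > 0) 3 * sqrt(model$eigenvalues[seq_len(M)]) else numeric(0)
  X <- do.call(rbind, shapes)                  # K x 3N
  N <- length(model$mean) / 3
  B <- if (M > 0) {
    matrix(stats::runif(n_samples * M, -1, 1), n_samples, M) %*% diag(lim, M)
  } else {
    matrix(0, n_samples, 0)
  }
  modes <- model$modes[, seq_len(M), drop = FALSE]
  samples <- matrix(rep(model$mean, each = n_samples), n_samples) +
    B %*% t(modes)
  # nearest training shape by an exact linear scan (numerically stable
  # differences, not the expanded quadratic form)
  d2min <- rep(Inf, n_samples)
  for (k in seq_len(nrow(X))) {
    d2 <- rowSums(sweep(samples, 2, X[k, ])^2)
    d2min <- pmin(d2min, d2)
  }
  dists <- if (squared) d2min else sqrt(d2min / N)
  list(mean = mean(dists), sd = stats::sd(dists), M = M,
       n_samples = n_samples,
       units = if (squared) "mm^2 (squared norm)" else "mm (rms per landmark)")
}

#' Metric curves over mode counts
#'
#' Evaluates compactness, generalization and specificity for a range of
#' mode counts and returns a tidy data frame (one row per metric and `M`).
#'
#' @param model a `shape_model` built from `shapes`.
#' @param shapes the aligned training shape vectors.
#' @param modes integer vector of mode counts.
#' @param n_samples,seed specificity Monte-Carlo controls.
#' @return A data frame with columns `metric`, `M`, `mean`, `sd`, `units`.
#' @export
metric_curves <- function(model, shapes, modes = seq_len(model$c),
                          n_samples = 1000, seed = 1) {
  rows <- list()
  for (M in modes) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "compactness", M = M, mean = compactness(model, M),
      sd = NA_real_, units = "mm^2")
    if (M <= length(shapes) - 2L) {
      g <- generalization(shapes, M)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "generalization", M = M, mean = g$mean, sd = g$sd,
        units = g$units)
    }
    s <- specificity(model, shapes, M, n_samples = n_samples, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "specificity", M = M, mean = s$mean, sd = s$sd, units = s$units)
  }
  do.call(rbind, rows)
}
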