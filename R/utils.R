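# Internal numeric helpers shared across modules.

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Row-wise Euclidean norms of an n x 3 matrix.
rownorms <- function(m) sqrt(rowSums(m * m))

# Normalize rows to unit length; zero rows left unchanged.
normalize_rows <- function(m) {
  n <- rownorms(m)
  n[n == 0] <- 1
  m / n
}

vnorm <- function(v) sqrt(sum(v * v))

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || anyNA(p)) {
    stop(sprintf("'%s' must be a numeric 3-vector", what), call. = FALSE)
  }
  p
}

# Canonical undirected-edge key for vertex index pairs (doubles are exact
# up to 2^53, far beyond any mesh/volume size handled here).
edge_key <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo + hi * 2^26
}

`%||%` <- function(a, b) if (is.null(a)) b else a
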