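#' Edge map of a volume
#'
#' Gradient magnitude of the Gaussian-blurred volume, min-max normalized to
#' `[0, 1]`. Gradients are spacing-aware central differences (one-sided at
#' the borders). An identically-zero gradient field is returned as all zeros.
#'
#' @param vol a [label_volume()] (or any list with `data`, `spacing`,
#'   `origin`).
#' @param sigma Gaussian blur standard deviation in voxels (`>= 0`; `0`
#'   disables blurring).
#' @return An object of class `edge_map` with fields `data` (in `[0, 1]`),
#'   `spacing`, `origin`, `sigma`.
#' @export
compute_edge_map <- function(vol, sigma = 1) {
  stopifnot(sigma >= 0)
  arr <- vol$data
  if (sigma > 0) arr <- gaussian_blur3(arr, sigma)
  g <- gradient_magnitude3(arr, vol$spacing)
  mn <- min(g); mx <- max(g)
  if (mx > mn) g <- (g - mn) / (mx - mn) else g[] <- 0
  structure(list(data = g, spacing = vol$spacing, origin = vol$origin,
                 sigma = sigma), class = "edge_map")
}

# Separable Gaussian blur, kernel truncated at 4 sigma, reflected borders.
gaussian_blur3 <- function(arr, sigma) {
  rad <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) arr <- filter_axis(arr, k, axis)
  arr
}

# 1-D correlation along `axis` with symmetric kernel, replicate padding;
# implemented by summing shifted copies (kernels here are short).
filter_axis <- function(arr, k, axis) {
  d <- dim(arr)
  rad <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  idx_clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (s in -rad:rad) {
    w <- k[s + rad + 1L]
    src <- idx_clamp(seq_len(d[axis]) + s, d[axis])
    out <- out + w * switch(axis,
      arr[src, , , drop = FALSE],
      arr[, src, , drop = FALSE],
      arr[, , src, drop = FALSE])
  }
  out
}

gradient_magnitude3 <- function(arr, spacing) {
  gx <- diff_axis(arr, 1) / spacing[1]
  gy <- diff_axis(arr, 2) / spacing[2]
  gz <- diff_axis(arr, 3) / spacing[3]
  sqrt(gx^2 + gy^2 + gz^2)
}

# Central differences along one axis, one-sided at the two borders.
diff_axis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  hi <- pmin(seq_len(n) + 1L, n)
  lo <- pmax(seq_len(n) - 1L, 1L)
  h <- hi - lo  # 2 interior, 1 at borders
  g <- switch(axis,
    arr[hi, , , drop = FALSE] - arr[lo, , , drop = FALSE],
    arr[, hi, , drop = FALSE] - arr[, lo, , drop = FALSE],
    arr[, , hi, drop = FALSE] - arr[, , lo, drop = FALSE])
  sweep_axis(g, h, axis)
}

sweep_axis <- function(arr, v, axis) {
  d <- dim(arr)
  rep_v <- switch(axis,
    array(rep(v, times = d[2] * d[3]), d),
    array(rep(rep(v, each = d[1]), times = d[3]), d),
    array(rep(v, each = d[1] * d[2]), d))
  arr / rep_v
}

#' Discrete vector-field-convolution kernel
#'
#' `(2R+1)^3` grid of vectors `k(x,y,z) = m(x,y,z) n(x,y,z)` where `n` is the
#' unit vector pointing from `(x,y,z)` toward the kernel origin (`0` at the
#' origin itself) and `m` is a decreasing magnitude function of the distance
#' `r`: the power law `m1 = (r + eps_div)^-gamma` or the Gaussian
#' `m2 = exp(-r^2 / zeta^2)`.
#'
#' @param R kernel radius in voxels (`>= 1`).
#' @param magnitude_kind `"m1"` (power-law, default) or `"m2"` (Gaussian).
#' @param gamma positive decay exponent for `m1`.
#' @param zeta positive Gaussian width (voxels) for `m2`.
#' @param eps_div division guard added to `r` in `m1`.
#' @return An object of class `vfc_kernel` with `ux`, `uy`, `uz` component
#'   arrays and the parameters.
#' @export
build_kernel <- function(R, magnitude_kind = c("m1", "m2"), gamma = 1.7,
                         zeta = 2, eps_div = 1e-8) {
  magnitude_kind <- match.arg(magnitude_kind)
  R <- as.integer(R)
  if (R < 1L) stop("'R' must be >= 1")
  if (magnitude_kind == "m1" && gamma <= 0) stop("'gamma' must be > 0")
  if (magnitude_kind == "m2" && zeta <= 0) stop("'zeta' must be > 0")
  ax <- seq(-R, R)
  n1 <- length(ax)
  X <- array(rep(ax, times = n1 * n1), c(n1, n1, n1))
  Y <- array(rep(rep(ax, each = n1), times = n1), c(n1, n1, n1))
  Z <- array(rep(ax, each = n1 * n1), c(n1, n1, n1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  m <- if (magnitude_kind == "m1") (r + eps_div)^(-gamma) else exp(-r^2 / zeta^2)
  rsafe <- r
  rsafe[r == 0] <- 1
  ux <- -m * X / rsafe
  uy <- -m * Y / rsafe
  uz <- -m * Z / rsafe
  ctr <- R + 1L
  ux[ctr, ctr, ctr] <- 0; uy[ctr, ctr, ctr] <- 0; uz[ctr, ctr, ctr] <- 0
  structure(list(ux = ux, uy = uy, uz = uz, R = R,
                 magnitude_kind = magnitude_kind, gamma = gamma, zeta = zeta,
                 eps_div = eps_div), class = "vfc_kernel")
}

# Zero-padded linear ("same") convolution of a 3-D array with an odd-sized
# kernel, via FFT. Exactly crops the full convolution to the input grid.
fft_convolve3 <- function(arr, ker) {
  da <- dim(arr)
  dk <- dim(ker)
  stopifnot(all(dk %% 2L == 1L))
  dfull <- da + dk - 1L
  pa <- array(0, dfull)
  pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- arr
  pk <- array(0, dfull)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- ker
  conv <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(dfull)
  off <- (dk - 1L) %/% 2L
  conv[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]),
       off[3] + seq_len(da[3]), drop = FALSE]
}

#' Vector field convolution of an edge map
#'
#' Componentwise zero-padded linear convolution of the edge map with the
#' vector-field kernel, cropped to the edge-map grid. If the kernel is more
#' than twice the volume extent along an axis it is cropped with a warning
#' (the discarded tail contributes nothing inside the grid beyond the
#' padding).
#'
#' @param edge an `edge_map`.
#' @param kernel a [build_kernel()] result.
#' @return A list of class `vfc_field` with `u`, `v`, `w` component arrays
#'   and grid metadata.
#' @export
compute_vfc_field <- function(edge, kernel) {
  stopifnot(inherits(edge, "edge_map"), inherits(kernel, "vfc_kernel"))
  d <- dim(edge$data)
  kx <- kernel$ux; ky <- kernel$uy; kz <- kernel$uz
  if (any(dim(kx) > 2 * d + 1)) {
    warning("kernel larger than twice the volume extent; cropping kernel")
    keep <- lapply(1:3, function(a) {
      R <- kernel$R
      lim <- min(R, d[a])
      (R + 1L) + seq(-lim, lim)
    })
    kx <- kx[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
    ky <- ky[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
    kz <- kz[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  }
  structure(list(
    u = fft_convolve3(edge$data, kx),
    v = fft_convolve3(edge$data, ky),
    w = fft_convolve3(edge$data, kz),
    spacing = edge$spacing, origin = edge$origin), class = "vfc_field")
}

#' Scalar VFC energy volume
#'
#' Voxelwise Euclidean magnitude of the VFC field, with the grid maximum
#' recorded as the out-of-volume saturation value. The magnitude crests at
#' object edges; the greedy evolution minimizes its negation (see
#' [sample_external_energy()]).
#'
#' @param field a `vfc_field`.
#' @return An object of class `vfc_energy` with `energy`, `max_energy`,
#'   `spacing`, `origin`.
#' @export
energy_from_field <- function(field) {
  stopifnot(inherits(field, "vfc_field"))
  en <- sqrt(field$u^2 + field$v^2 + field$w^2)
  structure(list(energy = en, max_energy = max(en), spacing = field$spacing,
                 origin = field$origin), class = "vfc_energy")
}

#' Sample the VFC energy at world points
#'
#' Trilinear interpolation of the energy grid at arbitrary positions (mm).
#' Points outside the grid return `max_energy`, which keeps the deformable
#' mesh inside the volume (outside positions are maximally penalized).
#'
#' @param ev a `vfc_energy`.
#' @param p numeric length-3 point or `n x 3` matrix of points (mm).
#' @return Numeric vector of sampled energies.
#' @export
sample_energy <- function(ev, p) {
  stopifnot(inherits(ev, "vfc_energy"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  trilinear_sample(ev$energy, p, ev$spacing, ev$origin, outside = ev$max_energy)
}

#' Sample the greedy external energy at world points
#'
#' The candidate score minimized by the greedy evolution: the negated VFC
#' magnitude shifted to `max_energy - ||v(p)||` (non-negative, minima on the
#' magnitude crests at object edges; the shift is irrelevant under the
#' window min-max normalization). Points outside the grid return
#' `max_energy`, the largest possible external energy, which penalizes
#' leaving the volume.
#'
#' @inheritParams sample_energy
#' @return Numeric vector of external energies.
#' @export
sample_external_energy <- function(ev, p) {
  stopifnot(inherits(ev, "vfc_energy"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  ev$max_energy -
    trilinear_sample(ev$energy, p, ev$spacing, ev$origin, outside = 0)
}

trilinear_sample <- function(arr, p, spacing, origin, outside) {
  d <- dim(arr)
  # continuous 0-based voxel coordinates
  q <- sweep(sweep(p, 2, origin, "-"), 2, spacing, "/")
  out <- rep(outside, nrow(p))
  ok <- q[, 1] >= 0 & q[, 1] <= d[1] - 1 &
    q[, 2] >= 0 & q[, 2] <= d[2] - 1 &
    q[, 3] >= 0 & q[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  q <- q[ok, , drop = FALSE]
  i0 <- pmin(floor(q[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(q[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(q[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- q[, 1] - i0; fy <- q[, 2] - j0; fz <- q[, 3] - k0
  lin <- function(di, dj, dk) {
    arr[(i0 + di) + (j0 + dj) * d[1] + (k0 + dk) * d[1] * d[2] + 1]
  }
  val <-
    lin(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    lin(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    lin(1, 1, 0) * fx * fy * (1 - fz) +
    lin(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    lin(1, 0, 1) * fx * (1 - fy) * fz +
    lin(0, 1, 1) * (1 - fx) * fy * fz +
    lin(1, 1, 1) * fx * fy * fz
  out[ok] <- val
  out
}

#' Precompute the VFC energy volume for a binary target
#'
#' Convenience chain: edge map, kernel, convolution, magnitude. The kernel
#' radius defaults to the production-scale `R = 256` capped at the largest volume
#' dimension (the power-law kernel decays, so the truncation error at desk
#' scale is negligible and the cap is logged via `message()`).
#'
#' @param vol a [label_volume()].
#' @param sigma edge-map blur (voxels).
#' @param R requested kernel radius (voxels).
#' @param gamma,eps_div power-law kernel parameters.
#' @param magnitude_kind,zeta see [build_kernel()].
#' @return A `vfc_energy`.
#' @export
vfc_energy_for_volume <- function(vol, sigma = 1, R = 256, gamma = 1.7,
                                  eps_div = 1e-8,
                                  magnitude_kind = "m1", zeta = 2) {
  Ruse <- min(as.integer(R), max(dim(vol$data)))
  if (Ruse < R) {
    message(sprintf("VFC kernel radius capped at %d (volume extent)", Ruse))
  }
  edge <- compute_edge_map(vol, sigma = sigma)
  ker <- build_kernel(Ruse, magnitude_kind = magnitude_kind, gamma = gamma,
                      zeta = zeta, eps_div = eps_div)
  energy_from_field(compute_vfc_field(edge, ker))
}
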