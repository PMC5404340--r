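#' Digitized ellipsoid label volume
#'
#' Deterministic binary volume of an axis-aligned ellipsoid: a voxel is
#' foreground iff its centre lies inside the ellipsoid. Used as the basic
#' ground-truth fixture for surface extraction and deformable-model fits.
#'
#' @param semi_axes positive length-3 semi-axes (mm).
#' @param spacing voxel spacing (mm), default isotropic 1 mm.
#' @param dims volume dimensions in voxels.
#' @param center ellipsoid centre (mm); defaults to the grid centre.
#' @param origin world position of voxel `(0,0,0)` (mm).
#' @return A [label_volume()].
#' @export
make_ellipsoid_volume <- function(semi_axes, spacing = c(1, 1, 1),
                                  dims = c(64, 64, 64),
                                  center = NULL, origin = c(0, 0, 0)) {
  semi_axes <- as_point3(semi_axes, "semi_axes")
  spacing <- as_point3(spacing, "spacing")
  dims <- as.integer(dims)
  if (any(semi_axes <= 0)) stop("semi-axes must be strictly positive")
  origin <- as_point3(origin, "origin")
  if (is.null(center)) center <- origin + (dims - 1) * spacing / 2
  center <- as_point3(center, "center")
  ax <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ay <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  az <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  u2 <- ((ax - center[1]) / semi_axes[1])^2
  v2 <- ((ay - center[2]) / semi_axes[2])^2
  w2 <- ((az - center[3]) / semi_axes[3])^2
  inside <- outer(outer(u2, v2, "+"), w2, "+") < 1
  arr <- inside * 1
  if (any(arr[1, , ] > 0) || any(arr[dims[1], , ] > 0) ||
      any(arr[, 1, ] > 0) || any(arr[, dims[2], ] > 0) ||
      any(arr[, , 1] > 0) || any(arr[, , dims[3]] > 0)) {
    stop("ellipsoid touches the volume border; enlarge 'dims' or shrink the axes")
  }
  label_volume(arr, spacing = spacing, origin = origin)
}

# Smooth angular mode shapes for the radial shape family: low-order
# spherical-harmonic-like patterns of the unit direction (ux, uy, uz),
# bounded by 1 in absolute value.
family_mode_basis <- list(
  function(u) (3 * u[, 3]^2 - 1) / 2,          # zonal (Y20-like)
  function(u) u[, 1]^2 - u[, 2]^2,             # sectoral (Y22-like)
  function(u) u[, 1] * u[, 3],                 # tesseral (Y21-like)
  function(u) u[, 1] * u[, 2]                  # tesseral (Y22'-like)
)

# Radius of the base ellipsoid along unit directions u (n x 3).
ellipsoid_radius <- function(u, semi_axes) {
  1 / sqrt((u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
             (u[, 3] / semi_axes[3])^2)
}

#' Specification of a synthetic radial shape family
#'
#' Describes a star-shaped family around a base ellipsoid: the radius along
#' unit direction `u` is `rho(u) = rho0(u) + sum_m b_m psi_m(u)` with smooth
#' angular modes `psi_m` and per-shape coefficients `b_m ~ N(0, lambda_m)`.
#' Because the surface radius is linear in `b`, the induced landmark family
#' is exactly linear with per-mode variances `lambda_m` — the ground truth
#' for PCA-recovery tests.
#'
#' @param semi_axes base ellipsoid semi-axes (mm).
#' @param mode_sd standard deviations `sqrt(lambda_m)` of the mode
#'   coefficients (mm); length gives the number of modes (up to 4).
#' @param noise_sd additive landmark noise standard deviation (mm).
#' @param K number of shapes.
#' @param seed RNG seed for coefficient and noise draws.
#' @param spacing,dims volume digitization grid.
#' @param subdiv icosphere subdivision of the ground-truth surfaces.
#' @return An object of class `shape_family_spec`.
#' @export
shape_family_spec <- function(semi_axes = c(16, 13, 10), mode_sd = c(3, 1),
                              noise_sd = 0, K = 10, seed = 1,
                              spacing = c(1, 1, 1), dims = c(64, 64, 64),
                              subdiv = 2) {
  if (length(mode_sd) > length(family_mode_basis)) {
    stop("at most ", length(family_mode_basis), " modes are available")
  }
  if (any(mode_sd < 0) || noise_sd < 0) stop("amplitudes must be >= 0")
  structure(list(semi_axes = as_point3(semi_axes, "semi_axes"),
                 mode_sd = as.numeric(mode_sd), noise_sd = noise_sd,
                 K = as.integer(K), seed = as.integer(seed),
                 spacing = as_point3(spacing, "spacing"),
                 dims = as.integer(dims), subdiv = as.integer(subdiv)),
            class = "shape_family_spec")
}

#' Generate a synthetic shape family with known ground truth
#'
#' Draws `K` member shapes of the radial family described by `spec`
#' (deterministically, from `spec$seed`), returning for each member its
#' digitized binary volume, its exact ground-truth triangle surface (all
#' members share vertex ids, i.e. correspondence is known by construction)
#' and the true mode coefficients. Draws whose radius would pinch to zero
#' or whose surface would touch the volume border are rejected and redrawn.
#'
#' @param spec a [shape_family_spec()].
#' @param volumes generate digitized volumes (set `FALSE` to get only the
#'   ground-truth meshes and coefficients, e.g. for model-recovery tests).
#' @return A list with `volumes` (list of `label_volume` or `NULL`),
#'   `meshes` (list of `triangle_mesh`), `coefficients` (`K x M` matrix) and
#'   `spec`.
#' @export
make_shape_family <- function(spec, volumes = TRUE) {
  stopifnot(inherits(spec, "shape_family_spec"))
  M <- length(spec$mode_sd)
  base <- icosphere(spec$subdiv, radius = 1)
  u <- normalize_rows(base$vertices)
  rho0 <- ellipsoid_radius(u, spec$semi_axes)
  psi <- vapply(seq_len(M), function(m) family_mode_basis[[m]](u),
                numeric(nrow(u)))
  # normalize each mode to unit norm in 3N landmark space (the radial
  # displacement of landmark i is u_i * psi_m(u_i), and ||u_i|| = 1), so the
  # drawn coefficients are exactly the modes' shape-space scores and the
  # coefficient variances are the population eigenvalues
  mode_scale <- if (M > 0) sqrt(colSums(psi^2)) else numeric(0)
  if (M > 0) psi <- sweep(psi, 2, mode_scale, "/")
  center <- (spec$dims - 1) * spec$spacing / 2
  rmax_ok <- min((spec$dims - 4) * spec$spacing / 2)   # 2-voxel margin

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)

  coefs <- matrix(0, spec$K, max(M, 1L))
  meshes <- vector("list", spec$K)
  vols <- if (volumes) vector("list", spec$K) else NULL
  for (i in seq_len(spec$K)) {
    repeat {
      b <- if (M > 0) stats::rnorm(M, 0, spec$mode_sd) else numeric(0)
      rho <- rho0 + if (M > 0) as.vector(psi %*% b) else 0
      if (all(rho > 1) && max(rho) < rmax_ok) break
      message("shape family: resampled a self-intersecting/oversized draw")
    }
    if (M > 0) coefs[i, seq_len(M)] <- b
    verts <- u * rho
    if (spec$noise_sd > 0) {
      verts <- verts + matrix(stats::rnorm(length(verts), 0, spec$noise_sd),
                              ncol = 3)
    }
    verts <- sweep(verts, 2, center, "+")
    meshes[[i]] <- triangle_mesh(verts, base$faces, validate = FALSE)
    if (volumes) {
      vols[[i]] <- digitize_radial(b / mode_scale, spec, center)
    }
  }
  list(volumes = vols, meshes = meshes,
       coefficients = coefs[, seq_len(max(M, 1L)), drop = FALSE],
       spec = spec)
}

# Digitize one radial family member: voxel inside iff its distance from the
# centre is below the direction's radius.
digitize_radial <- function(b, spec, center) {
  d <- spec$dims
  ax <- (seq_len(d[1]) - 1) * spec$spacing[1] - center[1]
  ay <- (seq_len(d[2]) - 1) * spec$spacing[2] - center[2]
  az <- (seq_len(d[3]) - 1) * spec$spacing[3] - center[3]
  X <- array(rep(ax, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ay, each = d[1]), times = d[3]), d)
  Z <- array(rep(az, each = d[1] * d[2]), d)
  R <- sqrt(X^2 + Y^2 + Z^2)
  Rsafe <- pmax(R, 1e-12)
  U <- cbind(as.vector(X / Rsafe), as.vector(Y / Rsafe), as.vector(Z / Rsafe))
  rho <- ellipsoid_radius(U, spec$semi_axes)
  for (m in seq_along(b)) {
    rho <- rho + b[m] * family_mode_basis[[m]](U)
  }
  inside <- array(as.vector(R) < rho, d)
  inside[R < 1e-12] <- TRUE
  label_volume(inside * 1, spacing = spec$spacing, origin = c(0, 0, 0))
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Analytic radius of a shape-family member
#'
#' Radius of the star-shaped family surface along unit directions, for a
#' given coefficient vector: the ground truth against which fitted meshes
#' can be measured. Uses the same unit-norm mode scaling as
#' [make_shape_family()].
#'
#' @param spec a [shape_family_spec()].
#' @param b coefficient vector (length `length(spec$mode_sd)`).
#' @param directions `n x 3` matrix of unit direction vectors.
#' @return Numeric vector of radii (mm).
#' @export
shape_family_radius <- function(spec, b, directions) {
  stopifnot(inherits(spec, "shape_family_spec"))
  M <- length(spec$mode_sd)
  stopifnot(length(b) == M)
  u <- normalize_rows(as.matrix(directions))
  rho <- ellipsoid_radius(u, spec$semi_axes)
  if (M > 0) {
    base_u <- normalize_rows(icosphere(spec$subdiv, radius = 1)$vertices)
    for (m in seq_len(M)) {
      scale_m <- sqrt(sum(family_mode_basis[[m]](base_u)^2))
      rho <- rho + b[m] * family_mode_basis[[m]](u) / scale_m
    }
  }
  rho
}

#' Single-voxel point-source edge map
#'
#' All-zero scalar grid with a single 1 at `location` (1-based voxel index);
#' the fixture for convolution sanity checks.
#'
#' @param dims grid dimensions (voxels).
#' @param location 1-based voxel index of the source.
#' @param spacing,origin grid metadata (mm).
#' @return An `edge_map` object (see [compute_edge_map()]).
#' @export
make_point_source_edge_map <- function(dims, location, spacing = c(1, 1, 1),
                                       origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  location <- as.integer(location)
  if (any(location < 1L) || any(location > dims)) {
    stop("'location' is outside the grid")
  }
  arr <- array(0, dims)
  arr[location[1], location[2], location[3]] <- 1
  structure(list(data = arr, spacing = as_point3(spacing, "spacing"),
                 origin = as_point3(origin, "origin"), sigma = 0),
            class = "edge_map")
}
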