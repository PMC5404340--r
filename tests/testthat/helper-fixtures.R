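# Shared fixtures built in code (no stored data).

# Regular tetrahedron with outward-oriented faces.
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# Simplex mesh of a perturbed sphere dual: generic non-symmetric geometry.
perturbed_sphere_simplex <- function(subdiv = 1, radius = 10, sd = 0.4,
                                     seed = 42) {
  sm <- dual_simplex_from_triangles(icosphere(subdiv, radius = radius))
  set.seed(seed)
  sm$vertices <- sm$vertices +
    matrix(rnorm(length(sm$vertices), 0, sd), ncol = 3)
  sm
}

# Radial distance from mesh vertices to an axis-aligned analytic ellipsoid.
ellipsoid_radial_gap <- function(vertices, center, semi_axes) {
  rel <- sweep(vertices, 2, center)
  rr <- sqrt(rowSums(rel^2))
  u <- rel / rr
  rho <- 1 / sqrt((u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
                    (u[, 3] / semi_axes[3])^2)
  rr - rho
}

# A tiny synthetic vfc_energy grid built directly from a function of the
# voxel centre, for controlled greedy tests.
energy_grid <- function(dims, fn, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  arr <- array(0, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) {
    i <- seq_len(dims[1])
    pts <- cbind(origin[1] + (i - 1) * spacing[1],
                 origin[2] + (j - 1) * spacing[2],
                 origin[3] + (k - 1) * spacing[3])
    arr[, j, k] <- fn(pts)
  }
  structure(list(energy = arr, max_energy = max(arr), spacing = spacing,
                 origin = origin), class = "vfc_energy")
}
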