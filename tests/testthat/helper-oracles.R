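# Independent brute-force oracles. These deliberately re-derive every
# quantity through different computational routes (linear solves, printed
# closed forms, plain loops) than the package implementation.

oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Circumcenter of a 3-D triangle by solving the equidistance system.
oracle_circumcircle <- function(p1, p2, p3) {
  nrm <- oracle_cross(p2 - p1, p3 - p1)
  nrm <- nrm / sqrt(sum(nrm^2))
  A <- rbind(2 * (p2 - p1), 2 * (p3 - p1), nrm)
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2), sum(nrm * p1))
  C <- solve(A, b)
  list(C = C, r = sqrt(sum((C - p1)^2)), n = nrm)
}

# Circumsphere of a tetrahedron by solving the 3x3 equidistance system.
oracle_circumsphere <- function(p, p1, p2, p3) {
  A <- rbind(2 * (p1 - p), 2 * (p2 - p), 2 * (p3 - p))
  b <- c(sum(p1^2) - sum(p^2), sum(p2^2) - sum(p^2), sum(p3^2) - sum(p^2))
  O <- solve(A, b)
  list(O = O, R = sqrt(sum((O - p)^2)))
}

# Simplex angle of vertex p over neighbors (continuous convention), via the
# explicit circumsphere solve.
oracle_simplex_angle <- function(p, p1, p2, p3) {
  cc <- oracle_circumcircle(p1, p2, p3)
  y <- sum((p - cc$C) * cc$n)
  if (abs(y) < 1e-14) return(0)
  sp <- oracle_circumsphere(p, p1, p2, p3)
  z <- sum((sp$O - cc$C) * cc$n)
  sign(y) * atan2(cc$r, -z * sign(y))
}

# Height from (r, d, phi) by the printed tangent closed form (r^2 under the
# radical), the formula the stable package expression must agree with.
oracle_height <- function(r, d, phi) {
  if (abs(sin(phi)) < 1e-14) return(0)
  if (abs(abs(phi) - pi / 2) < 1e-12) {
    return(sign(sin(phi)) * sqrt(r^2 - d^2))
  }
  eps <- if (abs(phi) < pi / 2) 1 else -1
  tp <- tan(phi)
  # the radicand is a squared quantity for realizable (r, d, phi); guard the
  # tiny negative values roundoff can produce when d > r
  (r^2 - d^2) * tp / (eps * sqrt(max(r^2 + (r^2 - d^2) * tp^2, 0)) + r)
}

# Plain-loop trilinear interpolation with the out-of-volume saturation rule.
oracle_sample_external <- function(ev, p) {
  d <- dim(ev$energy)
  q <- (p - ev$origin) / ev$spacing
  if (any(q < 0) || any(q > d - 1)) return(ev$max_energy)
  i0 <- pmin(floor(q), d - 2)
  f <- q - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    acc <- acc + wgt * ev$energy[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  ev$max_energy - acc
}

# Exhaustive window search: the full greedy step re-implemented with plain
# loops; returns the updated vertex matrix.
oracle_greedy_step <- function(mesh, ev, params) {
  v <- mesh$vertices
  nv <- nrow(v)
  half <- (params$w - 1) / 2
  # reference angles from the pre-step mesh
  phis <- vapply(seq_len(nv), function(i) {
    nb <- mesh$neighbors[i, ]
    oracle_simplex_angle(v[i, ], v[nb[1], ], v[nb[2], ], v[nb[3], ])
  }, 0)
  newv <- v
  for (i in seq_len(nv)) {
    nb <- mesh$neighbors[i, ]
    p <- v[i, ]
    p1 <- v[nb[1], ]; p2 <- v[nb[2], ]; p3 <- v[nb[3], ]
    cc <- oracle_circumcircle(p1, p2, p3)
    cg <- (p1 + p2 + p3) / 3
    phi_ref <- mean(phis[nb])
    vox_ctr <- ev$origin + round((p - ev$origin) / ev$spacing) * ev$spacing
    cand <- list()
    for (dz in -half:half) for (dy in -half:half) for (dx in -half:half) {
      cand[[length(cand) + 1L]] <- vox_ctr + c(dx, dy, dz) * ev$spacing
    }
    # NOTE: candidate enumeration order must match the package (x fastest)
    cand[[length(cand) + 1L]] <- p
    e_int <- e_ext <- numeric(length(cand))
    for (k in seq_along(cand)) {
      pc <- cand[[k]]
      y <- sum((pc - cc$C) * cc$n)
      Fp <- pc - y * cc$n
      d <- sqrt(sum((Fp - cc$C)^2))
      # candidate height enters the normal term directly (equals its
      # closed-form L wherever the form is single-valued)
      e_int[k] <- sum((cg - Fp)^2) +
        (oracle_height(cc$r, d, phi_ref) - y)^2
      e_ext[k] <- oracle_sample_external(ev, pc)
    }
    norm01 <- function(x) {
      if (max(x) - min(x) <= 0) return(rep(0, length(x)))
      (x - min(x)) / (max(x) - min(x))
    }
    score <- params$alpha * norm01(e_int) + params$beta * norm01(e_ext)
    best <- which(score == min(score))
    if (length(best) > 1L) {
      dd <- vapply(best, function(k) sum((cand[[k]] - p)^2), 0)
      best <- best[which.min(dd)]
    } else {
      best <- best[1]
    }
    q <- cand[[best]]
    newv[i, ] <- p + sum((q - p) * cc$n) * cc$n
  }
  newv
}

# 3-D numerical quadrature of the transformation-dependent L2 objective on a
# regular grid (trapezoid on a smooth decaying integrand is spectrally
# accurate; extent covers all component means by many standard deviations).
oracle_l2_quadrature <- function(f, g, T, h = 0.5, pad = 9) {
  mu <- sweep(f$means %*% t(T$A), 2, T$t, "+")
  smax <- max(f$scale, g$scale)
  allm <- rbind(mu, g$means)
  lo <- apply(allm, 2, min) - pad * smax
  hi <- apply(allm, 2, max) + pad * smax
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  dens <- function(px, py, pz, means, wts, s) {
    out <- 0
    for (i in seq_len(nrow(means))) {
      d2 <- (px - means[i, 1])^2 + (py - means[i, 2])^2 + (pz - means[i, 3])^2
      out <- out + wts[i] * exp(-d2 / (2 * s^2)) / ((2 * pi)^1.5 * s^3)
    }
    out
  }
  total <- 0
  xy <- expand.grid(x = gx, y = gy)
  for (zz in gz) {
    fv <- dens(xy$x, xy$y, zz, mu, f$weights, f$scale)
    gv <- dens(xy$x, xy$y, zz, g$means, g$weights, g$scale)
    total <- total + sum(fv^2 - 2 * fv * gv) * h^3
  }
  total
}

# Direct (shift-and-add) linear convolution: independent of the FFT route.
oracle_convolve3 <- function(arr, ker) {
  d <- dim(arr)
  R <- (dim(ker)[1] - 1) / 2
  out <- array(0, d)
  for (dx in -R:R) for (dy in -R:R) for (dz in -R:R) {
    wgt <- ker[dx + R + 1, dy + R + 1, dz + R + 1]
    if (wgt == 0) next
    sx <- seq_len(d[1]) - dx; sy <- seq_len(d[2]) - dy; sz <- seq_len(d[3]) - dz
    okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[okx, oky, okz] <- out[okx, oky, okz] +
      wgt * arr[sx[okx], sy[oky], sz[okz]]
  }
  out
}

# Brute-force specificity: plain-loop re-implementation with the same draw
# protocol (seeded uniform coefficients, nearest training shape).
oracle_specificity <- function(model, shapes, M, n_samples, seed) {
  set.seed(seed)
  lim <- if (M > 0) 3 * sqrt(model$eigenvalues[seq_len(M)]) else numeric(0)
  N <- length(model$mean) / 3
  B <- matrix(runif(n_samples * M, -1, 1), n_samples, M)
  dists <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    x <- model$mean
    for (m in seq_len(M)) x <- x + B[j, m] * lim[m] * model$modes[, m]
    best <- Inf
    for (k in seq_along(shapes)) {
      best <- min(best, sum((x - shapes[[k]])^2))
    }
    dists[j] <- sqrt(best / N)
  }
  c(mean = mean(dists), sd = sd(dists))
}
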