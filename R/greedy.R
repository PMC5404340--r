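#' Evolution parameters for the greedy deformable simplex mesh
#'
#' @param alpha non-negative internal-energy weight.
#' @param beta non-negative external-energy weight (`0` gives pure internal
#'   relaxation); `alpha + beta` must be positive.
#' @param w odd cubic window width in voxels (`>= 3`).
#' @param max_iters iteration cap.
#' @param move_tol convergence threshold on the maximum per-vertex
#'   displacement (mm).
#' @param log_every print the displacement every this many iterations
#'   (`0` disables logging).
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(alpha = 0.4, beta = 1.0, w = 11,
                             max_iters = 200, move_tol = 0.1, log_every = 0) {
  w <- as.integer(w)
  if (w < 3L || w %% 2L == 0L) stop("'w' must be odd and >= 3")
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    stop("'alpha' and 'beta' must be >= 0 with a positive sum")
  }
  structure(list(alpha = alpha, beta = beta, w = w,
                 max_iters = as.integer(max_iters), move_tol = move_tol,
                 log_every = as.integer(log_every)),
            class = "evolution_params")
}

# Per-vertex quantities that stay fixed while scoring that vertex's window
# candidates: neighbor positions, circumcircle, oriented plane normal,
# neighbor centroid and the reference simplex angle (mean of the three
# neighbors' angles on the current mesh).
vertex_frame <- function(mesh) {
  v <- mesh$vertices
  nb <- mesh$neighbors
  p1 <- v[nb[, 1], , drop = FALSE]
  p2 <- v[nb[, 2], , drop = FALSE]
  p3 <- v[nb[, 3], , drop = FALSE]
  cc <- circumcircle3(p1, p2, p3)
  nrm <- normalize_rows(cross3(p2 - p1, p3 - p1))
  phi <- simplex_angles(mesh)
  phi_ref <- (phi[nb[, 1]] + phi[nb[, 2]] + phi[nb[, 3]]) / 3
  list(p1 = p1, p2 = p2, p3 = p3, C = cc$C, r = cc$r,
       degenerate = cc$degenerate, n = nrm,
       centroid = (p1 + p2 + p3) / 3, phi_ref = phi_ref)
}

# Raw internal energy of candidate positions `cand` (k x 3) for vertex i
# given its frozen frame: tangential term ||centroid - F||^2 plus normal
# term (L(r, d, phi_ref) - L(r, d, phi_cand))^2.
internal_energy_candidates <- function(frame, i, cand) {
  if (frame$degenerate[i]) return(rep(Inf, nrow(cand)))
  C <- frame$C[i, ]; r <- frame$r[i]; nrm <- frame$n[i, ]
  rel <- sweep(cand, 2, C, "-")
  y <- as.vector(rel %*% nrm)
  Fp <- cand - outer(y, nrm)
  dC <- sweep(Fp, 2, C, "-")
  d <- sqrt(rowSums(dC * dC))
  tang <- sweep(Fp, 2, frame$centroid[i, ], "-")
  e_t <- rowSums(tang * tang)
  # normal term: deviation of the candidate height from the height the
  # reference angle prescribes. The candidate's L(r, d, phi_cand) is its
  # signed height y itself (the closed form agrees wherever it is
  # single-valued, and y stays smooth where the d > r branch of the closed
  # form would jump)
  Lref <- simplex_height(r, d, frame$phi_ref[i])
  e_n <- (Lref - y)^2
  e_t + e_n
}

#' Internal regularization energy at a candidate vertex position
#'
#' Evaluates the simplex-mesh internal energy for vertex `i` with its
#' position replaced by `candidate` and its neighbors frozen at their
#' current positions: a tangential term pulling the tangent-plane
#' projection toward the neighbor centroid (uniform vertex spacing) and a
#' normal term pulling the vertex height toward the height implied by the
#' mean of the neighbors' simplex angles (local smoothness).
#'
#' @param mesh a `simplex_mesh`.
#' @param i vertex index.
#' @param candidate length-3 candidate position (mm).
#' @return Scalar energy (mm^2); `Inf` for a degenerate neighbor triangle.
#' @export
internal_energy <- function(mesh, i, candidate) {
  frame <- vertex_frame(mesh)
  internal_energy_candidates(frame, i, matrix(as_point3(candidate), ncol = 3))[1]
}

# Window candidate positions for vertex i: the w^3 voxel centres around the
# voxel containing P_i, plus P_i itself as the last row.
window_candidates <- function(p, ev, w) {
  half <- (w - 1L) / 2L
  vox <- round((p - ev$origin) / ev$spacing)
  offs <- as.matrix(expand.grid(x = -half:half, y = -half:half, z = -half:half))
  ctr <- ev$origin + vox * ev$spacing
  rbind(sweep(offs %*% diag(ev$spacing), 2, ctr, "+"), p)
}

#' Combined candidate scores within a search window
#'
#' Scores every candidate position in vertex `i`'s cubic window: raw
#' internal and external energies are each min-max normalized to `[0, 1]`
#' across the window (a constant set normalizes to zeros) and combined as
#' `alpha * E_int + beta * E_ext`. The external raw energy is the negated
#' sampled VFC magnitude: the convolved-field magnitude of a closed edge
#' sheet crests at the sheet, so its negation makes edge voxels energy
#' minima for the greedy argmin.
#'
#' @param mesh a `simplex_mesh`.
#' @param i vertex index.
#' @param ev a `vfc_energy`.
#' @param params an [evolution_params()].
#' @param candidates optional candidate matrix; defaults to the `w^3` voxel
#'   centres around the voxel containing the vertex, plus the current
#'   position as the final row.
#' @return A list with `candidates`, `score`, `e_int`, `e_ext` (raw
#'   energies).
#' @export
candidate_energy <- function(mesh, i, ev, params, candidates = NULL) {
  frame <- vertex_frame(mesh)
  if (is.null(candidates)) {
    candidates <- window_candidates(mesh$vertices[i, ], ev, params$w)
  }
  e_int <- internal_energy_candidates(frame, i, candidates)
  e_ext <- sample_external_energy(ev, candidates)
  score <- params$alpha * minmax01(e_int) + params$beta * minmax01(e_ext)
  list(candidates = candidates, score = score, e_int = e_int, e_ext = e_ext)
}

minmax01 <- function(x) {
  fin <- is.finite(x)
  if (!any(fin)) return(rep(0, length(x)))
  mn <- min(x[fin]); mx <- max(x[fin])
  if (mx <= mn) {
    out <- numeric(length(x))
    out[!fin] <- Inf
    return(out)
  }
  out <- (x - mn) / (mx - mn)
  out[!fin] <- Inf
  out
}

# argmin with deterministic tie-breaks: smallest distance to the current
# position, then lowest candidate index.
argmin_candidate <- function(score, cand, p) {
  mn <- min(score)
  ties <- which(score == mn)
  if (length(ties) == 1L) return(ties)
  dd <- rowSums(sweep(cand[ties, , drop = FALSE], 2, p, "-")^2)
  ties[which.min(dd)]
}

#' One synchronous greedy evolution step
#'
#' For every vertex, scores the window candidates ([candidate_energy()]),
#' takes the minimum-score candidate `Q_i`, and moves the vertex along its
#' outward normal only: `P_i <- P_i + ((Q_i - P_i) . n_i) n_i`. All updates
#' are computed from the pre-step mesh, so the result is independent of
#' vertex order.
#'
#' @param mesh a `simplex_mesh`.
#' @param ev a `vfc_energy`.
#' @param params an [evolution_params()].
#' @return A list with `mesh` (updated) and `max_displacement` (mm).
#' @export
greedy_step <- function(mesh, ev, params) {
  frame <- vertex_frame(mesh)
  v <- mesh$vertices
  n <- nrow(v)
  half <- (params$w - 1L) / 2L
  offs <- as.matrix(expand.grid(x = -half:half, y = -half:half,
                                z = -half:half)) %*% diag(ev$spacing)
  disp <- numeric(n)
  newv <- v
  for (i in seq_len(n)) {
    p <- v[i, ]
    ctr <- ev$origin + round((p - ev$origin) / ev$spacing) * ev$spacing
    cand <- rbind(sweep(offs, 2, ctr, "+"), p)
    e_int <- internal_energy_candidates(frame, i, cand)
    e_ext <- sample_external_energy(ev, cand)
    score <- params$alpha * minmax01(e_int) + params$beta * minmax01(e_ext)
    qi <- cand[argmin_candidate(score, cand, p), ]
    step <- sum((qi - p) * frame$n[i, ]) * frame$n[i, ]
    newv[i, ] <- p + step
    disp[i] <- vnorm(step)
  }
  mesh$vertices <- newv
  list(mesh = mesh, max_displacement = max(disp))
}

#' Evolve a simplex mesh to convergence
#'
#' Iterates [greedy_step()] until the maximum vertex displacement drops
#' below `move_tol` or `max_iters` is reached. Aborts with a diagnostic if
#' the displacement grows for 10 consecutive iterations (divergence).
#'
#' @param mesh the initialized `simplex_mesh`.
#' @param ev the precomputed `vfc_energy` of the target volume.
#' @param params an [evolution_params()].
#' @return A list with `mesh` (final) and `report` (class
#'   `evolution_report`: `iterations`, `displacements`, `converged`).
#' @export
evolve <- function(mesh, ev, params = evolution_params()) {
  stopifnot(inherits(mesh, "simplex_mesh"), inherits(ev, "vfc_energy"),
            inherits(params, "evolution_params"))
  disps <- numeric(0)
  growing <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iters)) {
    res <- greedy_step(mesh, ev, params)
    mesh <- res$mesh
    disps <- c(disps, res$max_displacement)
    if (params$log_every > 0 && it %% params$log_every == 0L) {
      message(sprintf("iteration %d: max displacement %.4f mm", it,
                      res$max_displacement))
    }
    if (res$max_displacement < params$move_tol) {
      converged <- TRUE
      break
    }
    nd <- length(disps)
    # material growth only: voxel-scale flip-flop cycles jitter up and down
    # by a few percent without diverging
    growing <- if (nd > 1 && disps[nd] > 1.05 * disps[nd - 1]) {
      growing + 1L
    } else {
      0L
    }
    if (growing >= 10L) {
      stop(sprintf(
        "evolution diverging: displacement grew for 10 consecutive iterations (last %.3f mm)",
        res$max_displacement))
    }
  }
  report <- structure(list(iterations = length(disps), displacements = disps,
                           converged = converged),
                      class = "evolution_report")
  list(mesh = mesh, report = report)
}

#' @export
print.evolution_report <- function(x, ...) {
  cat(sprintf("evolution_report: %d iterations, %s (last displacement %.4g mm)\n",
              x$iterations,
              if (x$converged) "converged" else "not converged",
              utils::tail(x$displacements, 1)))
  invisible(x)
}
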