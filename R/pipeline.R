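#' Pipeline configuration
#'
#' Collects every tunable parameter of the model-construction workflow with
#' the package defaults, validates it, and returns it as a plain list that
#' can be serialized to YAML alongside the outputs.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # surface extraction
    iso_level = 0.5, smooth_iterations = 20, smooth_passband = 0.1,
    decimate_target = 2500,
    # GMM initialization
    gmm_scale_mm = NULL, gmm_max_components = 1000,
    # VFC energy
    vfc_sigma = 1, vfc_R = 256, vfc_gamma = 1.7, vfc_eps_div = 1e-8,
    vfc_magnitude = "m1", vfc_zeta = 2,
    # greedy evolution
    alpha = 0.4, beta = 1.0, w = 11, max_iters = 200, move_tol = 0.1,
    # model building / evaluation
    gpa_scaling = FALSE, metric_modes = NULL, n_specificity_samples = 1000,
    seed = 1,
    # io
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$beta > 0, cfg$w >= 3, cfg$w %% 2 == 1,
            cfg$vfc_R >= 1, cfg$iso_level > 0, cfg$iso_level < 1,
            cfg$decimate_target >= 4)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Construct a statistical shape model from binary training volumes
#'
#' The full correspondence-and-model workflow: each volume is surfaced
#' (isosurface, low-pass smoothing, decimation, dualization to a simplex
#' mesh); one sample is selected as the template (minimum summed
#' post-registration Gaussian-mixture L2 objective); the template is
#' affinely initialized on every other sample and evolved under the greedy
#' internal + VFC energy scheme; the corresponded landmark sets are aligned
#' by generalized Procrustes analysis; a PCA shape model is built and the
#' three quality metrics evaluated. Deterministic for a fixed configuration.
#'
#' @param volumes list of [label_volume()] objects (or paths readable by
#'   [read_label_volume()]).
#' @param config a [pipeline_config()].
#' @return A list of class `ssm_pipeline_result` with `template_index`,
#'   `fitted` (list of fitted simplex meshes), `aligned` (aligned shape
#'   vectors), `model` (`shape_model`), `metrics` (data frame),
#'   `reports` (per-target evolution reports) and the resolved `config`.
#' @export
run_pipeline <- function(volumes, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(volumes)) volumes <- lapply(volumes, read_label_volume)
  K <- length(volumes)
  if (K < 2L) stop("need at least 2 training volumes")
  for (i in seq_len(K)) {
    if (!inherits(volumes[[i]], "label_volume")) {
      stop("input ", i, " is not a binary label volume")
    }
  }
  stage <- function(name, i, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed on input %s: %s",
                   name, i, conditionMessage(e)), call. = FALSE)
    })
  }

  simplexes <- vector("list", K)
  for (i in seq_len(K)) {
    simplexes[[i]] <- stage("surface_extraction", i, {
      tri <- extract_surface(volumes[[i]], level = config$iso_level)
      tri <- smooth_mesh(tri, iterations = config$smooth_iterations,
                         passband = config$smooth_passband)
      if (nrow(tri$faces) > config$decimate_target) {
        tri <- decimate_mesh(tri, config$decimate_target)
      }
      dual_simplex_from_triangles(tri)
    })
  }

  tmpl_idx <- stage("template_selection", "all", {
    select_template(simplexes, scale = config$gmm_scale_mm,
                    max_components = config$gmm_max_components)
  })
  template <- simplexes[[tmpl_idx]]
  tmpl_gmm <- mesh_to_gmm(template, scale = config$gmm_scale_mm,
                          max_components = config$gmm_max_components)

  fitted <- vector("list", K)
  reports <- vector("list", K)
  params <- evolution_params(alpha = config$alpha, beta = config$beta,
                             w = config$w, max_iters = config$max_iters,
                             move_tol = config$move_tol)
  for (i in seq_len(K)) {
    init_mesh <- if (i == tmpl_idx) template else stage("gmm_init", i, {
      tgt_gmm <- mesh_to_gmm(simplexes[[i]], scale = config$gmm_scale_mm,
                             max_components = config$gmm_max_components)
      reg <- register_affine(tmpl_gmm, tgt_gmm)
      apply_affine(template, reg$transform)
    })
    ev <- stage("vfc_energy", i, {
      vfc_energy_for_volume(volumes[[i]], sigma = config$vfc_sigma,
                            R = config$vfc_R, gamma = config$vfc_gamma,
                            eps_div = config$vfc_eps_div,
                            magnitude_kind = config$vfc_magnitude,
                            zeta = config$vfc_zeta)
    })
    res <- stage("greedy_evolution", i, evolve(init_mesh, ev, params))
    fitted[[i]] <- res$mesh
    reports[[i]] <- res$report
  }

  shapes <- lapply(fitted, as_shape_vector)
  gpa <- stage("gpa", "all", gpa_align(shapes, with_scaling = config$gpa_scaling))
  model <- stage("model", "all", build_model(gpa$aligned))
  modes <- config$metric_modes %||% seq_len(max(model$c, 1L))
  modes <- modes[modes <= length(model$eigenvalues)]
  metrics <- if (length(modes) > 0) {
    stage("metrics", "all", metric_curves(
      model, gpa$aligned, modes = modes,
      n_samples = config$n_specificity_samples, seed = config$seed))
  } else {
    data.frame()
  }

  result <- structure(list(
    template_index = tmpl_idx, fitted = fitted, aligned = gpa$aligned,
    model = model, metrics = metrics, reports = reports, config = config),
    class = "ssm_pipeline_result")
  if (!is.null(config$out_dir)) save_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.ssm_pipeline_result <- function(x, ...) {
  cat(sprintf("ssm_pipeline_result: K = %d shapes, template = sample %d\n",
              length(x$fitted), x$template_index))
  print(x$model)
  invisible(x)
}

# Persist every stage output plus the resolved configuration.
save_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(result$config), file.path(out_dir, "config.yaml"))
  for (i in seq_along(result$fitted)) {
    write_simplex_mesh(result$fitted[[i]],
                       file.path(out_dir, sprintf("fitted_%03d.ply", i)))
  }
  write_shape_model(result$model, file.path(out_dir, "model.ssm.json"))
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Per-landmark variance map of a shape model
#'
#' Attaches the total per-landmark variance, `sum_m lambda_m *
#' ||mode m at landmark||^2`, to the mean mesh as a scalar attribute
#' (`attr(mesh, "variance")`); the attribute sums to the total model
#' variance. Intended for export and external rendering of where on the
#' surface the population varies.
#'
#' @param model a `shape_model`.
#' @param mean_mesh a `simplex_mesh` with `model$N` vertices (typically the
#'   mean shape rebuilt on the template connectivity).
#' @return The mesh with a `"variance"` attribute (length `N`).
#' @export
export_variation_map <- function(model, mean_mesh) {
  stopifnot(inherits(model, "shape_model"), inherits(mean_mesh, "simplex_mesh"))
  if (nrow(mean_mesh$vertices) != model$N) {
    stop("mesh landmark count does not match the model")
  }
  v <- numeric(model$N)
  if (length(model$eigenvalues) > 0) {
    for (m in seq_along(model$eigenvalues)) {
      comp <- matrix(model$modes[, m], ncol = 3L, byrow = TRUE)
      v <- v + model$eigenvalues[m] * rowSums(comp^2)
    }
  }
  attr(mean_mesh, "variance") <- v
  mean_mesh
}
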