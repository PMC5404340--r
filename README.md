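# ssmesh — statistical shape models from deformable 2-simplex meshes

`ssmesh` builds point-correspondence statistical shape models (SSMs) from
binary segmentation volumes, fully automatically. It is aimed at medical /
biological image analysts who have a set of segmented training structures
(e.g. bones from CT) and want a PCA shape model — mean shape, modes of
variation, eigenvalues — without manual landmarking.

## The method

Correspondence is established by mesh-to-volume registration: a single
template mesh is fitted to every training volume, so each template vertex
becomes a landmark with the same identity in every sample.

1. **Surfacing.** Each binary volume is isosurfaced (watertight tetrahedral
   marching), low-pass smoothed, decimated to the landmark budget, and
   converted to a **2-simplex mesh** — the triangle-mesh dual in which every
   vertex has exactly 3 neighbors. A vertex is encoded exactly by its
   barycentric *metric parameters* (ε₁, ε₂, ε₃) in the neighbor triangle and
   its *simplex angle* φ, with local mean curvature H = sin(φ)/r.
2. **Template choice & initialization.** The sample closest (in summed
   post-registration Gaussian-mixture L2 distance) to all others is the
   template; it is affinely registered (A = QS, quasi-Newton on the
   closed-form mixture-L2 objective with analytic gradients) to each target
   as the starting shape.
3. **Greedy evolution with VFC energy.** The external energy is the
   magnitude of the **vector field convolution** (VFC) of the target's edge
   map with a power-law vector kernel, precomputed once per volume. Each
   iteration scores the w³ voxel window around every vertex with
   window-normalized internal (tangential + normal simplex regularizers)
   plus external energy, E = αE_int + βE_ext (defaults α = 0.4, β = 1.0,
   w = 11), and moves the vertex along its normal toward the best candidate.
4. **Model building.** Fitted landmark sets are aligned by generalized
   Procrustes analysis (no scaling, units stay mm) and eigen-decomposed
   (Gram dual when 3N > K); modes are retained up to a cumulative variance
   fraction > 0.98. Model quality is reported by the standard triad:
   compactness C(M) = Σλₘ, leave-one-out generalization, and Monte-Carlo
   specificity.

Everything is deterministic given the configuration and seeds.

## Worked example

Build a model from a synthetic four-member shape family with known ground
truth (a star-shaped ellipsoid family with two smooth deformation modes):

```r
library(ssmesh)

fam <- make_shape_family(shape_family_spec(
  K = 4, seed = 42, semi_axes = c(12, 10, 8), mode_sd = c(6, 3),
  dims = c(44, 44, 44)))

cfg <- pipeline_config(decimate_target = 400, smooth_iterations = 10,
                       w = 5, max_iters = 40, gmm_max_components = 200,
                       n_specificity_samples = 500, metric_modes = 1:2,
                       seed = 7)
result <- run_pipeline(fam$volumes, cfg)
print(result)
#> ssm_pipeline_result: K = 4 shapes, template = sample 3
#> shape_model: K = 4 training shapes, N = 400 landmarks, 3 modes (c = 3 retained at 98%)

print(result$metrics[, c("metric", "M", "mean", "sd", "units")], digits = 3)
#>           metric M    mean     sd                 units
#> 1    compactness 1  88.229     NA                  mm^2
#> 2 generalization 1   0.504 0.0634 mm (rms per landmark)
#> 3    specificity 1   0.415 0.1942 mm (rms per landmark)
#> 4    compactness 2 109.005     NA                  mm^2
#> 5 generalization 2   0.501 0.0622 mm (rms per landmark)
#> 6    specificity 2   0.514 0.2323 mm (rms per landmark)
```

Reading the output: the four fitted meshes share the template's 400 vertex
identities (the correspondence), the model keeps 3 modes to pass 98%
cumulative variance, and unseen-shape reconstruction (generalization) and
sampled-shape validity (specificity) both sit around half a millimetre per
landmark for this family. `synthesize(result$model, b)` generates new
shapes with coefficients clamped to ±3√λₘ; `export_variation_map()`
attaches per-landmark variance to the mean mesh for rendering.

A thin command-line wrapper for volume files is provided at
`inst/cli/ssmesh-pipeline.R`
(`Rscript ssmesh-pipeline.R --volumes a.nii.gz,b.nii.gz --out run/`).

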