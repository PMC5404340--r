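---
title: "Building statistical shape models with deformable simplex meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building statistical shape models with deformable simplex meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmesh)
```

## The problem

Point-correspondence statistical shape models (SSMs) summarize a population
of segmented anatomical structures as a mean shape plus principal modes of
variation. The hard part is never the PCA: it is placing the *same* landmark
on the *same* anatomical location of every training sample. `ssmesh`
implements a mesh-to-volume strategy: one template mesh is fitted to every
binary training volume by a deformable-model evolution, so the template's
vertex identities carry the correspondence.

The deformable surface is a **2-simplex mesh** — the topological dual of a
triangle mesh, in which every vertex has exactly three neighbors. This
connectivity gives each vertex a canonical local frame: its three neighbors
span a tangent plane, and the vertex is encoded exactly by three barycentric
"metric parameters" of its tangent-plane projection plus a signed **simplex
angle** that fixes its height through the circumscribed circle (radius $r$,
center $C$) of the neighbor triangle and the circumscribed sphere of the
vertex tetrahedron. The local mean curvature is $H = \sin(\varphi)/r$.

## Per-vertex geometry and its numerical treatment

For neighbors $P_{N_1}, P_{N_2}, P_{N_3}$ and projection $F$ with offset
$d = \lVert F - C\rVert$, the height of the vertex over the tangent plane is

$$L(r, d, \varphi) =
  \frac{(r^2 - d^2)\tan\varphi}
       {\varepsilon\sqrt{r^2 + (r^2 - d^2)\tan^2\varphi} + r},
\qquad \varepsilon = \begin{cases} +1 & |\varphi| < \pi/2 \\ -1 & |\varphi| > \pi/2,\end{cases}$$

which `simplex_height()` evaluates through an equivalent sine/cosine
rearrangement, $L = (r^2-d^2)\sin\varphi \,/\,
(\sqrt{r^2\cos^2\varphi + (r^2-d^2)\sin^2\varphi} + r\cos\varphi)$ (with a
rationalized twin on the $\cos\varphi < 0$ branch), so the expression stays
finite and exact at $|\varphi| = \pi/2$ and avoids cancellation.

Two conventions matter and are worth stating because they are easy to get
wrong:

* **Angle continuity.** The sign factor in the cosine definition of the
  simplex angle is evaluated with the plane normal oriented *toward the
  vertex*. Only this reading makes the angle continuous through flat
  configurations (a shallow dimple gets a small negative angle, not an angle
  near $-\pi$) and makes the closed form above an exact inverse of the
  construction on every branch — the package's round-trip test reconstructs
  vertex positions to $10^{-9}$ mm from `(eps, phi, neighbors)`.
* **The $d > r$ ambiguity.** When a vertex's projection falls outside the
  neighbor circumcircle, two different heights produce identical
  $(r, d, \varphi)$, so the closed form is two-valued. `vertex_geometry()`
  therefore stores the true signed height in its `L` field (identical to the
  closed form in every regular configuration), and the internal energy and
  `reconstruct_position()` use it where the formula would jump.

## Template construction and initialization

Each binary volume is surfaced by a 6-tetrahedra (Kuhn) decomposition
marcher (`extract_surface()`), which produces a watertight, consistently
oriented triangle mesh on binary data without case-table ambiguities, then
low-pass (Taubin) smoothed — two-coefficient $\lambda/\mu$ steps, so the
enclosed volume shrinks by well under 2% — and decimated by link-condition
shortest-edge collapses to the configured landmark budget (default 2,500
faces, i.e. 2,500 simplex vertices after dualization at triangle
centroids).

The template is the training sample whose Gaussian-mixture L2 distance to
all other samples, after affine registration, is smallest
(`select_template()`). Registration represents each mesh as an isotropic
Gaussian mixture (one component per vertex, uniform weights, shared scale
defaulting to the mean edge length) and minimizes the transformation-
dependent part of the L2 distance
$\int f_{A,t}^2 - 2\int f_{A,t}\,g$ over the affine map $A = QS$
(rotation-vector and log-Cholesky parametrization keeps $Q$ orthogonal and
$S$ symmetric positive definite). Both integrals have closed Gaussian-
product forms; the implementation supplies the analytic gradient in
$(A, t)$ chained through the parametrization, which makes the BFGS search
roughly an order of magnitude faster than finite differences at identical
optima. Components can be deterministically subsampled (`max_components`)
to bound the $O(mn)$ pairwise cost.

## External energy: vector field convolution

The edge map is the gradient magnitude of the (optionally Gaussian-blurred,
default $\sigma = 1$ voxel) binary volume, min–max normalized to $[0, 1]$.
It is convolved — zero-padded linear convolution via FFT, verified against
direct spatial convolution to $10^{-10}$ — with a vector kernel whose
vectors point toward the kernel origin with power-law magnitude
$m_1 = (r + \varepsilon)^{-\gamma}$ (defaults $\gamma = 1.7$,
$\varepsilon = 10^{-8}$, radius $R = 256$ capped at the volume extent; the
Gaussian magnitude $m_2$ is available). The voxelwise field magnitude
$\lVert v\rVert$ is the precomputed external-energy volume, sampled by
trilinear interpolation; positions outside the grid receive the maximal
energy so the mesh cannot leave the volume.

A point worth understanding before trusting any fit: **for a closed surface
in 3-D the magnitude crest sits slightly outside the surface.** The far
side of a closed edge sheet pulls inward everywhere, which adds
constructively just outside the sheet and destructively just inside; with
$\gamma = 1.7$ — below the 3-D shell-theorem critical exponent of 2 — the
interior field in fact points toward the object centre everywhere, so the
raw magnitude has its minimum at the *centre*, not on the edge. The greedy
evolution therefore minimizes the *negated* magnitude (implemented as
`max_energy` $- \lVert v\rVert$, so the out-of-volume rule stays a
penalty). The remaining consequence is a systematic outward offset of the
converged surface of about 1.5–2.5 voxels at desk scale (measured on
digitized spheres and ellipsoids; roughly 1.5 voxels even for $\gamma = 3$
or an unblurred edge map). Because the offset is common to all training
samples it barely affects the cross-sample consistency that the SSM quality
metrics measure, but absolute surface placement is biased by that amount —
a genuine limitation of magnitude-crest seeking that users of the fitted
meshes as segmentations should know about.

## Greedy evolution

Per iteration and per vertex, the candidate set is the $w^3$ voxel centres
(default $w = 11$) of the cubic window around the vertex's containing
voxel, plus the current continuous position (so "stay" is always
available and sub-voxel equilibria exist). Raw internal and external
energies are each min–max normalized over the window — constant sets
normalize to zeros, making the weights $\alpha = 0.4$, $\beta = 1.0$
scale-free — and combined as $\alpha E_{int} + \beta E_{ext}$. The internal
energy is the classical simplex-mesh regularizer: a tangential term
$\lVert \frac13\sum P_{N_k} - F\rVert^2$ that uniformizes vertex spacing
and a normal term $(L(r, d, \tilde\varphi) - L(r, d, \varphi))^2$ with
$\tilde\varphi$ the mean of the three neighbors' simplex angles (a local
smoothness prior). Neighbors are frozen at their pre-step positions and all
updates are computed synchronously, so the result is independent of vertex
order; the winning candidate moves the vertex along its normal only,
$P \leftarrow P + ((Q - P)\cdot n)\,n$, with ties broken toward the nearest
candidate and then the lowest index.

Iteration stops when the maximum displacement falls below `move_tol`
(default 0.1 voxel) or after `max_iters` (default 200). Two empirical
behaviors are documented by tests rather than idealized away: a handful of
vertices can settle into a bounded voxel-scale flip-flop between two
adjacent candidates (the run then ends at `max_iters` with a stable mesh
and `converged = FALSE`), and a divergence guard aborts only on *material*
growth (>5% per iteration for ten consecutive iterations), since limit
cycles jitter by fractions of a percent. Because movement is normal-only,
pure internal relaxation ($\beta = 0$) homogenizes the simplex angles and
rounds a jittered sphere but leaves tangential spacing essentially frozen —
the tangential term only matters jointly with the external attraction.

## Model building and quality metrics

Fitted landmark sets are aligned by generalized Procrustes analysis —
scaling off by default so everything stays in mm — and summarized by PCA
with the $1/(K-1)$ covariance, computed through the $K \times K$ Gram dual
when $3N > K$. The retained-mode count $c$ is the smallest $t$ with
cumulative eigenvalue fraction strictly above 0.98; eigenvector signs are
fixed by making each mode's largest component positive. Synthesis clamps
coefficients to $\pm 3\sqrt{\lambda_m}$; held-out reconstruction uses the
orthonormal projection $b_m = \phi_m^\top(x - \bar x)$.

The quality triad follows the standard definitions: compactness
$C(M) = \sum_{m \le M}\lambda_m$; generalization, the leave-one-out
reconstruction error with the held-out shape rigidly re-aligned to the
leave-one-out mean first (optional — the re-alignment itself moves an
exactly-linear family slightly off its own span, so subspace tests disable
it); and specificity, the seeded Monte-Carlo distance from sampled shapes
(coefficients uniform in $\pm 3\sqrt{\lambda_m}$) to their nearest training
shape by exact linear scan. Although these error definitions are squared
norms, results are reported by default as the root-mean
per-landmark distance $\lVert x - x'\rVert/\sqrt N$ in mm — the scale on
which such models are usually quoted — with the raw squared-norm variant
behind `squared = TRUE`.

## The synthetic validation family

`make_shape_family()` generates the study population: a star-shaped radial
family around a base ellipsoid, $\rho(u) = \rho_0(u) + \sum_m b_m\psi_m(u)$,
with smooth low-order angular modes (zonal/sectoral/tesseral patterns),
coefficients $b_m \sim N(0, \lambda_m^*)$, optional landmark noise, and
digitization by exact inside tests on a 1 mm isotropic grid (default
$64^3$) with a guaranteed background margin. Modes are normalized to unit
norm in landmark space, so the drawn coefficients are exactly the
population's principal-component scores and $\lambda_m^*$ its eigenvalues —
which is what makes closed-form PCA-recovery tests possible. Star-shapedness
keeps every member genus-0 and makes the analytic surface
(`shape_family_radius()`) available as ground truth for fit-accuracy
measurements; draws that would pinch ($\rho \le 1$ mm) or touch the volume
border are rejected and redrawn. Everything is a pure function of the spec
and seed (bitwise reproducible, caller RNG untouched).

What passing on this family does and does not show: it validates the
correspondence machinery, the energy computations and the model algebra
under known ground truth, on smooth convex-ish single-object shapes. It
does not exercise thin or highly concave anatomy, anisotropic voxels,
segmentation errors, or multi-object scenes; conclusions about such data
require their own validation.

## Problem sizes and runtime choices

The shipped tests run the full pipeline on three-member families of
$40^3$ volumes with ~320-vertex templates and a 5-voxel window, and the
single-fit validation on a $64^3$ ellipsoid with the default 11-voxel
window; the acceptance script uses six $48^3$ members with 500-vertex
templates. These sizes keep a complete run in minutes on one CPU while
leaving every algorithmic path identical to production-scale use; all of
the parameters scale to larger volumes unchanged, with the kernel radius
capped at the volume extent (the power-law kernel's truncated tail is
negligible at these scales).

## Known limitations

* The outward crest bias of the magnitude-based external energy, described
  above — the dominant absolute-accuracy limitation.
* Greedy window search with normal-only projection can leave isolated
  vertices in bounded flip-flop cycles; `move_tol` convergence is therefore
  not guaranteed, only stability.
* The VFC kernel is built in voxel units; strongly anisotropic spacings
  would distort it (fixtures and defaults are isotropic).
* Topology is fixed: the template's genus must match the target's, and no
  topology changes occur during evolution.
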