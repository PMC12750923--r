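---
title: "Methods: CT-style bilateral bony symmetry evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT-style bilateral bony symmetry evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific model

`osteosym` quantifies how symmetric a person's left and right knee bones are,
using only triangulated surface models of the distal femur, patella and
proximal tibia (as segmented from CT). The underlying assumption is that a
healthy contralateral bone is a good geometric template for its pair, so the
*residual* shape difference after mirroring and optimal alignment is a
clinically meaningful measure of asymmetry.

For one bone pair the pipeline is:

1. **Fragment filtering.** Segmentation often leaves loose ossicles or
   disconnected islands; only the largest connected component (by surface
   area) of each side is kept.
2. **Isotropic remeshing** of both surfaces to a uniform 2.0 mm element size,
   so that correspondence-point (CP) density is comparable across subjects
   and sides and no region is over-weighted in the statistics.
3. **Sagittal mirroring** of the left model (negation of the medial-lateral
   coordinate, with face orientation fixed up), turning the left bone into a
   synthetic "second right bone".
4. **Rigid registration** of the mirrored left model onto the right model by
   rigid Coherent Point Drift (CPD), without scale estimation: size
   differences between sides are part of the asymmetry signal and must not be
   absorbed by the alignment.
5. **Global anatomical alignment** (femur and tibia) by principal axes —
   proximal-distal on Z, medial-lateral on X — with the joint end identified
   as the wider end by radial cross-sectional spread. Compact bones
   (patella), whose principal axes are ambiguous, are aligned by rigid CPD
   onto a pre-aligned reference model instead.
6. **Iterative trim-and-register** (femur and tibia): the kept model height
   equals the medial-lateral extent of the bone (or the available height
   minus 5 mm when the scan is shorter than that); the femur keeps its distal
   portion, the tibia its proximal portion. Both meshes are cut at the plane
   and the rigid registration refined, twice by default, each iteration
   re-cutting the pristine mirrored-left mesh under its refined pose so the
   final cuts are planar and symmetric. Patellae are never trimmed.
7. **Nonrigid CPD** deforms the right model onto the trimmed, aligned
   mirrored-left model. The per-vertex displacement magnitude of this
   deformation is the CP distance: CPD's deformed Gaussian-mixture centroids
   *are* the correspondences, so no separate closest-point search is needed.
8. **Cut-plane exclusion.** CPs within 2.0 mm of any cut plane are excluded
   from statistics, absorbing artificial asymmetries from residual trimming
   differences.
9. **Statistics and heatmaps.** Included CP distances are summarised by
   median, interquartile range and 1st-99th percentiles; surface heatmaps
   grey out distances at or below the 1.0 mm measurement-accuracy floor.

No hypothesis testing is performed; the design is descriptive, and group
comparisons are reported as pooled distributional summaries.

## Coherent Point Drift implementation

Both CPD variants follow Myronenko & Song's EM formulation with a uniform
outlier component of weight `w`. The moving set is modelled as Gaussian
mixture centroids fitted to the fixed set with a single isotropic variance
`sigma2` that is re-estimated in closed form each M-step.

* **Rigid:** rotation via SVD of the weighted cross-covariance with a
  determinant correction (proper rotation only, never a reflection), plus a
  translation. Scale is deliberately **not** estimated (see step 4 above).
* **Nonrigid:** the displacement field is `T(Y) = Y + G W` with Gaussian
  kernel `G(i, j) = exp(-||y_i - y_j||^2 / (2 beta^2))`; each M-step solves
  `(diag(P1) G + lambda sigma2 I) W = P X - diag(P1) Y`. The reported
  objective is the penalised negative log-likelihood
  `nll + lambda/2 * tr(W' G W)`, which is monotone non-increasing.

Numerical safeguards that mattered in practice:

* The E-step is computed in log space (log-sum-exp of the Gaussian and
  outlier terms). At small `sigma2` the naive outlier constant
  `c * exp(-k)` overflows; the log-space form is exact and stable.
* When `sigma2` reaches its floor (`1e-8`) the fit is as tight as
  representable and the EM loop stops *as converged* rather than warning.
* The final EM run continues from the `sigma2` selected during multi-start
  screening instead of re-initialising it broadly, which would erase the
  basin selection.

### Parameters (units, defaults, rationale)

| Parameter | Default | Rationale |
|---|---|---|
| `w` | 0.1 | Uniform outlier weight; robust to small segmentation junk without biasing clean fits. |
| `beta` | 10 mm | Coherence scale of the nonrigid kernel; bone-scale smoothness (condyle-sized features move together, vertex noise does not). |
| `lambda` | 2 | Regularisation weight of the deformation energy. |
| `tolerance` | 1e-6 | Relative objective change for convergence. |
| `max_iterations` | 150 | EM iteration cap. |
| `subsample_cap` | 1800 | Nonrigid node cap; the M-step solve is O(M^3), and 1800 nodes keep a full femur pair under ~15 s per fit at 2 mm remeshing with no measurable accuracy loss on the synthetic benchmarks. |
| `rigid_subsample_cap` | 6000 | Rigid cap; rigid EM is only O(MN) per iteration, so bones remesh at 2 mm run essentially at full resolution. Capping the rigid step aggressively costs real accuracy (see below). |
| `sigma2_floor` | 1e-8 mm^2 | Convergence floor for the mixture variance. |
| `n_starts` | 5 | Multi-start rigid initialisation: identity plus four principal-axes alignments (proper-rotation sign combinations). |
| `screen_iterations` | 30 | EM iterations used to screen starts on a ~600-point voxel subset; the two best-screened starts are refined fully and the lower final `sigma2` wins, because 30-iteration `sigma2` can misrank two close basins. |

### Deterministic voxel-grid subsampling

Point-count caps are enforced by **voxel-grid downsampling** (one
representative vertex per occupied cell, with the cell size chosen by
bisection so the count approaches the cap from below), not by random
subsampling. This is a substantive choice, not a style one: random
subsampling changes which points carry mass in the GMM and thereby *biases
the registration optimum itself*. On a femur-scale cloud we measured a
~1.45 degree shift of the global rigid optimum under random subsampling — EM
started at the true transform drifted to the biased optimum, so no amount of
restarting fixes it. Voxel-grid subsampling is spatially uniform,
deterministic, and showed no measurable bias. For the same reason the rigid
step runs at (near) full resolution (`rigid_subsample_cap = 6000`).

## Synthetic paired-bone generator

No CT meshes ship with the package, so validation uses parametric
surrogates: smoothly deformed ellipsoids with bone-like features (condyles
and a trochlea-like anterior boss for the femur, plateau flare and a tubercle
for the tibia, an articular ridge for the patella), built from a subdivided
icosahedron and remeshed to the standard 2 mm element size. They are
deliberately *not* anatomically realistic; they are elongated/compact in the
right ways to exercise both alignment paths, watertight, single-component,
and — crucially — fully analytic, so injected asymmetry has exact ground
truth:

* **Bumps:** Gaussian displacements along vertex normals with chosen anchor,
  amplitude, radius and sign; the per-vertex analytic displacement is
  returned as the truth and can be re-evaluated on any (remeshed,
  transformed) mesh.
* **Noise:** i.i.d. Gaussian vertex noise emulating segmentation jitter.
* **Misalignment:** a random rigid transform of the left mesh emulating scan
  pose differences.
* **Loose fragments:** a small detached ellipsoid near the bone, emulating
  segmentation islands, to exercise the fragment filter.

A marching-cubes/implicit-surface generator was considered and rejected: it
adds a large code surface for no validation benefit, since the pipeline never
sees volumetric data — its inputs are surface models.

When validating amplitude recovery, bump radii must exceed `beta` (10 mm):
the nonrigid field cannot represent features narrower than its coherence
scale, so e.g. an 8 mm-radius bump is recovered at roughly half amplitude by
construction, while 15 mm-radius bumps are recovered within about 25%. This
is resolution physics, not an implementation artefact, and mirrors the
resolution limits of any smoothness-regularised registration.

## Numerical and statistical conventions

* All percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7), fixed package-wide and verified in the tests
  against an independent sort-based oracle.
* The trim height is computed **once** from the aligned right mesh and the
  cut plane held fixed across trim/register iterations; what iterates is the
  pose of the left mesh. This makes the iteration a fixed-point refinement
  with a well-defined stability diagnostic (`plane_shift`, the maximum change
  of any left-vertex's perpendicular distance to the plane between
  iterations).
* Mesh clipping is exact: crossing triangles are split by edge-plane
  intersection and new vertices are placed exactly on the plane.
* STL files lose vertex identity (triangle soup) and carry 32-bit floats;
  the reader re-merges duplicate vertices, and PLY is used whenever scalar
  fields (CP distances) must survive a round trip.

## Limitations

* Surrogates are geometric stand-ins, not statistical shape models of real
  bones; absolute CP-distance levels on clinical data will differ.
* CP distances are displacement magnitudes of a regularised deformation:
  features narrower than `beta` are attenuated (see above), and the method
  reports *where and how much* the sides differ, not *why*.
* The rigid step assumes the two surfaces are largely overlapping bones of
  the same type; it is not a general partial-overlap registration.
* Group summaries are descriptive; no inferential statistics are provided.
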