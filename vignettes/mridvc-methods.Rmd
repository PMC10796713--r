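---
title: "Measuring meniscal displacement by digital volume correlation: models, parameters and validation"
author: "mridvc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meniscal displacement by digital volume correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Loading a knee changes where the menisci sit. On high-resolution MRI the
medial meniscus moves by tenths of a millimetre to a few millimetres
under axial compression — below or near the voxel size of even a 0.35 mm
isotropic acquisition. Digital volume correlation (DVC) measures this
motion directly from a pair of 3D images: a reference state `f(X)` and a
loaded state `g(x)`. Around each measurement node a cubic sub-volume
(the *subset*) of grey levels is tracked from `f` into `g`; the local
material transformation `phi` maps reference positions to deformed
positions, `x = phi(X)`, and the displacement at the node is
`u = phi(X) - X`. With subvoxel optimization of `phi` against
interpolated grey levels, DVC resolves displacements well below one
voxel.

`mridvc` implements this measurement chain for the meniscal use case:
bone-referenced rigid registration of the two acquisitions, subset
correlation over a segmented region of interest, directional
displacement statistics in the conventional Mean / Min–Max / SD layout,
and — because no real paired scans ship with the package — a phantom
generator with exactly known ground truth against which every stage is
validated.

## Subset matching

### Similarity criterion

The integer stage scores candidate subset positions with the zero-mean
normalized cross-correlation (ZNCC); the subvoxel stage minimises the
zero-mean normalized sum of squared differences (ZNSSD)

$$
\chi^2(p) \;=\; \sum_i \left[ \frac{f_i - \bar f}{\sigma_f}
 \;-\; \frac{g_i(p) - \bar g}{\sigma_g} \right]^2 ,
$$

where the sums run over the subset voxels and `g_i(p)` is the deformed
volume sampled at the warped voxel positions. ZNSSD and ZNCC are
monotonically related (`chi^2 = 2(1 - ZNCC)`), so optimizing one
optimizes the other; ZNSSD gives a least-squares structure for
Gauss–Newton while ZNCC is reported because its `[-1, 1]` scale is
interpretable. Both are invariant to affine intensity changes of either
image, which buys robustness against MR intensity drift between
acquisitions.

### Integer search

The integer stage is an exhaustive ZNCC argmax over every integer offset
inside a Euclidean search ball (default radius 10 voxels). Exhaustive
search is deliberate: it cannot be trapped by local optima, it is
trivially testable against an independent brute-force implementation,
and the summed-area-table + row-correlation implementation keeps it
fast. Ties are broken by the smaller offset norm, then lexicographic
order, so results are bit-reproducible.

### Subvoxel refinement

From the integer optimum, Gauss–Newton iteration refines the parameters
of `phi`: a pure subset translation (3 unknowns, `shapeOrder = 0`,
the default) or translation plus a full 3×3 displacement gradient
(12 unknowns, `shapeOrder = 1`). Each step solves the normal
equations of the linearized residual, with the reference subset
statistics frozen and the analytic gradient of the interpolant used for
the Jacobian. Iteration stops when the step norm falls below `tol`
(default 1e-4 voxel) or after `maxIter` (50) iterations; a step norm
that grows three times in a row is declared divergent and the best
iterate is returned unconverged. The default pure-translation model
matches the meniscal regime, where displacements are small relative to
the subset size; the affine-subset option exists for fields with
appreciable within-subset gradients (see the Gaussian-bump validation
below) and is the right choice when the imposed field varies over the
subset.

### Interpolation

Subvoxel sampling uses separable piecewise cubic **Lagrange**
interpolation on a 4-point stencil per axis. It is interpolating (exact
at grid nodes) and reproduces polynomial volumes up to degree 3 exactly,
which gives a sharp, testable exactness contract (the suite checks
reproduction of degree-3 volumes to 1e-9). The popular alternative,
Catmull–Rom cubic convolution, is C^1-continuous but only reproduces
polynomials up to degree 2; we preferred the higher reproduction order
and accept a derivative that is only piecewise continuous across cell
boundaries. The practical consequence of the C^0 kernel — a one-sided
derivative at integer offsets that couples with acquisition noise — is
neutralised by the prefilter described next.

### Why the engine prefilters: noise through an interpolant

Matching two *independently noisy* acquisitions with an interpolating
kernel produces a subtle, large artifact. At integer offsets the
deformed subset is sampled exactly on voxels, so it carries the full
noise variance; at fractional offsets interpolation averages
neighbouring voxels and the sampled noise variance drops. The
normalization in ZNCC/ZNSSD then *prefers* fractional offsets, creating
spurious optima near ±0.2 voxel, and the one-sided kernel derivative at
the integer starting point gives the first Gauss–Newton step a
systematic push. On the package's null test (two noise realizations of
one state, 2% noise) this produced a ~0.19 voxel systematic error.

The standard remedy, implemented here, is a mild Gaussian prefilter of
both volumes before matching (`prefilterSigma`, default 1 voxel,
0 disables). Band-limited noise no longer loses variance under
interpolation, and on the same null test the systematic error collapses
to ~0.003 voxel with ~0.015 voxel random scatter. The prefilter is part
of `correlateVolumes()`; the low-level `integerSearch()` /
`subvoxelRefine()` operate on the volumes exactly as given.

### Boundary handling

Measurement nodes are laid on a regular grid (step `gridStep`, default
8 voxels) over the ROI bounding box. A node is kept only if its subset,
the full search window, the tricubic support, and (when prefiltering)
the smoothing kernel support all fit inside the volume — smoothing does
not commute with deformation at a mirrored boundary, so
boundary-adjacent nodes would silently degrade. When the ROI is a
segmented structure rather than a block, `subsetInRoi = TRUE`
additionally keeps only nodes whose subset (plus prefilter support)
lies entirely inside the mask: subsets straddling the structure edge
mix moving and stationary texture and bias the estimate toward zero.
The end-to-end pipeline uses this option for the meniscus mask.

## Rigid registration on the bone

The two acquisitions are taken minutes apart with the specimen
repositioned by the loading rig, so before correlation the loaded
volume is rigidly aligned to the reference using the bones, which do
not deform. `registerRigid()` maximises the normalized
cross-correlation over the bone mask — the same-modality, same-session
setting makes NCC the appropriate metric, not mutual information —
through a 3-level coarse-to-fine schedule (smoothing sigma / mask
stride 2/4, 1/2, 0.75/1) with derivative-free Nelder–Mead refinement of
the 6 parameters at each level. The finest level keeps a 0.75-voxel
smoothing for the reason described above: sampling raw noise through an
interpolating kernel biases the metric optimum measurably (on the 64^3
validation scene the mean residual drops from ~0.07 to ~0.013 voxel).
Rotations act about the volume's geometric centre, which minimises
rotation–translation coupling in the optimization; angles are expressed
in degrees about the X, then Y, then Z axes. A user-supplied initial
transform can seed the search (the semi-automated workflow); the
achieved NCC is reported and the transform is flagged when it falls
below a configurable floor (0.5).

On synthetic scenes the contract is: perturbations up to 3 degrees and
3 voxels are recovered with a mean residual below 0.1 voxel over the
bone mask, and the result is invariant to affine intensity rescaling of
either input.

## The phantom generator

`generateKneePhantom()` builds the study conditions in miniature:

* **Texture.** White Gaussian noise low-pass filtered with a Gaussian
  kernel of sigma `correlationLength` (default 2 voxels), rescaled to
  `intensityRange`, emulates the smooth bright-dark grey-level
  structure that subset matching feeds on at 0.35 mm isotropic
  resolution. The autocorrelation of the result is Gaussian with
  half-width-at-half-maximum `2 sigma sqrt(ln 2)`, which the suite
  checks by FFT.
* **Two acquisitions.** Reference and deformed volumes carry
  *independent* additive Gaussian noise realizations (default sd 2% of
  the intensity range — the acquisition SNR is not otherwise
  constrained, so this is a package choice, and the uncertainty module
  sweeps it).
* **Geometry.** An ellipsoidal wedge plays the meniscus; a rectangular
  block plays the bone. At the default 96^3 scale the wedge half-height
  is ~10 voxels (3.4 mm), of the order of a real meniscal cross
  section.
* **Ground truth.** The meniscus moves by a parametric warp model
  (rigid, affine, Gaussian bump, or compositions). The field applies
  fully inside the meniscus mask, decays to zero across a cosine-taper
  shell (default width 4 voxels; width 0 produces the abrupt,
  lesion-like discontinuity), and is identically zero in the bone. The
  deformed image is produced by pull-back resampling with the exact
  inverse of the warp (analytic for rigid/affine, fixed-point for the
  rest), so `truthField()` is exact at every node, not approximated.
* **Repositioning.** A rigid perturbation of the whole deformed volume
  exercises the registration stage.

What the phantom does *not* emulate: MR physics (bias fields, ghosting,
partial-volume averaging at tissue interfaces), multi-tissue anatomy,
or load-dependent intensity changes. Passing the validation suite
therefore demonstrates that the *measurement chain* is correct and
quantifies its precision under controlled texture and noise; it does
not certify accuracy on any particular scanner's images.

## Measurement uncertainty

`assessUncertainty()` implements the imposed-shift protocol: generate a
texture, translate it by known subvoxel amounts (tricubic resampling),
give both volumes independent noise, run the full engine on a central
ROI, and pool the recovered-minus-imposed errors over nodes, shifts and
seeds. The summary statistic is the **pooled standard deviation** of
the per-node per-axis errors about their per-axis means, with bias
reported separately — "uncertainty" is not otherwise standardised, so
the package declares its convention. Including the zero shift
reproduces the classic zero-strain test (two noisy images of one
state). At the study conditions (96^3, correlation length 2, 2% noise,
17^3 subsets, shifts 0.1–0.9 voxel, 3 seeds) the pooled SD evaluates to
~0.014 voxel, comfortably inside the 0.05-voxel instrument level that
`scripts/acceptance.R` checks; interpolation bias follows the familiar
S-curve and is antisymmetric about the half-voxel shift.

```{r uncertainty-example}
library(mridvc)
spec <- textureSpec() # 96^3, 0.35 mm, correlation length 2, 2% noise
report <- assessUncertainty(
  spec,
  shifts = cbind(seq(0.1, 0.9, by = 0.1), 0, 0),
  cfg = dvcConfig(), seeds = c(101L, 202L, 303L)
)
print(report)
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `subsetHalfWidth` | 8 (17^3 subset) | voxels | enough texture per subset for ~0.01-voxel precision at 2% noise; error shrinks monotonically with subset size |
| `gridStep` | 8 | voxels | one node per subset width; denser grids measure no new information |
| `searchRadius` | 10 | voxels | covers the few-millimetre meniscal range at 0.35 mm |
| `shapeOrder` | 0 | — | meniscal displacements are near-uniform at subset scale; order 1 for fields with within-subset gradients |
| `correlationFloor` | 0.75 | — | validity threshold on the final ZNCC |
| `tol` | 1e-4 | voxels | Gauss–Newton step-norm stop, far below the noise floor |
| `prefilterSigma` | 1 | voxels | suppresses the noise-interpolation artifact (see above) |
| texture `correlationLength` | 2 | voxels | speckle scale a 0.35 mm DESS acquisition offers |
| texture `noiseSd` | 2% of range | intensity | plausible high-field SNR stand-in; swept in the uncertainty module |
| `taperWidth` | 4 | voxels | smooth field decay the subset model can follow; 0 reproduces a tear-like discontinuity |

## Conventions and numerical choices

* Voxel indices are 0-based `(i, j, k)`; physical position is
  `origin + index * spacing` (mm). Axis labels: X lateromedial,
  Y anteroposterior, Z axial.
* Reported statistics flip the sign of the X (extrusion) component for
  left knees (`laterality = "left"`), so both sides share one
  convention; stored fields are never flipped.
* Statistics use the sample SD (n−1); a single-node ROI reports SD 0.
* Displacement images are written as 3-component NIfTI in 32-bit float
  (0.05-voxel quantities sit far above float32 resolution), invalid
  nodes as NaN; node tables as plain CSV with full double precision.
* Mismatched grids (shape, spacing, origin) are always an error, never
  a silent resample.
* Warping displaces image content by the model's displacement field —
  `warpVolume(v, translationWarp(c(2, 0, 0)))` moves the image +2
  voxels along X — by resampling at the exact inverse of the
  transformation.
* All randomness is seeded and every stage is deterministic given its
  inputs; rerunning a pipeline configuration reproduces its CSV outputs
  byte for byte.

## Validation problem sizes

The test suite validates the engine at the full 96^3 study scale where
the contract demands it (uncertainty, uniform-translation and
Gaussian-bump recovery) and at 24^3–64^3 for unit-level properties,
keeping the default run at desk scale. The end-to-end pipeline tests
run two-condition studies on 64^3 scenes with 9^3 subsets and a
slightly thickened meniscal wedge so that interior subsets exist at
that scale. Uniform-translation and bump recovery use numerically
warped volumes (the deformed image is the warp of the same acquisition),
the standard validation that isolates engine error from acquisition
noise; the two-noise-realization case is quantified separately by the
uncertainty protocol.

## Known limitations

* The subset model measures displacement only; strain is out of scope.
* Pure-translation subsets bias toward zero where the true field varies
  strongly within a subset (tear edges, steep gradients); the affine
  option reduces but does not remove this.
* Registration assumes a rigid bone transformation; scanner-induced
  geometric distortion is not modelled.
* The phantom's realism limits are listed above; absolute agreement
  with any particular in-vivo or cadaver dataset is not claimed — the
  package quantifies its own precision on known ground truth.
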