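# mridvc

Digital volume correlation (DVC) for load-bearing musculoskeletal MRI,
built around one question: **how far does the medial meniscus move when
the knee is loaded?** Under axial compression the meniscus extrudes
laterally-medially and migrates antero-posteriorly by tenths of a
millimetre to a few millimetres — near or below the voxel size of even
a 0.35 mm isotropic high-field acquisition. Given a reference and a
loaded 3D scan plus a segmentation of the structure of interest,
`mridvc` measures the three components of its displacement field at
subvoxel precision and reports them in the conventional per-direction
Mean / Min–Max / SD layout.

## Who it is for

Biomechanics and musculoskeletal-imaging groups who have paired
volumetric acquisitions (NIfTI-1) of a loaded and unloaded state, a
region-of-interest mask, and a stationary reference structure (bone) —
and who want a tested, deterministic, scriptable measurement chain with
a validation story: every stage of the package is exercised on
synthetic phantoms whose ground-truth displacement field is known
exactly.

## The method

Around each node of a measurement grid, a cubic sub-volume *D* of grey
levels `f(X)` in the reference state is located in the deformed state
`g(x)` under a local material transformation `x = phi(X)`:

1. **Integer search** — exhaustive zero-mean normalized
   cross-correlation (ZNCC) argmax over all integer offsets in a search
   ball (deterministic tie-breaking).
2. **Subvoxel refinement** — Gauss–Newton minimisation of the zero-mean
   normalized sum of squared differences between the reference subset
   and the deformed subset sampled by tricubic interpolation, over the
   parameters of `phi` (subset translation by default; optionally
   translation + 3×3 displacement gradient). The displacement at the
   node is `u = phi(X) − X`.

Around the engine sit bone-referenced rigid registration (masked-NCC,
3-level pyramid, Nelder–Mead), mask-restricted directional statistics
with a knee-laterality sign convention, an imposed-shift
measurement-uncertainty protocol, a phantom generator, and an
end-to-end two-condition (e.g. native vs lesioned) pipeline driven by
one YAML config. The methods vignette
(`vignettes/mridvc-methods.Rmd`) documents the models, the parameter
defaults, and the numerical choices — including why the engine
prefilters both volumes before matching.

## Worked example

A complete miniature study on a 64³ phantom: the "meniscus" is
translated by (−0.983, 0.167, 0) mm, the whole deformed volume is
rigidly perturbed to emulate repositioning, and both acquisitions carry
independent 2% noise.

```r
library(mridvc)

spec <- textureSpec(shape = c(64, 64, 64), seed = 7)
scene <- generateKneePhantom(
  spec,
  translationWarp(c(-0.983, 0.167, 0) / 0.35),          # mm -> voxels
  bonePerturbation = rigidWarp(rotation = c(0, 0, 0.5),
                               translation = c(0.6, -0.4, 0.3),
                               center = c(31.5, 31.5, 31.5)),
  geometry = list(meniscusSemiAxes = c(0.34, 0.34, 0.20))
)

reg <- registerRigid(scene@reference, scene@deformed, scene@boneMask)
aligned <- applyRigid(scene@deformed, reg)$volume

cfg <- dvcConfig(subsetHalfWidth = 4, gridStep = 4, searchRadius = 4,
                 prefilterSigma = 0.75)
field <- correlateVolumes(scene@reference, aligned, scene@meniscusMask,
                          cfg, subsetInRoi = TRUE)
stats <- roiStatistics(field, scene@meniscusMask, laterality = "right")
stats
```

which prints

```
  axis       direction      mean_mm     min_mm      max_mm       sd_mm n_nodes
1    X    lateromedial -0.978898737 -0.9885407 -0.96928165 0.009301740       4
2    Y anteroposterior  0.163299766  0.1543783  0.17039325 0.007264171       4
3    Z           axial  0.001532038 -0.0143628  0.01576489 0.012608269       4
```

The imposed (−0.983, 0.167, 0) mm motion is recovered to within
~0.005 mm — about 0.015 voxel — after the registration stage removed a
0.5°/0.25 mm repositioning (achieved metric NCC 0.996).
`formatStatsTable(stats)` renders the same numbers in the Mean /
Min–Max / SD report layout. For a full two-condition study
(`stats_<condition>.csv`, `comparison.csv`, `provenance.json`, all
byte-reproducible under a fixed config) see `runPipeline()`, or the
thin CLI at `inst/cli/mridvc.R`.

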