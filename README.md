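# voxview

A headless R toolkit for the computational core of classic desktop
neuroimaging viewers: reading the field's volumetric formats into one common
model, placing voxels in world space, composing windowed/colored/blended
slice views and mosaics, rudimentary CPU volume rendering, binary lesion
(VOI) drawing with a legacy run-length ROI codec, and group lesion incidence
maps. Everything runs from scripts — no GUI, no downloads: seeded phantom
generators stand in for scanner data, so every feature is testable offline.

It is aimed at researchers and tool builders who need reproducible,
scriptable versions of the operations a lesion-mapping viewer performs
interactively: batch figure generation, lesion bookkeeping across a cohort,
format conversion, and regression-testable rendering.

## What it computes

**Geometry.** A volume is a 3D array plus a 4×4 affine **A** mapping the
0-based voxel index of a voxel *center* to RAS+ millimetres:
`[x y z 1]ᵀ = A · [i j k 1]ᵀ`. NIfTI-1 supplies **A** through the sform or
the quaternion qform (including the `qfac` sign); MGH through the
direction-cosine matrix `Mdc`, voxel sizes and RAS center `Pxyz_c`; AFNI
through `ORIENT_SPECIFIC` / `ORIGIN` / `DELTA` (native LPS+ axes, converted
to RAS+); NRRD through `space directions` / `space origin`; legacy VTK
through `SPACING` / `ORIGIN`. Display happens either in *image space*
(raw grid, nearest-neighbor, anisotropy visible) or *world space*
(trilinear reslice onto an isotropic grid).

**Display.** Intensities are windowed,
`w = clamp((v − min)/(max − min), 0, 1)`, looked up in a 256-entry RGBA LUT
at index `round(255 w)`, and composited source-over in float:
`out = src·α + dst·(1 − α)`. Overlay voxels below their display minimum are
fully transparent. A legacy-palette mode reproduces the old 8-bit
limitation: 255 gray levels plus one reserved opaque lesion color.

**Rendering.** Orthographic ray casting through the canonical RAS volume:
MIP keeps `max w` per ray; composite mode accumulates front-to-back with
per-sample opacity `α = w · gain`, so a uniform block crossed by `k` samples
accumulates exactly `1 − (1 − α)^k`. Hybrid mode textures the exposed faces
of an axis-aligned cut-out box with the matching 2D slices.

**Lesions.** VOIs are binary masks on a reference grid. Drawing (pen,
ellipse, 4-connected bucket fill, intensity-based 3D region growing,
spherical morphology, slice copy/paste) happens in image space. `.voi`
files are gzipped uint8 NIfTI (rename to `.nii.gz` for any other tool). The
legacy ROI codec stores per-slice runs of set pixels with 16-bit
start/length fields, which caps a slice at 65 536 in-plane pixels. The
incidence map over `n` subjects is the voxelwise mean of the masks, shown
with the classic thresholds: transparent below 1 %, saturating red at 10 %.

## Worked example

```r
library(voxview)

vol <- make_phantom(demo_phantom_spec(seed = 7))
vol
#> <vv_volume> 24 x 24 x 24 [float32, synthetic]
#>   voxel size (mm): 1 x 1 x 1
#>   intensity range: -2.97326 .. 93.2582

lesions <- make_lesion_set(10, vol, seed = 7, radius_range = c(2, 4))
map <- incidence_map(lesions)
map
#> <vv_incidence> 24 x 24 x 24, n = 10, max fraction = 0.2

round(voi_descriptives(lesions[[1]], label = "sub-01")[,
      c("n_voxels", "volume_mm3", "com_x", "com_y", "com_z")], 2)
#>   n_voxels volume_mm3 com_x com_y com_z
#> 1      262        262  9.94   5.8  5.03
```

The intensity range is the phantom's gradient + sphere + noise; `max
fraction = 0.2` says the most-overlapped voxel is lesioned in 2 of the 10
synthetic subjects; the first lesion covers 262 voxels of 1 mm³ centered
near (9.9, 5.8, 5.0) mm. Layered figures come from the same objects:

```r
sc <- scene(windowed_layer(vol),
            list(incidence_overlay(map, opacity = 0.7)))
save_png(compose_mosaic(sc, mosaic_spec("axial", slices = c(4, 8, 12, 16),
                                        columns = 4, overlap_fraction = 0.3,
                                        scale = 4)), "mosaic.png")
save_png(raycast(sc, render_spec(azimuth = 40, elevation = 20,
                                 mode = "composite")), "render.png")
```

A command-line wrapper covers the same ground (`inst/cli/voxview`), and
`run_script()` executes YAML task lists; see
`inst/extdata/example-pipeline.yaml` for a full fixtures → draw → mosaic →
render → incidence pipeline that reruns byte-identically under a fixed seed.

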