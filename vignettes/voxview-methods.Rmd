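---
title: "voxview: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxview: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

voxview reimplements, as a headless scriptable library, the computational
core that desktop lesion-mapping viewers perform interactively: multi-format
volume I/O, voxel/world geometry, layered color display, slice mosaics,
rudimentary CPU volume rendering, binary lesion drawing with a legacy
run-length ROI codec, and lesion incidence mapping. This vignette records
the models behind each piece, the conventions the package commits to, and
the decisions taken where the design was genuinely open.

## The volume model and geometry

A `vv_volume` is a 3D numeric array plus a 4×4 affine $A$ that maps the
0-based index of a voxel *center*, in homogeneous form $(i, j, k, 1)^T$, to
RAS+ world millimetres. Data are held in double precision *after* any
on-disk scale/intercept, so all downstream arithmetic sees physical units.
Two assumptions run through everything: the affine's 3×3 part is
nonsingular (enforced at construction), and world space is RAS+ — readers
for formats with other native axes (AFNI's LPS+ ordering, MGH's
center-anchored frame) convert on ingestion.

Format support is deliberately a reimplementation, not a wrapper: the
package writes and parses NIfTI-1 (348-byte header, magic at offset 344,
quaternion qform including the `qfac` sign, sform preferred when its code is
positive, pixdim-diagonal fallback with a warning when both codes are 0),
big-endian MGH/MGZ (affine from `Mdc`, voxel sizes and `Pxyz_c` with the
anchor at voxel `dims/2`), AFNI HEAD/BRIK (all 48 `ORIENT_SPECIFIC`
combinations on read; `BRICK_FLOAT_FACS` applied when nonzero; sub-brick 0
only; the writer also emits `IJK_TO_DICOM_REAL` as modern AFNI does),
NRRD (attached data, raw or gzip encodings, 3D scalar kind; detached
headers rejected), and legacy VTK structured points (BINARY big-endian or
ASCII). Independent readers — RNifti in-process and nibabel through python —
appear *only* in tests, as oracles; the library itself has no such
dependency. Because test phantoms serialize as 4-byte floats, the generator
snaps voxel values to their nearest float32-representable double at
creation, which makes every round trip bit-exact rather than merely close.

Interpolation and resampling follow two fixed rules. Nearest-neighbor
lookups round each coordinate **half away from zero** — one tie rule,
applied identically in every module (slice indexing, mm→index conversion,
LUT indexing). Out-of-grid samples return 0 (background) rather than
clamping: lesion maps and statistical overlays must not smear their edge
values outward. Trilinear sampling is the standard 8-neighbor weighted
average; it reproduces globally linear intensity fields exactly wherever
all 8 neighbors are in-grid, which the tests exploit as an oracle.
`canonical_ras()` reorients losslessly (axis permutation/flips only,
choosing the permutation that maximizes the affine diagonal's absolute
sum), is idempotent, and preserves every voxel's world position; "axial /
coronal / sagittal" are defined on this canonical orientation. World-space
display reslices the scene onto an isotropic grid whose spacing is the
smallest source voxel dimension — fine enough to lose nothing, coarse
enough to stay cheap.

## Display, palettes, mosaics

Windowing is linear with clamping: $w = \mathrm{clamp}((v - \min)/(\max -
\min), 0, 1)$. Color comes from 256-entry RGBA LUTs indexed by
$\mathrm{round}(255\,w)$; the built-in ramps (grayscale, red, blue, hot,
cool, warm, viridis-like) are this package's own documented tables — the
historical viewer's exact ramps were never published, so these are
replacements, not reconstructions. Compositing is source-over in floating
point, quantized to 8 bits once at the end, avoiding cumulative rounding.
Overlay voxels strictly *below* the overlay's display minimum get alpha 0;
a voxel exactly at the minimum is shown at the LUT's cold end. (The
incidence display inherits this: fractions below the 1 % threshold are
invisible, 1 % itself is the first visible blue.)

The legacy-palette mode reproduces a historical memory constraint as a
feature: 255 gray levels (indices 0–254) for the anatomy plus one reserved
opaque entry (index 255) for the lesion, hence no lesion translucency in
that mode, by construction.

Mosaics tile arbitrary (not necessarily equidistant) slice lists row-major;
horizontal placement advances by `tile_width × (1 − overlap_fraction)`.
Where tiles overlap, later slices paint over earlier ones and
zero-intensity (pure black) pixels are treated as transparent — the rule
that visually reproduces overlapping brain slices on a black background.
The overlap fraction is a free display parameter in $[0, 0.9]$. In image
space each voxel is a `scale`×`scale` square of screen pixels regardless of
voxel anisotropy (anisotropy stays visible; world-space mode is the cure).
Colorbar labels use a built-in 3×5 pixel font so PNG output never depends
on a graphics device.

## Rendering

Rays are cast orthographically — the historical tool's static-figure use
case does not need perspective — through the canonical volume, with
ray/volume intersection by the slab method in voxel coordinates and
sampling starting at the entry face plus half a step (`step_mm`, default
1 mm). MIP keeps the maximum windowed intensity per ray and colors it
through the base LUT. Composite mode accumulates front-to-back with
per-sample alpha $\alpha = w \cdot \text{gain}$ (gain in $(0,1]$, default
0.5) and terminates a ray at accumulated alpha ≥ 0.99; a uniform block
crossed by $k$ samples therefore accumulates exactly $1-(1-\alpha)^k$,
which the tests check in closed form. The transfer function (windowed
intensity × gain) is a documented stand-in: the original tool's function
was never specified. There is no lighting or gradient shading — the
rendering is rudimentary on purpose, and a shading hook would be the first
extension. Cut-out boxes are axis-aligned in voxel coordinates with
inclusive index bounds; a box with any `max < min` is empty. Hybrid
rendering treats the box's exposed faces as opaque surfaces textured by
nearest-neighbor scene colors at the face plane, so face texels are exactly
slice colors.

## Lesion drawing and the ROI codec

Drawing operates in image space only — tracing in the acquisition grid
avoids aliasing the binary mask. The pen sets voxels whose centers lie
within `thickness/2` (Euclidean, in-plane) of the polyline; ellipses use
inclusive membership of the inscribed ellipse, with the outline defined as
the filled disc minus its 4-connected erosion. Bucket fill floods
4-connected so that 8-connected drawn contours are watertight. Intensity
growing is a 3D connected component (6 or 26 connectivity) over an
inclusive intensity band. Morphology uses the discrete spherical element
$\{\,\delta : \|\delta\|^2 \le r^2\,\}$ (radius 1 = the 7-voxel 6-connected
ball), with outside-the-grid treated as background. Every 2D operator
touches only its addressed slice, which the tests verify by hashing the
untouched slices.

`.voi` persistence is deliberately boring: a gzipped uint8 NIfTI-1 with the
reference affine, so renaming to `.nii.gz` opens it anywhere. The legacy
ROI codec is different in kind: the historical byte layout was never
documented, so this package *defines* a dialect (magic `MRO1`, grid
dimensions, then per-slice 16-bit little-endian (offset, length−1) pairs
over the raster-ordered plane) whose 16-bit fields reproduce the historical
capacity exactly — at most 65 536 in-plane pixels, enforced with a
capacity error. Storing `length − 1` lets a single run span a full
65 536-pixel plane without overflowing 16 bits; empty runs cannot occur.
Bit-compatibility with archived historical files is explicitly not claimed
(even their flattening order is unknowable); the capacity behavior is.

## Incidence maps

The incidence map over $n$ subjects is the voxelwise mean of binary masks,
$f_v = \frac{1}{n}\sum_s m_{s,v}$. Inputs on mismatched grids are rejected,
never silently resliced — interpolating binary masks behind the user's back
is how fractional "lesions" sneak into group maps; an explicit
nearest-neighbor `reslice_world()` call is the sanctioned route. The
default overlay thresholds (transparent below 0.01, warm saturation at
0.10) reproduce the classic 1 %-blue / 10 %-red incidence display; the
cold-to-warm ramp itself is this package's documented substitute for an
untabulated original.

## Synthetic data: what it does and does not show

The generators produce geometric phantoms (spheres, boxes, linear
gradients) with additive Gaussian noise, and cohorts of spherical lesions
with uniform centers and radii (defaults 2–4 voxels on a 24³, 1 mm grid —
small focal lesions at a scale where incidence overlap actually occurs).
All randomness flows through `set.seed(seed, kind = "Mersenne-Twister")`,
one named, versioned PRNG, so seeds are portable and every artifact is
bit-reproducible. These fixtures exercise geometry, codecs, compositing and
statistics exactly; they do **not** emulate anatomy, bias fields, partial
volume effects, motion artifacts, or realistic lesion shapes. Passing
tests therefore demonstrate that the machinery is correct, not that any
segmentation-like behavior transfers to clinical images.

Test problem sizes are chosen to keep the full suite under a minute on one
core: phantoms of 8³–24³ voxels, 10⁴ random interpolation probes, 100
randomized drawing slices per operator against brute-force oracles, 10³
random masks through the RLE codec, 33²–48² rendered images. The
quantities under test (capacity limits, closed-form compositing, exact
round trips) are size-independent, so small grids lose no generality.

## Known limitations

- NIfTI-2, CIFTI, DICOM, ECAT, BrainVoyager and BVOX are out of scope;
  DICOM conversion belongs to dedicated converters.
- NRRD support is the common attached-data raw/gzip dialect only.
- No nonlinear warping, registration or normalization, and no
  voxelwise lesion-symptom statistics — those belong to dedicated tools;
  this package stops at incidence arithmetic and descriptives.
- Rendering is non-interactive by design; large volumes render in seconds,
  not frames per second.
- Dual-polarity (positive/negative) statistical coloring and cluster
  thresholding are not implemented.
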