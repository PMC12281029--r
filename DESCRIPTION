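Package: voxview
Title: Headless Volumetric Neuroimaging Viewer Core
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless library and command-line tool reproducing the
    computational core of a classic desktop neuroimaging viewer: readers and
    writers for NIfTI-1 (.nii/.nii.gz), FreeSurfer MGH/MGZ, AFNI HEAD/BRIK,
    NRRD and legacy VTK structured-points volumes with magic-byte format
    sniffing; voxel/world affine geometry, canonical RAS reorientation and
    nearest/trilinear reslicing; intensity windowing, color lookup tables,
    translucent multi-layer blending and a legacy 8-bit palette emulation;
    slice mosaics with partial overlap; CPU orthographic ray-cast volume
    rendering with slice cut-outs; binary lesion (VOI) drawing tools with a
    16-bit run-length ROI codec and gzipped-NIfTI .voi persistence; group
    lesion incidence maps; and a YAML-scripted batch interface. Seeded
    phantom generators make every feature testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
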