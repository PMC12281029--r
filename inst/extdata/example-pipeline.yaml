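# Example batch script: phantom fixtures -> lesion drawing -> mosaic ->
# rendering -> incidence map.  Run from a working directory of your choice:
#   Rscript -e 'voxview::run_script(system.file("extdata/example-pipeline.yaml", package = "voxview"))'
# All outputs land under ./voxview-example/ and are byte-identical across
# reruns with the same seed.
tasks:
  - command: fixtures
    seed: 42
    options:
      dir: voxview-example/fixtures
  - command: draw
    options:
      ref: voxview-example/fixtures/phantom.nii
      ops: voxview-example/draw-ops.yaml
      out: voxview-example/lesion.voi
  - command: mosaic
    inputs: [voxview-example/fixtures/phantom.nii]
    options:
      overlay: voxview-example/lesion.voi
      overlay-lut: red
      overlay-min: 0.5
      overlay-max: 1
      opacity: 0.6
      axis: axial
      slices: "8,11,12,13,16"
      columns: 5
      overlap: 0.2
      scale: 4
      out: voxview-example/mosaic.png
  - command: render
    inputs: [voxview-example/fixtures/phantom.nii]
    options:
      mode: composite
      azimuth: 40
      elevation: 20
      step: 1
      gain: 0.4
      size: 96x96
      cutout: "12,12,12,23,23,23"
      out: voxview-example/render.png
  - command: incidence
    inputs: [voxview-example/lesion.voi, voxview-example/lesion.voi,
             voxview-example/lesion.voi]
    options:
      out: voxview-example/incidence.nii
      csv: voxview-example/descriptives.csv
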