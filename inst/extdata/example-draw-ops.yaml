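# Scripted drawing operations consumed by `voxview draw --ops`.
# Coordinates are 0-based voxel indices on the reference volume's grid.
- op: ellipse
  slice: 12
  min: [6, 6]
  max: [16, 14]
  filled: true
- op: pen
  slice: 13
  points: [[8, 8], [14, 8], [14, 12]]
  thickness: 3
- op: morph
  operation: close
  radius: 1
- op: paste
  from: 12
  to: 11
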