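# Example phantom scene: one mandible-segment-style block with nine markers
# (three each of 10/20/30 ul) and no confounders.
seed: 42
spacing: [0.4, 0.4, 0.6]
marker_pitch: 10
depth_range: [1, 2]
include_bone: true
markers:
  - {nominal_volume: 10}
  - {nominal_volume: 20}
  - {nominal_volume: 30}
  - {nominal_volume: 10}
  - {nominal_volume: 20}
  - {nominal_volume: 30}
  - {nominal_volume: 10}
  - {nominal_volume: 20}
  - {nominal_volume: 30}
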