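# Example configuration for: dcvtrace.R simulate release-movie
# Frame windows are half-open [start, end) in 1-based frames at 1 Hz.
baseline: [1, 21]
stimulation: [21, 51]
rest: [51, 111]
nh4cl: [111, 231]
washout: [231, 261]
frame_interval: 1
noise:
  photon_scale: 2
  read_sigma: 2
  background_level: 20
rois:
  - {row: 20, col: 20, a_stim: 1, a_nh4cl: 6}
  - {row: 40, col: 44, a_stim: 2, a_nh4cl: 8}
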