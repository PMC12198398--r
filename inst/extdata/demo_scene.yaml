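# Demo scene: two orbiting foci on a 1680x1050 screen, 80 attentive and 20
# wandering observers, 60 s at 25 fps sampled at 500 Hz.
video:
  fps: 25
  duration: 60
  width: 1680
  height: 1050
sampling_rate: 500
observers:
  n_attentive: 80
  n_wandering: 20
  noise_sd: 15
foci:
  - {x: 640, y: 525, motion: circle, radius: 120, period: 23}
  - {x: 1040, y: 525, motion: circle, radius: 120, period: 31, phase: 1.7}
seed: 1
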