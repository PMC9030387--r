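Amy:
  eta_x: -2.24
  eta_y: -3.16
Joe:
  eta_x: 0.0
  eta_y: 0.0
Sam:
  eta_x: 2.24
  eta_y: 3.16
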