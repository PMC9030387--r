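variables:
- eta_x
- eta_y
- X1
- Y1
- X2
- Y2
- X3
- Y3
- X4
- Y4
directed_edges:
- - X1
  - X2
  - 0.05
- - Y1
  - X2
  - 0.4
- - X1
  - Y2
  - -0.6
- - Y1
  - Y2
  - 1.2
- - X2
  - X3
  - 0.05
- - Y2
  - X3
  - 0.4
- - X2
  - Y3
  - -0.6
- - Y2
  - Y3
  - 1.2
- - X3
  - X4
  - 0.05
- - Y3
  - X4
  - 0.4
- - X3
  - Y4
  - -0.6
- - Y3
  - Y4
  - 1.2
- - eta_x
  - X1
  - -4.0
- - eta_y
  - Y1
  - 19.0
- - eta_y
  - X1
  - 8.0
- - eta_x
  - Y1
  - -12.0
- - eta_x
  - X2
  - 1.0
- - eta_y
  - Y2
  - 1.0
- - eta_x
  - X3
  - 1.0
- - eta_y
  - Y3
  - 1.0
- - eta_x
  - X4
  - 1.0
- - eta_y
  - Y4
  - 1.0
error_cov:
- - eta_x
  - eta_x
  - 5.0
- - eta_x
  - eta_y
  - 2.5
- - eta_y
  - eta_y
  - 10.0
- - X1
  - X1
  - 131.759999999999991
- - X1
  - Y1
  - 254.120000000000005
- - Y1
  - Y1
  - 632.940000000000055
- - X2
  - X2
  - 20.0
- - Y2
  - Y2
  - 40.0
- - X3
  - X3
  - 20.0
- - Y3
  - Y3
  - 40.0
- - X4
  - X4
  - 20.0
- - Y4
  - Y4
  - 40.0
latents:
- eta_x
- eta_y
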