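# Desk-scale multi-organ preset: 1 channel, 3 classes, 48^3 grid.
grid: [48, 48, 48]
channels: 1
num_classes: 3
noise_sigma: 5.0
blur_sigma: 0.5
spacing: [1.0, 1.0, 1.0]
organs:
  - class_id: 1
    shape: ellipsoid
    center: [0.45, 0.50, 0.50]
    radii: [0.28, 0.24, 0.26]
  - class_id: 2
    shape: ellipsoid
    center: [0.72, 0.30, 0.35]
    radii: [0.12, 0.10, 0.11]
intensity_table:
  - [0.0]
  - [80.0]
  - [160.0]
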