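# 4-channel nested-lesion preset (edema shell / core shell / enhancing centre).
grid: [64, 64, 64]
channels: 4
num_classes: 4
noise_sigma: 4.0
blur_sigma: 0.5
spacing: [1.0, 1.0, 1.0]
organs:
  - class_id: 1
    shape: ellipsoid
    center: [0.5, 0.5, 0.5]
    radii: [0.34, 0.30, 0.32]
  - class_id: 2
    shape: ellipsoid
    center: [0.5, 0.5, 0.5]
    radii: [0.21, 0.19, 0.20]
  - class_id: 3
    shape: ellipsoid
    center: [0.5, 0.5, 0.5]
    radii: [0.10, 0.09, 0.10]
intensity_table:
  - [0.0, 0.0, 0.0, 0.0]
  - [60.0, 20.0, 90.0, 30.0]
  - [25.0, 80.0, 40.0, 70.0]
  - [95.0, 55.0, 15.0, 100.0]
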