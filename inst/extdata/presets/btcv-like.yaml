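# Multi-organ CT-style preset: 1 channel, 14 classes (background + 13
# structures), mixing large organs, small glands and tubular vessels.
grid: [64, 64, 64]
channels: 1
num_classes: 14
noise_sigma: 5.0
blur_sigma: 0.5
spacing: [1.0, 1.0, 1.0]
organs:
  - {class_id: 1,  shape: ellipsoid, center: [0.32, 0.60, 0.45], radii: [0.20, 0.24, 0.22]}  # large organ, liver-like
  - {class_id: 2,  shape: ellipsoid, center: [0.72, 0.68, 0.50], radii: [0.10, 0.12, 0.11]}  # spleen-like
  - {class_id: 3,  shape: ellipsoid, center: [0.30, 0.25, 0.62], radii: [0.08, 0.07, 0.10]}  # kidney R
  - {class_id: 4,  shape: ellipsoid, center: [0.70, 0.25, 0.62], radii: [0.08, 0.07, 0.10]}  # kidney L
  - {class_id: 5,  shape: blob,      center: [0.55, 0.55, 0.35], radii: [0.12, 0.12, 0.10]}  # stomach-like blob
  - {class_id: 6,  shape: tube,      center: [0.50, 0.42, 0.50], radii: [0.035, 0.035, 0.40]} # aorta-like
  - {class_id: 7,  shape: tube,      center: [0.42, 0.36, 0.50], radii: [0.030, 0.030, 0.38]} # IVC-like
  - {class_id: 8,  shape: ellipsoid, center: [0.38, 0.48, 0.30], radii: [0.045, 0.040, 0.055]} # gallbladder-like
  - {class_id: 9,  shape: tube,      center: [0.52, 0.50, 0.80], radii: [0.025, 0.025, 0.16]}  # esophagus-like
  - {class_id: 10, shape: blob,      center: [0.52, 0.40, 0.55], radii: [0.10, 0.045, 0.04]}  # pancreas-like
  - {class_id: 11, shape: tube,      center: [0.55, 0.52, 0.55], radii: [0.10, 0.022, 0.022]} # portal-vein-like
  - {class_id: 12, shape: ellipsoid, center: [0.33, 0.30, 0.74], radii: [0.035, 0.030, 0.030]} # adrenal R
  - {class_id: 13, shape: ellipsoid, center: [0.67, 0.30, 0.74], radii: [0.035, 0.030, 0.030]} # adrenal L
intensity_table:
  - [0.0]
  - [40.0]
  - [80.0]
  - [120.0]
  - [160.0]
  - [200.0]
  - [240.0]
  - [280.0]
  - [320.0]
  - [360.0]
  - [400.0]
  - [440.0]
  - [480.0]
  - [520.0]
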