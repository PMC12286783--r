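---
title: "Fourier-operator token mixing for 3D segmentation: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier-operator token mixing for 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(afnoseg)
```

## The model

`afnoseg` segments multi-channel 3D volumes with a hybrid
encoder–decoder. The encoder is a hierarchical vision transformer whose
token mixing is an *adaptive Fourier neural operator* (AFNO); the decoder
is a skip-connected convolutional U-Net.

**Patch embedding.** The input volume (shape `H x W x D x C`, channel axis
last throughout the package) is cut into non-overlapping cubic patches of
edge `P`; each flattened patch is projected linearly and a learned
positional vector is added:

    E_patch = Flatten(x) . W_proj + E_pos

Positional encodings are a learned table with one vector per 3D token-grid
position, initialized from N(0, 0.02^2). Fixed sinusoids are not used; when
a model runs on a different grid than it was built for, the table is
resampled trilinearly.

**Transformer blocks.** Each block is pre-norm residual:

    z' = Mix(Norm(z)) + z
    z  = MLP(Norm(z')) + z'

with a two-layer MLP (hidden ratio 4, exact Gaussian-error activation
`x * pnorm(x)`). `Mix` is one of three interchangeable token mixers
(`mixing_mode`):

* `afno_3d` (default): per channel, the tokens on their `(h, w, d)` grid are
  transformed by a separable 3D DFT, every frequency is multiplied by its
  own learned complex weight `W(k)`, and the inverse DFT returns to the
  spatial domain:

      F(k)     = sum_n e(n) exp(-2 pi i n k / N)
      F_mod(k) = F(k) . W(k)
      e'(n)    = (1/N) sum_k F_mod(k) exp(+2 pi i n k / N)

* `afno_1d`: the literal one-dimensional form of the same equations over
  the flattened token index — useful for checking the algebra, less
  faithful to the 3D geometry.
* `msa_only`: conventional multi-head self-attention.

The spectral weights are initialized to `1 + 0i`, so the mixing path starts
as the identity; they are kept Hermitian-symmetric (projected after every
optimizer step) so real token fields map to real token fields, and the
imaginary residue after the inverse transform is checked against `1e-8`.
The package stores the full complex spectrum (R's native FFT layout) rather
than a half-spectrum; Hermitian symmetry is enforced by projection, which
is the same constraint expressed differently.

**Hierarchy.** Four stages with default widths 48, 96, 192, 384. Between
stages, *patch merging* concatenates each 2x2x2 token neighbourhood and
projects it linearly, halving the grid. With the default stem patch size
`P = 2` the stage outputs sit exactly at `H/2, H/4, H/8, H/16` of the input
resolution — the documented worked-example schedule. (The patch-embedding
functions default to `P = 4` when used standalone; a 4-voxel stem is
incompatible with a stage-1 resolution of `H/2`, and the stage schedule is
the operative description, so the hierarchical encoder resolves the
conflict in favour of `P = 2`.) A `constant_resolution` mode (embedding
width 768, 12 layers, patch size 4) keeps one token grid throughout and
taps skip sources after each quarter of the layer stack; the decoder then
resamples those skips to the mirror resolutions. Both modes share all other
machinery.

**Decoder.** Mirror-wired U-Net fusion:

    F_dec_i = Conv(Up(F_dec_{i-1}) (+) F_enc_i)

`Up` is a learned 2x transposed convolution (kept learnable rather than
fixed trilinear), `(+)` is channel concatenation, and `Conv` is two 3x3x3
convolutions each followed by per-voxel layer normalization and the
Gaussian-error nonlinearity. After the last fusion stage a final transposed
convolution restores the padded input resolution, the patch padding is
cropped, and a 1x1x1 convolution plus per-voxel softmax yields class
probabilities. Hard labels are the argmax, ties broken toward the lowest
class index.

## Training

The loss is soft-Dice plus cross-entropy, equally weighted by default,
computed from logits through a stable log-softmax (the softmax head is
applied for outputs; the loss never exponentiates unshifted logits). The
soft-Dice term averages over foreground classes with an `1e-6` smoothing
constant. Gradients for every layer are hand-derived and verified against
central finite differences in the test suite (relative error below `1e-4`
on a 4^3 toy for the loss; ~`1e-9` per layer).

`train_config()` defaults encode the intended full-scale recipe: AdamW
(learning rate `1e-4`, decoupled weight decay `0.01` on weight tensors
only), batch accumulation of 2, up to 150 epochs with early stopping
(patience 20) on validation mean Dice, an 80/20 train/test split with the
validation set carved 90/10 out of the training portion, and augmentation
by per-axis random rotations (±15°), isotropic scaling (0.9–1.1) and
elastic deformation (field smoothed with σ = 4 voxels, amplitude 10
voxels) — magnitudes are the package's own defaults, chosen at
field-typical values. Volumes are interpolated trilinearly, labels by
nearest neighbour, so augmented labels never leave the original class set.
Early stopping always returns the parameters of the best validation epoch.

**Desk-scale settings.** The packaged experiments (acceptance script and
heavy tests) run reduced-width models (stage widths 8/16/32/64) on phantom
grids of 32^3–48^3, with learning rate `5e-3`, batch size 1, augmentation
off, and 200 steps (single-phantom overfit) or 12 epochs over 20 phantoms
(generalization). A few hundred AdamW updates at `1e-4` cannot move any
model far enough to converge; the larger rate is part of the same
scale-down as the reduced widths, not a change to the full-scale defaults.
Problem sizes were chosen so each experiment completes in minutes on one
CPU core.

## Synthetic phantoms

`phantom_spec()`/`generate_phantom()` build seeded synthetic volumes with
exact labels: geometric organs (ellipsoids, axis-aligned tubes, lumpy
blobs) rasterized in listed order (later organs overwrite earlier ones, so
small-on-large structures compose naturally), per-(class, channel) mean
intensities, additive Gaussian noise, and a Gaussian partial-volume blur
applied to intensities only. Three presets ship as YAML:
`btcv-like` (1 channel, 14 classes, mixed large/small structures),
`msd-like` (4 channels, nested lesion classes), and `btcv-like-mini`
(1 channel, 3 classes, 48^3) for desk-scale training runs.
`nested_tumor_phantom()` produces the 4-channel nested-shell configuration
directly.

Phantoms emulate the *structure* of multi-organ CT and multi-modal MRI
tasks — class geometry, channel count, intensity separability, partial
voluming, noise — but not anatomy, bias fields, Rician noise, motion or
inter-subject variability. Passing the packaged learning tests therefore
demonstrates that the architecture, gradients, optimizer and pipeline are
correct and can fit and generalize on separable volumetric structure; it
does not certify clinical-grade accuracy on real scans. Noise defaults are
kept below a quarter of the smallest inter-class intensity gap, which
guarantees (and the suite verifies) that a per-voxel nearest-mean
classifier reaches 99% accuracy — i.e. the phantoms are learnable by
construction.

## Evaluation

`dice()` is `2|T∩S| / (|T|+|S|)`. Both masks empty returns 1 with an
explicit flag (perfect agreement on absence); exactly one empty returns 0.
`hd95()` extracts surfaces as foreground voxels with at least one
background 6-neighbour (out-of-bounds counts as background), scales
coordinates by the voxel spacing (so distances are in mm — spacing-aware
rather than voxel-count distances), computes directed nearest-neighbour
distances both ways, takes the 95th percentile of each (linear
interpolation between closest ranks) and returns the larger. The percentile
is a parameter; 100 recovers the classical maximum Hausdorff distance.
`evaluate()` reports classes `1..K-1` (background excluded, as organ-wise
tables do); undefined HD95 values are flagged and excluded from the mean
with a note, never silently dropped.

## Inference

`sliding_window_predict()` tiles large volumes with fixed windows (default
the model's reference shape; stride `window * (1 - overlap)`, last window
shifted flush with the boundary), blends per-window probabilities under a
Gaussian importance map (σ = window/8, floored at 1e-3) and normalizes by
the accumulated weight, so blending weights form a partition of unity at
every voxel. A volume covered by a single window returns the direct forward
pass unchanged.

## Numerical choices and edge cases

* Token/patch enumeration order is the package's column-major convention
  (H fastest, then W, D; channel last) everywhere; tests pin it.
* Volumes not divisible by the patch size are zero-padded high-side; the
  padding is recorded and cropped after decoding, so output shape always
  equals input shape. Odd grids at a merge are padded by one.
* Z-score normalization is per channel over the whole volume (no
  foreground mask), with population standard deviation; channels with SD
  below `1e-8` become all zeros rather than NaN.
* Degenerate attention (one token) reduces to the residual plus the
  value/output projections; softmax rows are max-shifted for stability.
* The whole pipeline is deterministic under a fixed seed: phantom
  generation, splitting, shuffling, augmentation and weight initialization
  all flow through explicit seeds with no hidden global state.

## Known limitations

* Pure R execution: full-width configurations (48–384 channels, 128^3
  inputs) run forward passes in minutes, but training at that scale is not
  practical without accelerators; the packaged experiments use reduced
  widths.
* The "adaptive global-local coupling units" and the parallel CNN/ViT
  pathway sometimes described alongside this architecture family have no
  defining equations; the implemented model is the sequential AFNO encoder
  plus convolutional decoder, with the mixing mode and constant-resolution
  variants exposed as configuration.
* No DICOM ingestion, resampling/registration, orientation handling beyond
  voxel spacing, deep supervision, or test-time augmentation.
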