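# afnoseg

Semantic segmentation of 3D medical volumes (multi-organ CT, multi-modal
brain MRI) in R, built around a hybrid architecture: a hierarchical vision
transformer encoder whose token mixing is an **adaptive Fourier neural
operator** (AFNO), and a skip-connected convolutional U-Net decoder. The
package is aimed at methods researchers who want a fully inspectable,
dependency-light reference implementation of this architecture family —
every forward *and backward* pass is written out in R and verified against
finite differences — together with the surrounding machinery a
segmentation study needs: NIfTI I/O, z-score normalization, seeded
synthetic phantoms, Dice/HD95 evaluation, a complete training loop, and
sliding-window inference.

## The model in brief

A volume `x` (`H x W x D x C`) is cut into non-overlapping cubic patches,
embedded as tokens

    E_patch = Flatten(x_v) · W_proj + E_pos,

and processed by four pre-norm transformer stages

    z' = Mix(Norm(z)) + z,        z = MLP(Norm(z')) + z',

where `Mix` transforms the token field to the frequency domain, modulates
every frequency with a learned complex weight, and transforms back:

    F(k) = Σ_n e(n) e^{-2πi nk/N},   F_mod(k) = F(k)·W(k),
    e'(n) = (1/N) Σ_k F_mod(k) e^{+2πi nk/N}.

Patch merging halves the grid between stages (widths 48/96/192/384 at
resolutions `H/2 … H/16`). The decoder mirrors the encoder,

    F_dec_i = Conv(Up(F_dec_{i-1}) ⊕ F_enc_i),

and a final `1×1×1` convolution plus per-voxel softmax yields
`Y_pred = Softmax(Conv1×1×1(F_dec_final))`. Evaluation uses the Dice
coefficient `2|T∩S|/(|T|+|S|)` and the 95th-percentile Hausdorff distance
between segmentation surfaces, in mm (spacing-aware). Training follows
AdamW (lr `1e-4`, weight decay `0.01`), soft-Dice + cross-entropy loss, an
80/20 split, rotation/scaling/elastic augmentation and early stopping.

## Worked example

Train a reduced-width model on synthetic multi-organ phantoms and evaluate
a held-out one:

```r
library(afnoseg)

spec  <- phantom_preset("btcv-like-mini")       # 1 channel, 3 classes, 48^3
ds    <- generate_dataset(spec, 8, seed = 7)
sp    <- split_dataset(ds, 0.8, seed = 7)       # 6 train / 2 test

cfg   <- encoder_config(stage_channels = c(8, 16, 32, 64))
model <- init_model(cfg, c(48, 48, 48), in_channels = 1, num_classes = 3,
                    seed = 7)
tc    <- train_config(learning_rate = 5e-3, max_epochs = 25, batch_size = 1,
                      augment = FALSE, seed = 7)
fit   <- train(model, sp$train, tc, verbose = TRUE)

ph   <- sp$test[[1]]
pred <- sliding_window_predict(fit$model, ph$volume, window = c(48, 48, 48))
evaluate(pred$labels, ph$labels)
```

The run prints one line per epoch (losses falling, validation Dice
rising — e.g. `epoch 25  train 0.1934  val 0.1696  val dice 0.9154`) and
ends with the held-out report:

```
<afno_metric_report>
 class      dice   hd95_mm n_voxels_gt n_voxels_pred
     1 0.9505049         1        8092          8051
     2 0.8664643         1         608           710
mean Dice 0.9085 | mean HD95 1.000 mm
```

Class 1 is the large organ analogue, class 2 the small one; Dice is
overlap (1 = perfect), and HD95 of 1 mm says the predicted surface is
within one voxel of the true surface for 95% of surface points.

A command-line front end wrapping the same functions ships in
`inst/cli/volseg` (`generate`, `train`, `predict`, `evaluate`
subcommands).

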