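# ghostherd

Lightweight convolutional networks for individual Holstein cow
identification from side-view coat patterns — built, audited and trained
entirely in R.

Holstein cows wear individually distinctive black-and-white blob patterns;
a classifier over side-view images identifies animals without tags or RFID.
`ghostherd` implements a lightweight identification network obtained by
reducing a 50-layer residual trunk to three stages and rebuilding it around
three components:

- a **dilated stem**: a 3×3 convolution with dilation rate 3, whose
  effective receptive field `d(k−1)+1 = 7` matches a 7×7 kernel at a 3×3
  kernel's parameter cost;
- **GhostBottlenecks**: residual blocks whose ghost modules compute only
  `1/s` of each feature map with a dense pointwise convolution and
  synthesize the rest with cheap depthwise operations
  (concatenated), cutting parameters where stacked convolutions are most
  redundant;
- **channel + spatial attention (CBAM)** after every stage: pooled channel
  descriptors gate "what", pooled channel maps gate "where", both through
  logistic squashing, with no change to activation shapes.

The head is a global average pool plus a fully-connected softmax
classifier. Since no deep-learning framework is available in this stack,
the entire engine — grouped/dilated convolution (im2col + GEMM via
RcppArmadillo), batch normalization, pooling, attention, softmax
cross-entropy, and momentum-SGD backpropagation — is implemented in the
package and validated against finite differences.

Around the network the package provides:

- an **exact accounting engine**: trainable parameters, multiply-accumulate
  operations, FP32 size (4 bytes/parameter, MiB convention), receptive
  fields, compression ratios, per-block reports (`count_parameters()`,
  `count_macs()`, `fp32_size_mib()`, `accounting_report()`,
  `ablation_report()`);
- a **configuration search** (`search_space()`, `search_to_target()`,
  `ledger_search()`) that reverse-engineers the unprinted trunk widths
  against a published per-variant parameter ledger using closed-form
  arithmetic — no weight allocation — and publishes minimal-gap
  configurations;
- the full **training recipe**: stratified 70/20/10 split with half-up
  rounding, lossless rotation tripling of the training set, bilinear
  resizing, Xavier initialization with zero biases, momentum SGD
  (0.9) with learning rate 0.001 decayed ×0.1 every 10 epochs,
  cross-entropy loss, best-validation checkpointing;
- a **synthetic herd generator** emulating the statistical shape of a
  13-cow side-view dataset (persistent thresholded-noise blob identities
  rendered under rotation, zoom, brightness and clutter), so the whole
  pipeline is testable without proprietary farm imagery;
- a command-line tool (`inst/cli/ghostherd`) with `generate`, `build`,
  `analyze`, `search`, `train`, `eval` and `report` subcommands.

## Worked example

```r
library(ghostherd)

# exact accounting of the unmodified baseline
baseline <- build_reference_resnet50(num_classes = 13)
count_parameters(baseline)
#> [1] 23534669
fp32_size_mib(count_parameters(baseline))
#> [1] 89.78
effective_receptive_field(kernel = 3, dilation = 3)
#> [1] 7

# the published final model counts 947,226 parameters:
compression_ratio(count_parameters(baseline), 947226)
#> [1] 24.85

# a synthetic herd, split and trained at desk scale
herd <- generate_dataset(herd_spec(master_seed = 101), "herd")
man <- augment_rotations(split_dataset(herd, seed = 201), seed = 202)
table(man$split)
#>  test train   val
#>    42   873    83

hyper <- desk_train_hyper()           # 10 epochs, 48 px, lr 0.01
lv <- sort(unique(man$identity))
tr <- load_manifest_images(man[man$split == "train", ], "herd", 48, lv)
va <- load_manifest_images(man[man$split == "val", ], "herd", 48, lv)
run <- fit_model(assemble_model(desk_model_config()), tr, va, hyper,
                 seed = 301, verbose = TRUE)
#> epoch  4 lr 1.0e-02 loss 0.4181 train_acc 0.891 val_acc 0.928 (16.2s)
#> ...
#> epoch  9 lr 1.0e-02 loss 0.0024 train_acc 1.000 val_acc 1.000 (16.5s)
run$best$val_acc
#> [1] 1
```

The first numbers are the exact architecture audit: the 13-class baseline
counts 23,534,669 trainable scalars (89.78 MiB at FP32), the dilated stem
sees a 7-pixel field, and the published lightweight model is 24.85× smaller.
The training run shows the full recipe driving the desk-scale model to
perfect held-out identification of the 13 synthetic identities within 10
epochs.

Searching the printed parameter ledger:

```r
ledger_search()
#>   variant   params size_mib printed_params  gap
#>  ResNet50 23534669    89.78       23534669    0
#>         A  1702733     6.50        1694925 7808
#>         B  1687373     6.44        1687437   64
#>         C   923117     3.52         923125    8
#>      Ours   947227     3.61         947226    1
```

The baseline row is exact by construction, and the search recovers the
ghost and final-model rows to within 8 and 1 parameters (sizes match the
printed 3.52 and 3.61 MB exactly). The residual A-row gap is structural:
the printed A-to-B delta of 7,488 parameters is unrealizable by a
7×7-to-dilated-3×3 stem swap at any integer stem width (the swap saves
`120 × w1`), so no single configuration can match both rows — the methods
vignette discusses this, and the published gap is the deliverable.

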