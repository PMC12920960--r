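# airseg

Interconnected attention blocks for 2D airway segmentation in R.

Segmenting the bronchial tree on CT slices is hard for two reasons:
airway pixels are a tiny fraction of each slice (and small branches a tiny
fraction of those), and airway lumina share their intensity range with
vessels, mucus and dense tissue, so thresholding fails. `airseg`
implements an attention block that refines encoder features of a
UNet-like segmentation network along five complementary axes —

* **IAM** (image attention): multi-head scaled dot-product attention over
  flattened spatial tokens, `softmax(QK'/sqrt(D))` with `D = C/heads`,
  reduced to one global gate per image;
* **PAM** (positional): per-pixel channel max/mean pooled maps through a
  `7x7` convolution, `sigmoid`, one weight per location;
* **SAM** (semantic): global spatial max/mean through a shared MLP, one
  weight per channel;
* **SCAM** (self-channel): squeeze-and-excitation-style bottleneck
  (`ratio = 16`) over global pools, one weight per channel;
* **CSAM** (cross-spatial): channel mean/max maps through a `k in {3,7}`
  convolution, one weight per location —

each stage gated in parallel by a **learnable variance-based embedding
(LEM)**: per channel, with spatial mean `mu` and unbiased variance
`sigma^2` (stabilised by `epsilon`),

    y = (x - mu)^2 / (k * sigma^2) + 0.5,    y' = sigmoid(y),

so features far from their channel mean (relative to the channel's own
variance) are emphasised. Defaults: `epsilon = 1e-4`, `k = 4`,
multiplicative scaling. Sequential, sum and parallel fusion of the five
stages are supported, as are patch- and CNN-embedding ablation baselines,
plain and residual UNet backbones, nested skip aggregation, a hybrid
Dice + IoU training loss, and a fully seeded training loop (Adam,
lr `1e-4`, weight decay `1e-5`, early stopping) — all implemented in
R/C++ with hand-derived backpropagation, validated against finite
differences and naive-loop oracles in the test suite.

Airway micro-CT corpora with expert masks are rarely shareable, so the
package ships
a synthetic branching-airway phantom generator: recursive tube trees with
per-generation radius decay (class imbalance on both axes), textured
noisy backgrounds, and bright elliptical distractors at airway-like
intensity that defeat global thresholding.

## Worked example

```r
library(airseg)

# a small corpus of 128x128 phantoms
corpus <- generate_corpus(phantom_spec(image_size = 128),
                          n_train = 200, n_test = 50, seed = 1)

# residual UNet, width 8, AirSeg block at the bottleneck
spec <- model_spec(backbone = "resunet", base_width = 8, depth = 4,
                   airseg = airseg_config(heads = 2),
                   airseg_placement = 4)
cfg <- train_config(batch_size = 2, max_epochs = 10,
                    early_stop_patience = 8, seed = 1)

fit <- train(spec, cfg, corpus$train, verbose = TRUE)
evaluate_dataset(fit$model, corpus$test)
#> Segmentation metrics over 50 images
#>   DSC  0.9033 +/- 0.0222
#>   IOU  0.8243 +/- 0.0366

threshold_baseline(corpus$test)$report
#> Segmentation metrics over 50 images
#>   DSC  0.7666 +/- 0.0481
#>   IOU  0.6239 +/- 0.0625
```

The trained network reaches a mean Dice similarity coefficient around
0.90 on held-out phantoms after ten epochs (about eight minutes on one
CPU core); the oracle-best global intensity threshold plateaus near 0.77
because the bright distractors are only separable by shape and context. `ablate()` trains and evaluates attention-subset ×
embedding × fusion grids on a shared test split, reporting mean ± SD
DSC/IoU per configuration with paired-difference statistics.

A thin command-line interface over these functions lives at
`inst/cli/airseg.R` (subcommands `generate`, `train`, `evaluate`,
`ablate`, each taking `--config <yaml> --seed <int>`).

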