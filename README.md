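# orchardvit

Class-imbalanced image classification for orchard fruit collections:
variety recognition, fresh-versus-rotten sorting, and disease phenotyping.
The package is built around two pieces:

* **The measured focal cross-entropy (MFCE) loss.** For a one-hot label
  with true-class probability `p`, cross-entropy `CE = -log p` penalises
  every mistake fully but lets abundant classes dominate the total loss;
  focal loss `F = (1-p)^γ · CE` discounts well-classified samples but also
  weakens the penalty on badly misclassified ones. MFCE blends the two
  with a probability-dependent softmax gate of sharpness `dv`:

  ```
  MFCE(p) = [ w(p) + (1 - w(p)) (1-p)^γ ] · CE(p),
  w(p)    = e^{(1-p)dv} / (e^{p·dv} + e^{(1-p)dv})
  ```

  so a poorly classified sample (`p → 0`) keeps a near cross-entropy
  penalty while a well-classified one receives the focal discount. For all
  `γ, dv ≥ 0`: `F ≤ MFCE ≤ CE` pointwise, with equality at `γ = 0`.

* **A configurable vision-transformer classifier** (patch embedding with a
  shared linear projection, learned positional encodings and a CLS token,
  a pre-norm multi-head-attention encoder stack, a GELU MLP head with
  softmax), with hand-written analytic gradients and Adam training — no
  external deep-learning framework. The reference geometry is 12 layers,
  hidden size 790, 12 heads, feed-forward width 3092, 6×6 patches on a
  70×70 input; tiny configurations run the identical code path.

Around them: a seeded synthetic generator of labelled fruit images whose
built-in designs reproduce the three study collections' counts exactly
(85 classes × 315/35, 2 × 1,044/116, 7 classes with 2,682/294 in total),
confusion-matrix evaluation with per-class precision/recall/F1 and
macro/weighted averages, stratified k-fold cross-validation, and a paired
class-imbalance loss-comparison experiment.

## A worked example

Scalar losses (values as printed):

```r
library(orchardvit)
cross_entropy(c(1, 0), c(0.5, 0.5))
#> [1] 0.6931472                       # ln 2
gate_weights(0.1, dv = 1)
#>         w_ce      w_f
#> [1,] 0.6899745 0.3100255            # the gate leans towards CE at p = 0.1
mfce_loss(1, c(0.5, 0.5), loss_params(gamma = 2, dv = 1))
#> [1] 0.433217                        # = 0.625 ln 2, between focal and CE
```

Generate an easy 3-class dataset, train a tiny transformer, evaluate:

```r
design <- easy_design(3, per_class_train = 64, per_class_test = 16,
                      image_size = 32)
generate_dataset(design, "orchard-demo", master_seed = 11)

cfg <- oaom_config(num_classes = 3, image_size = 32, patch_size = 8,
                   hidden_size = 32, num_layers = 2, num_heads = 2,
                   mlp_size = 64, head_widths = 32, dropout_rate = 0)
run <- oaom_train(cfg, "orchard-demo",
                  train_config(epochs = 30, batch_size = 32,
                               loss_kind = "mfce", seed = 1))
tail(run$history, 1)
#>    epoch  train_loss train_acc    val_loss val_acc
#> 30    30 0.003733238         1 0.003594795       1
run$test_report$accuracy
#> [1] 1
```

The model separates the hue-coded classes perfectly — the point of the
easy regime is that failures would indicate a defect, not a hard task.
The class-imbalance experiment compares losses under paired seeds and
identical initialisation:

```r
imb <- imbalance_design(2, 95, 5, 0.5, per_class_test = 20, image_size = 32)
tab <- imbalance_experiment(imb, c("ce", "mfce"), seeds = 1:5)
tab[is.na(tab$seed), c("loss_kind", "minority_recall", "accuracy")]
#>     loss_kind minority_recall accuracy
#>            ce            0.82    0.910
#>    ce_control            0.88    0.940
#>          mfce            1.00    1.000
```

Here MFCE recovers the 5-image minority class in every seed while plain
cross-entropy drops it in some; the `ce_control` arm (cross-entropy under
an independent training seed) shows the ce-vs-control gap is ordinary seed
noise.

A thin command-line front end wraps the same functions:

```sh
scripts/orchardvit datagen --preset afqc --out data/afqc --seed 1
scripts/orchardvit losscurves --loss mfce --gamma 0.5,2 --dv 0.5,5 --out curves.csv
scripts/orchardvit train --config run.yaml --data data/afqc
```

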