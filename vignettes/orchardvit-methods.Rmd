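---
title: "Methods: the MFCE loss family and the orchard vision transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MFCE loss family and the orchard vision transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Orchard image collections — apple variety recognition, fresh-versus-rotten
sorting, disease phenotyping — are almost never class-balanced: a handful of
common varieties or the healthy phenotype dominate, and the rare classes are
the ones a grower most needs recognised. A classifier trained with plain
cross-entropy allocates most of its total loss to the abundant classes and
drifts towards them; focal loss counteracts this by discounting
well-classified samples, but it also *weakens* the penalty on badly
misclassified samples, exactly the samples that carry the minority signal.

`orchardvit` implements a loss family that interpolates between the two, a
configurable vision-transformer classifier trained with it, a seeded
synthetic image generator that emulates the structure of the three orchard
collections, and the evaluation and experiment machinery around them.

## The measured focal cross-entropy (MFCE) loss

For a one-hot label with true class $s$ and a predicted probability vector
$p$, write $p_s$ for the true-class probability. The three losses are

$$
\mathrm{CE}(p_s) = -\log p_s, \qquad
\mathrm{F}(p_s) = (1-p_s)^\gamma \,\mathrm{CE}(p_s),
$$

$$
\mathrm{MFCE}(p_s) = \bigl[\,w(p_s) + (1-w(p_s))\,(1-p_s)^\gamma\,\bigr]
\,\mathrm{CE}(p_s),
\qquad
w(p) = \frac{e^{(1-p)\,dv}}{e^{p\,dv} + e^{(1-p)\,dv}}.
$$

$w(p)$ is a two-way softmax gate over the exponents $p\,dv$ and
$(1-p)\,dv$: for a poorly classified sample ($p \to 0$) the gate opens
towards the cross-entropy term, so the sample keeps its full penalty; for a
well-classified sample ($p \to 1$) it opens towards the focal term, so the
sample is discounted. The sharpness parameter $dv \ge 0$ controls how fast
the gate switches; $dv = 0$ freezes it at an even blend, and at $p = 1/2$
symmetry forces $w = 1/2$ for every $dv$, giving the closed form
$\mathrm{MFCE}(1/2) = \tfrac12 (1 + 2^{-\gamma}) \ln 2$ that the tests pin.

Because $w \in (0,1)$ and $(1-p)^\gamma \le 1$, the mixture is a convex
combination of the CE and focal integrands, so

$$\mathrm{F} \;\le\; \mathrm{MFCE} \;\le\; \mathrm{CE}$$

pointwise for every $\gamma \ge 0$ and $dv \ge 0$, with all three equal at
$\gamma = 0$. The test suite verifies this ordering on a 999-point
probability grid against a $\{\gamma\} \times \{dv\}$ lattice.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `gamma` | focusing exponent (unitless, $\ge 0$) | 2 | the conventional focal-loss setting |
| `dv` | gate sharpness (unitless, $\ge 0$) | 1 | a mid-range gate: visibly probability-dependent without saturating |
| `epsilon` | log-clipping floor | 1e-7 | keeps $\log p$ finite in single-sample edge cases |
| `reduction` | batch reduction | mean | scale-free in the batch size |

### The gate-exponent convention

The gate's typeset form is ambiguous between $e^{(1-p)\cdot dv}$ and
$e^{(1-p)/dv}$. Only the multiplicative reading makes larger `dv` pin the
loss to cross-entropy near $p = 0$ (the divisive reading does the
opposite, as a unit test demonstrates), so the multiplicative form is the
default; `gate_convention = "divisive"` is exposed for completeness. The
gate is evaluated as `plogis((1 - 2p) * dv)`, a numerically stable logistic
form that cannot overflow at large `dv` and makes $w_{ce} + w_f = 1$ exact.

### Gradients

No automatic-differentiation framework is used: the package ships analytic
gradients. With a one-hot label the loss depends on $p$ only through
$p_s$, so for logits $z$ with $p = \mathrm{softmax}(z)$,

$$
\frac{\partial L}{\partial z_k} = f'(p_s)\, p_s (\mathbb{1}[k = s] - p_k),
$$

where $f'$ is the derivative of the scalar loss core (for MFCE this
includes the gate's own derivative $w' = -2\,dv\,w(1-w)$). In the gradient
path $p$ is clipped to $[\epsilon, 1-\epsilon]$ so the
$(1-p)^{\gamma-1}$ factor stays finite for $\gamma < 1$. Every loss
gradient, and the full model backward pass, is checked against central
finite differences at relative tolerance $10^{-4}$.

## The classifier

The classifier is a standard pre-norm vision transformer: the image is
tiled into non-overlapping `Ph x Pw` patches in row-major order, each
flattened patch is mapped by one *shared* affine projection to width `D`, a
learned positional-encoding vector (indexed by the integer patch position)
is added, and a learned CLS token is prepended. Each encoder block computes
`x + MHSA(LN(x))` then `y + FFN(LN(y))` with a two-layer GELU feed-forward;
the CLS token after a final layer norm drives a GELU MLP head and a softmax
over classes. The reference geometry is 12 layers, `D = 790`, 12 heads,
feed-forward width 3092, 6-pixel patches on a 70-pixel input; the tests run
the identical code path at 2 layers / `D = 32`.

Where the architecture description leaves choices open, the package makes
them explicit:

* **Boundary policy.** 70 is not divisible by 6, so the patch-count rule
  $N = (H \times W)/(P_h \times P_w)$ cannot hold exactly.
  `boundary_policy = "resize"` (default) rescales bilinearly to the nearest
  multiple (70 → 72, $N = 144$); `"crop"` drops the bottom/right remainder
  ($N = 11^2 = 121$). Both are exposed in the configuration.
* **Head width.** 790 is not divisible by 12 heads, so `head_dim` is an
  independent parameter (default `floor(D / num_heads)` = 65) and the
  concatenated heads are projected back to `D` by an output matrix,
  honouring the stated sizes without divisibility constraints.
* **Positional encodings** are a learned `N x D` table ("an integer
  between 1 and n" maps to a vector), not sinusoidal; the CLS token
  receives none. With the table zeroed, the CLS logits are provably
  invariant to patch permutation — a property test.
* **Regularisation** is inverted dropout (default 0.1) after the attention
  and feed-forward sublayers and after head activations, at train time
  only.
* **Nonlinearity** is exact GELU ($x\,\Phi(x)$), the convention for this
  architecture family; **attention scaling** is $1/\sqrt{\text{head\_dim}}$;
  a **final layer norm** precedes the head, as pre-norm stacks require for
  a scale-controlled CLS readout.
* **Initialisation** is Gaussian with sd 0.02 for projections, zeros for
  biases, ones/zeros for layer-norm gains/biases.

The forward and backward passes are hand-written base-R matrix algebra
(BLAS-backed); there is no compiled code and no external deep-learning
dependency.

## The synthetic orchard generator

The generator emulates the *statistical structure* of the three
collections, not their photographs:

* **Variety classes** (the 85-class design) differ by fruit hue, spaced
  evenly on the colour wheel, and by cycling ellipse eccentricities.
* **Fresh vs rotten** (2 classes) differ by an expanding brown rot region
  covering about half the fruit.
* **Disease phenotypes** (7 classes) each get a distinct lesion operator:
  irregular dark blotches, ringed brown rot, dimpled cork spots, a pale
  powdery-mildew overlay, expanding rot, small scab dots, or none.

Each image is an elliptical fruit with radial shading and a specular
highlight on a cluttered background (a smooth random field), plus Gaussian
pixel noise. Rendering is a pure function of `(spec, seed)`; per-image
seeds derive from the master seed by a stable counter rule
(`seed + 69069 * image_id mod 2147483629`, where `image_id` encodes class,
split and index), so any subset regenerates identically and PNG output is
byte-exact across runs. "Easy" designs (low clutter/noise, well-separated
hues) exist so that a mean-colour linear probe reaches over 90% accuracy —
the generator demonstrably emits learnable signal, which is what makes the
training tests informative.

The built-in designs reproduce the published counts exactly: 85 classes
with 315/35 train/test each (29,750 images); 2 classes with 1,044/116 each
(2,320); 7 classes with 2,682/294 in total. The 7-class per-class breakdown
is not published, so train counts are spread as evenly as 2,682/7 allows
(384 for the healthy class, 383 elsewhere) and test counts are 42 per
class; only the totals are claimed. Default image size is 96 px for
desk-scale speed (the presets accept any size). What the generator does
*not* emulate: photographic texture, lighting and camera variation,
background diversity, within-class shape detail. Passing tests therefore
establish the correctness and the comparative behaviour of the losses and
the training machinery on images with a recoverable signal — not
photographic-scale accuracy numbers.

## The training pipeline

Training minimises the selected batched loss with Adam (default learning
rate 0.001, the reference setting; $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$). Every source of randomness — initialisation, the
validation carve, shuffling, dropout — derives from the single
`train_config` seed, so runs are exactly reproducible; changing only the
loss kind leaves the initial weights bit-identical, which is what makes
loss comparisons paired.

* **Splits.** The dataset layout separates train and test; the pipeline
  carves a stratified validation subset from train (default 1/9, giving
  80/10/10 overall). Every class with at least two training images keeps at
  least one image on each side of the carve — a validation set missing a
  minority class entirely would let a majority-collapsed model win
  checkpoint selection.
* **Checkpointing** keeps the best validation accuracy, ties broken by the
  earliest epoch.
* **Cross-validation** pools train and test and deals each class's shuffled
  indices round-robin into k folds, keeping per-fold class proportions
  within one sample of the global ones.
* **The imbalance experiment** trains each loss kind on the same per-seed
  dataset from the same initialisation and reports minority-class
  recall/F1, macro-F1 and accuracy per `(loss, seed)` with seed-averaged
  rows. Its `ce_control` arm reruns cross-entropy from an independently
  derived training seed: since a literal rerun would be bit-identical (a
  determinism check, not a control), the control instead measures pure
  seed-to-seed noise, which should centre at zero paired difference.

### Problem sizes used by the tests and the acceptance script

The package's own evidence runs at desk scale, chosen so the full suite
completes in minutes on one CPU: the overfit check uses 3 easy classes
with 64 training images each at 32 px and a 2-layer, width-32 model for 30
epochs; the imbalance experiment uses a 95:5 two-class easy design (95 + 5
training images, 20 test images per class) with $\gamma = 2$, $dv = 1$,
five paired seeds, and the same 30-epoch budget — at much shorter budgets
both arms remain at the all-majority collapse and the comparison is
degenerate. The reference 12-layer configuration is constructed and
shape-checked, but not trained: photographic-scale accuracy reproduction
is explicitly out of scope.

## Known limitations

* Single-threaded, per-sample backward passes: intended for study-scale
  experiments, not photographic datasets.
* Only non-overlapping patch tiling (`stride = patch_size`) is
  implemented.
* The synthetic images are deliberately simple; conclusions about real
  orchard photographs require the real collections.
* JPEG input is not read; datasets are PNG (the generator's output format).

## A worked session

```{r example}
library(orchardvit)

design <- easy_design(3, per_class_train = 64, per_class_test = 16,
                      image_size = 32)
generate_dataset(design, "orchard-demo", master_seed = 11)

cfg <- oaom_config(num_classes = 3, image_size = 32, patch_size = 8,
                   hidden_size = 32, num_layers = 2, num_heads = 2,
                   mlp_size = 64, head_widths = 32, dropout_rate = 0)
run <- oaom_train(cfg, "orchard-demo",
                  train_config(epochs = 30, batch_size = 32,
                               loss_kind = "mfce", seed = 1))
run$test_report
```
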