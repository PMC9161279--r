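---
title: "Two-stream segmentation and leaf counting: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stream segmentation and leaf counting: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Top-down images of rosette plants such as Arabidopsis carry two of the most
widely used phenotyping traits: the projected plant area (via a whole-plant
binary segmentation) and the leaf count. The two traits are tightly linked —
leaf number correlates with area, age and genotype — which motivates a
two-stream architecture in which the segmentation stream's output, the
segmented binary mask (SBM), is fed to the counting stream as an auxiliary
input cue. The mask suppresses soil, moss and pot clutter, and in practice
stabilises the count regression.

`leafseg` implements both streams natively: all convolution, pooling and
upsampling kernels plus a small reverse-mode autograd tape live inside the
package (C++ via Rcpp), so everything runs on a plain CPU.

## Segmentation stream

The segmentation network is a five-level encoder–decoder with *nested dense
skip pathways*. Nodes are indexed $x^{i,j}$ with resolution level $i$
(spatial size halved per level by 2×2 max pooling) and skip depth $j$:

$$
x^{i,j} =
\begin{cases}
\mathcal{H}(x^{i-1,0}) & j = 0\\
\mathcal{H}\big(\big[[x^{i,k}]_{k=0}^{j-1},\ \mathcal{U}(x^{i+1,j-1})\big]\big) & j > 0
\end{cases}
$$

so node $(i, j>0)$ concatenates its $j$ same-level predecessors with one
upsampled lower-level output and has in-degree $j+1$; the index set is
triangular with $L(L+1)/2$ nodes for $L$ levels. Each $\mathcal{H}$ is two
3×3 convolutions, each followed by a ReLU. The head is a 1×1 convolution
with a logistic activation on $x^{0,L-1}$, turning whole-plant segmentation
into per-pixel binary classification. `build_node_graph()` exposes the graph
structure directly so the architecture is testable independently of the
weights.

Foreground pixels are a small minority of a pot image, so training combines
binary cross-entropy with the Dice overlap
$d = 2|X \cap Y|/(|X|+|Y|)$:

$$
\mathcal{L} = w_{\mathrm{bce}}\,\mathrm{BCE}(Y_{\mathrm{pred}}, Y_{\mathrm{gt}})
 + w_{\mathrm{dice}}\,(1 - d(Y_{\mathrm{pred}}, Y_{\mathrm{gt}})),
$$

averaged over the batch, with default weights $(1/2, 1)$. A literal
per-pixel variant of the combined expression, as sometimes printed, is
available as
`loss_form = "as_printed"` for comparison; it is not usable as a training
objective because every summand vanishes on background pixels and the
optimum is negative, which is why the standard decomposition above is the
default.

An optional boundary weight map emphasises pixels near mask boundaries:

$$
w(x) = w_c(x) + w_0 \exp\!\left(-\frac{(d_1(x)+d_2(x))^2}{2\sigma^2}\right)
$$

with $w_c$ the inverse-frequency class weight ($0.5/\mathrm{freq}$, so a
balanced mask weighs both classes 1), $d_1$/$d_2$ the Euclidean distances to
the nearest and second-nearest foreground-component boundary, $\sigma = 0.5$
px and $w_0 = 10$ by default. With a single component we set $d_2 = d_1$:
the original purpose of the two-distance term — separating touching objects
— is vacuous for whole-plant masks, and this choice keeps the exponent
continuous. The map is **off** by default because the combined objective
above carries no weight term; it is exposed as
`use_boundary_weight_map = TRUE` and is verified against an
exhaustive-distance oracle in the tests.

### Numerical and architectural choices

* **Upsampling** $\mathcal{U}$: bilinear ×2 followed by a learned 1×1
  channel reduction by default; a learned 2×2 stride-2 transposed
  convolution is available (`upsample_mode = "transposed_conv"`).
* **Widths**: the desk profile (8, 16, 32, 64, 128) trains in CPU minutes;
  a conventional paper-scale profile (32, 64, 128, 256, 512) is a config
  choice away. Channel widths at paper scale follow the common U-Net-family
  convention; they are an assumption, not a documented setting.
* **Deep supervision** is off by default; when on, the shared head is
  applied to every $x^{0,j}$ and probabilities are averaged. A pruning
  scheme over the intermediate heads is *not* implemented: no usable
  selection criterion is documented for it.
* **Binarisation** at 0.5, the logistic midpoint.
* **Probabilities** are clamped to $[10^{-7}, 1-10^{-7}]$ inside the loss;
  gradients are taken analytically with respect to the logits, which avoids
  the usual numerical blow-up of differentiating through the sigmoid at
  saturation.

## Counting stream

The counter is a residual regression network. Each residual unit is

$$ y_l = h(x_l) + F(x_l, W_l), \qquad x_{l+1} = f(y_l) $$

with $h$ the identity and $f$ a ReLU, so a stack of units with zeroed
branches is exactly the identity and gradients reach shallow layers
unattenuated ($x_L = x_l + \sum_{i=l}^{L-1} F(x_i, W_i)$). The last layer is
a single-output fully connected head on a global average pool, and training
minimises the mean squared error $\frac1m \sum_i (y^i_{\mathrm{pred}} -
y^i_{\mathrm{gt}})^2$ on raw (unrounded) predictions. Reported counts are
rounded half away from zero and floored at 0; both raw and rounded values
are returned because reporting practice varies on which enters the count
metrics.

Four input schemes couple the streams (`count_config(input_mode = ...)`):

* `rgb` — image only (the ablation baseline);
* `rgb_mask_channel` — the binary mask as a fourth input channel;
* `mixture` — two 3-channel items per sample, the RGB image and the mask
  replicated to three channels, both with the same count label;
* `rgb_x2` — the RGB item duplicated, a sample-doubling control.

The channel-extension and mixture schemes are both legitimate ways to
inject the mask cue, and neither is privileged; the package defaults to
`rgb_mask_channel` as the tighter coupling. During training the mask comes
from the ground truth; at inference it defaults to the segmentation
stream's prediction (`run_two_stream()`), with ground-truth masks allowed
for oracle experiments. ImageNet pre-training is replaced by a hook for
externally supplied initial weights (`train_config(init_params = ...)`);
when 3-channel stem weights are loaded into a 4-channel model the extra
channel is initialised to the mean of the RGB filters.

The desk profile uses 4 residual blocks, widths (16, 32, 64, 128), a 3×3
stem and 64×64 inputs; a paper-scale backbone (16 blocks, 7×7 stem,
224–480 px inputs) is reachable through the same config.

## Training recipe

`train_config()` defaults are the reference recipe: Adam, 100 epochs,
batch size 4, learning rate $10^{-3}$, weight decay $10^{-4}$. A reduction
factor of 0.1 coexists in that recipe with a constant learning rate; we
read the factor as an optional plateau-based reduction and disable it by
default (`reduce_on_plateau = FALSE`). Weight
decay is folded into the Adam gradient (classic L2, not decoupled). Both
trainers checkpoint the best validation model (IoU for segmentation, ADiC
for counting) and log a per-epoch history. One global seed fans out through
`derive_seed()` to data generation, splitting, weight init, shuffling and
augmentation, making a full pipeline run bit-reproducible.

## Data pipeline and augmentation

Images load as `[0, 1]` float arrays; masks are thresholded at 0.5 to
strict {0, 1} (they are stored as {0, 255} 8-bit PNGs, the CVPPP
convention). `resize_pair()` resizes images bilinearly and masks by nearest
neighbour with re-binarisation. Augmentation follows the standard paired scheme —
90° rotations, flips (h/v/hv), random rescaling, gamma, brightness,
contrast, HSV shifts, normalisation — applied on the fly each epoch, with
geometric steps applied identically to image and mask and photometric steps
to the image only. The scale range of the resize step is a free choice, exposed as a config
range with default [0.8, 1.2]. Every applied step and
its drawn parameters are returned in the augmentation log, which the test
suite replays through an independent oracle. Normalisation defaults to per-channel `[0, 1]` scaling; optional mean/std
standardisation constants can be stored in the config.

## The synthetic rosette generator

Training-recovery experiments need labelled imagery with known ground
truth, so the generator renders CVPPP-style rosettes: `n_leaves` teardrop
leaves (an ellipse family sheared toward the tip; ellipse-family shapes reproduce
the occlusion patterns that matter without modelling true leaf geometry) radiating from a jittered centre, at successive
golden-angle (137.5°) offsets with ±10° noise — the phyllotaxis typical of
rosettes — or at uniform random angles for worst-case overlap. Each leaf
gets its own length, width, green shade, midrib darkening and tip-ward
brightness gradient; backgrounds are flat grey (`plain`), low-frequency
brown noise with speckle and sparse moss patches (`soil`), or soil plus a
terracotta pot rim and bench surround (`soil_with_pot`) as clutter the mask
channel is meant to suppress. The mask is the exact union of the rasterised
leaf polygons and the count is the number of leaves drawn, so labels are
correct by construction even under heavy occlusion. The default count range 1–12 is a free choice covering young through
mature rosettes, exposed as a parameter.

What the generator does *not* emulate: real leaf texture and venation,
petioles, specular highlights, shadows, camera noise, inter-dataset domain
shift, and tobacco-specific morphology. Passing the training-recovery
tests therefore shows that the implementation can fit and generalise on
imagery with the right coarse statistics — it does not certify benchmark
accuracy on real CVPPP images, which would require the external dataset
and GPU-scale training.

## Problem sizes used by the tests and the acceptance script

The package's experiments are deliberately desk-scale, chosen once as the
smallest sizes at which recovery is meaningful: segmentation trains on 64
synthetic 64×64 soil-background rosettes for 30 epochs (validation IoU
well above 0.85 at convergence); counting trains on 200 rosettes with 1–8
leaves over cluttered backgrounds for 40 epochs, in the mask-guided and
RGB-only modes (held-out ADiC within one leaf for the mask-guided mode,
and the mask-guided mode no worse than RGB-only on average — the
directional content of the mask ablation). The test suite runs the
counting ablation at two seeds and the pipeline-determinism check at a
reduced 32 px / 2-epoch scale.

## Known limitations

* The engine is CPU-only and sized for desk-scale experiments; paper-scale
  profiles run but are slow without a GPU framework.
* Whole-plant semantic segmentation only — no per-leaf instance masks, and
  counting is pure regression (no detection or localisation).
* The `as_printed` loss and `dice_style` overlap exist for fidelity
  comparisons, not for training or reporting.
* Macro (per-image mean) aggregation is the reporting default; micro
  (pooled-pixel) aggregation is available as an option.
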