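# leafseg

Two-stream segmentation and leaf counting for rosette plant phenotyping.

Top-down images of rosette plants (Arabidopsis and similar) carry two core
phenotyping traits: the whole-plant silhouette and the leaf count. `leafseg`
implements a two-stream convolutional framework that extracts both, for
plant scientists and phenotyping-pipeline developers who want a fully
self-contained, CPU-only, seed-reproducible implementation:

* **Segmentation stream** — a five-level encoder–decoder with nested dense
  skip pathways: node $x^{i,j}$ receives its $j$ same-level predecessors
  plus one upsampled lower-level output ($x^{i,0}$ receives only the pooled
  encoder input), each node being two 3×3 convolutions + ReLU, with a 1×1
  logistic head. Trained with the combined objective
  $w_\mathrm{bce}\,\mathrm{BCE} + w_\mathrm{dice}\,(1 - \mathrm{Dice})$,
  optionally weighted near mask boundaries by
  $w(x) = w_c(x) + w_0 e^{-(d_1+d_2)^2/2\sigma^2}$.
* **Counting stream** — a residual regression network
  ($x_{l+1} = \mathrm{ReLU}(x_l + F(x_l))$, global average pool, single
  output neuron, MSE loss) that estimates the leaf count directly. The
  segmented binary mask (SBM) is fed to the counter as an auxiliary cue —
  as a fourth input channel or as extra mask-only training samples — to
  suppress soil/pot clutter.
* **Metrics** — IoU, precision, recall per mask; DiC $=\frac1m\sum(y_{gt} -
  y_{pred})$, ADiC and MSE per split.
* **Synthetic rosette generator** — seeded, phyllotaxis-based rendering of
  overlapping teardrop leaves over plain/soil/pot backgrounds with exact
  masks and counts by construction, so the whole pipeline trains and
  evaluates at desk scale without any external dataset.

All network kernels (convolution, pooling, bilinear upsampling) and a small
reverse-mode autograd engine are implemented in the package itself
(Rcpp/RcppArmadillo) — no external deep-learning framework is required.

## Worked example

```r
library(leafseg)

## 1. a labelled synthetic dataset (images + {0,255} masks + CSV manifest)
dir <- file.path(tempdir(), "rosettes")
manifest <- generate_dataset(64,
  rosette_sampler(image_size = 64, n_leaves_range = c(1L, 10L),
                  background_mode = "soil"),
  seed = 424, out_dir = dir)
manifest <- split_dataset(manifest, ratio = 0.8, seed = 3)

## 2. train the segmentation stream (desk profile, ~6 min on one CPU)
seg <- train_segmentation(manifest, seg_config(),
  train_config(epochs = 30, batch_size = 4, seed = 11, input_size = 64))

## 3. train the counting stream with the mask as a fourth channel
cnt <- train_counter(manifest, count_config(input_mode = "rgb_mask_channel"),
  train_config(epochs = 30, batch_size = 4, seed = 11))

## 4. run both streams on a new image
sample <- generate_sample(rosette_spec(n_leaves = 7, seed = 2026))
out <- run_two_stream(sample$image / 255, seg, cnt)
out$count
#> leaf count: raw 6.472, rounded 6

## 5. evaluate over the held-out split
print(evaluate_split(manifest, "val", seg_model = seg, count_model = cnt))
#> Evaluation over split 'val' (13 images, macro aggregation)
#>   segmentation: IoU 0.9897 | Precision 99.17% | Recall 99.79%
#>   counting:     DiC -0.154 | ADiC 0.769 | MSE 1.231
```

The segmentation row says the predicted silhouettes overlap the true plant
masks by ~99% on held-out images. The counting row (computed here with the
segmentation stream's predicted masks feeding the counter) says the model
is on average within 0.8 leaves of the truth, with a slight tendency to
over-count (negative DiC, since DiC is mean of truth minus prediction).

A command-line wrapper over the same functions ships in
`inst/cli/leafseg.R` (`generate`, `train-seg`, `train-count`, `predict`,
`predict-count`, `evaluate`, `run-all`).

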