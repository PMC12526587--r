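---
title: "Pseudo-label conditional adversarial adaptation for Raman spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-label conditional adversarial adaptation for Raman spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cdanpl)
```

## The problem

Serum Raman spectroscopy gives a cheap, label-free molecular fingerprint of
a blood sample, and supervised classifiers on such spectra can diagnose
disease with high accuracy — when a large, reliably labeled cohort exists.
For autoimmune disease that assumption routinely fails: diagnoses are
exclusionary and labels are scarce and noisy, and spectra acquired on a
different spectrometer (or for a related disease) follow a different
distribution than the labeled cohort. `cdanpl` implements an unsupervised
domain adaptation (UDA) pipeline for this setting: a labeled *source*
domain $D_s = \{(x_s, y_s)\}$ and an unlabeled *target* domain
$D_t = \{x_t\}$ with $P_s(x, y) \neq P_t(x, y)$, where the goal is a
classifier that works on the target domain without ever seeing a target
label.

## The model

Three trainable components play a conditional adversarial game:

* **Feature extractor `G`** — dual-branch: a self-attention (transformer)
  encoder over linear patch embeddings of the spectrum, in parallel with
  multi-scale 1-D convolutions (kernels 3/7/15, ReLU, global average
  pooling); the branch outputs are concatenated and fused by one fully
  connected layer with ReLU and LayerNorm into a `feature_dim`-dimensional
  representation.
* **Classifier `C`** — a single linear + softmax head on the features; it is
  simultaneously the "neuron prediction" read by the pseudo-label
  generator.
* **Conditional domain discriminator `D`** — two ReLU hidden layers with
  dropout and a sigmoid output, consuming the multilinear map
  $\phi(f, g) = f \otimes g$ of features with class probabilities, so the
  domain alignment is conditioned on the class structure rather than on
  marginal features alone.

Training losses, per batch:

* source classification cross-entropy $L_{cls}$;
* adversarial loss
  $L_{adv} = -\mathbb{E}_s \log(1 - D(\phi(f_s, g_s)))
             -\mathbb{E}_t \log D(\phi(f_t, g_t))$,
  minimized by `D` and maximized by `G` through gradient reversal;
* a Fisher-style metric-constraint loss
  $L_{MC} = \log \frac{\sum_{y_u \neq y_v} e^{-d_{uv}/T_m}}
                      {\sum_{y_u = y_v,\,u \neq v} e^{-d_{uv}/T_m}}$
  over squared pairwise feature distances $d_{uv}$, with normalization
  $T_m = \frac{1}{B}\sum_{u \neq v} d_{uv}$, which keeps classes separable
  while the adversary confuses the domains;
* pseudo-label cross-entropy $L_{CE}$ on confidence-filtered target
  samples.

`G` and `C` descend $L_{cls} + L_{CE} + \lambda (L_{MC} - L_{adv})$; `D`
descends $L_{adv}$. Both updates run from one forward pass per step under
RMSprop.

Pseudo-labels are regenerated from the current model at every epoch: the
classifier's softmax output ("neuron" probabilities) is fused at decision
level with the class frequencies of the $K$ Euclidean nearest labeled
source samples in feature space (KNN probabilities), as
$w \cdot p_{neuron} + (1 - w) \cdot p_{knn}$; samples whose fused
confidence does not exceed $\kappa$ are dropped from the pseudo-label
losses for that epoch.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lr` | 1e-5 | RMSprop learning rate (published setting) |
| `batch` | 32 | batch size, both domains (published setting) |
| `iterations` | 500 | training iterations; see below |
| `lambda` | 1.0 | adversarial/MC weight; optional 0→1 warm-up over the first 30% of updates |
| `K` | 5 | KNN neighbors for pseudo-labels |
| `kappa` | 0.9 | confidence threshold; strict, following the high-reliability intent |
| `w` | 0.5 | decision-fusion weight; the symmetric prior between neuron and KNN paths |
| `feature_dim` | 64 | fused feature width (512 in the desk-scale experiment config) |

Unstated architecture sizes (patching, widths, depths, discriminator shape)
are configuration with documented defaults in `net_config()`; none of the
method's claims depend on them.

### Reading "iterations"

The published optimizer settings pin the learning rate at `1e-5` for 500
iterations. Under RMSprop the per-update parameter displacement is at most
`lr` (the update is `lr * g / sqrt(v)` with `v ≈ g²`), so 500 single-batch
updates can move any weight by at most `5e-3` — about 3% of the Xavier
initialization scale of any layer — and no network can leave its
initialization under that reading; a direct simulation of a linear head on
perfectly separated features confirms it stays at chance. We therefore
count an iteration as one epoch over the balanced source training pool
(`ceiling(n / batch)` updates), which reproduces learning at the published
learning rate; `iteration_unit = "step"` keeps the literal reading
available.

### Which probabilities feed what

The confidence filter is applied to the **fused** probabilities, since the
fused prediction is the final one; the discriminator's conditioning vector
uses the classifier's softmax output and is treated as a constant during
backpropagation (matching the reference conditional-adversarial design);
`condition_grad = TRUE` propagates adversarial gradients through the
conditioning as the literal objective prescribes. The MC batch contains the
source batch plus the kept pseudo-labeled target samples by default
(`mc_on_targets = FALSE` restricts it to source samples). The printed
$1/B$ prefactor of $T_m$ is the default; the conventional pair-count mean
is available (`tm_mode = "pairmean"`) and only rescales $T_m$, which the
loss's scale invariance absorbs.

## Preprocessing stack

Fixed order per spectrum: iterative polynomial baseline correction
(modified polyfit: degree 3, up to 100 refits, points above the running fit
clipped to it, stopping when the relative residual change falls below
0.001) → mean smoothing (window 9, shrink-to-valid at the edges, so no
intensities are invented outside the measured range) → per-spectrum min-max
normalization to [0, 1]. Healthy controls are split 1:1 between the
domains, each domain 7:3 into train/test (stratified — the source of the
split being stratified is a package choice, exposed in `split_spec()`).
SMOTE oversamples every training class to 300 rows (k = 5 same-class
neighbors, convex interpolation; classes already at the target are left
alone; test sets are never balanced). When the two domains sit on different
wavenumber grids, both are linearly resampled to the shorter grid and
projected onto one PCA basis (50 components, fitted on the pooled training
rows, warning if the cumulative explained variance drops below 99%) so the
adversarial game sees a single feature space.

Note that balancing the *target* training pool uses the sealed labels only
through class counts, mirroring the original protocol in which target
labels exist but are withheld from training.

## The synthetic generator

Clinical serum spectra are not distributable, so the package ships a
generator that emulates the study conditions: each spectrum is a sum of
Gaussian peaks (positions echo serum bands commonly assigned to
proline/valine ~924, phenylalanine ~991, guanine ~1317, lipids ~1444
cm⁻¹) with an additive disease amplitude at designated peaks, a cubic
fluorescence baseline, multiplicative gain, per-sample peak jitter and
i.i.d. noise, on a 600-point 500–2000 cm⁻¹ grid. Cohort sizes default to
the original study scale (34 source / 68 target controls, ~70 disease
each). Because
baseline and gain are removed by preprocessing *by construction*, a domain
shift that only changed them would vanish before training; the generator
therefore also supports two instrument effects that do survive
preprocessing: per-peak response factors emulating the different
excitation wavelengths of the two spectrometers (785 vs 532 nm), and a
systematic wavenumber calibration offset between the setups. Calibrating
the presets showed these act very differently on the two pseudo-label
paths: a response tilt misleads the classifier head before it corrupts
feature-space neighborhoods, while a large calibration offset corrupts
nearest-neighbor geometry (and with it the KNN pseudo-labels) even where
the classifier still transfers. The presets were calibrated once against
their prescribed roles: `easy` must be learnable (a source linear probe
exceeds 0.95) yet leave a real transfer gap for the network, so it pairs a
mild response tilt with a small calibration offset; `hard` pushes both
effects and must open a ≥10-point probe gap; `nonhomologous_like` places
the domains on different grids to exercise the PCA path.

What passing on synthetic data does **not** show: Gaussian peaks carry no
Lorentzian/Voigt line shapes, no cosmic-ray spikes, no detector
nonlinearity, and the class signal is exactly peak-local — so localization
results (Grad-CAM) are cleaner than clinical reality, and absolute
accuracies do not transfer to clinical claims. Directional results
(adaptation beats no adaptation; pseudo-labels help) are what the
synthetic experiments establish.

## Numerical choices

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside every logarithm,
  keeping all losses finite on saturated outputs.
* Degenerate MC batches (no cross-class or no same-class pair, or zero
  $T_m$) return 0 with a skip flag and the term is omitted for that step.
* An empty kappa-filtered set skips the pseudo-label CE term for that
  epoch and flags the pseudo-label set.
* KNN majority ties break by the smallest summed neighbor distance, then
  the lowest class code; fusion argmax ties break to the lowest code.
* Baseline fitting uses an orthogonal polynomial design on a centred,
  scaled abscissa (QR solve), so degree-3 fits on 600-point grids stay well
  conditioned.
* Xavier initialization is the uniform Glorot draw; biases start at zero,
  LayerNorm gains at one. All randomness (init, batching, dropout, SMOTE,
  t-SNE) derives from explicit seeds; identical seed + config + data
  reproduce training bit-exactly.
* t-SNE is the exact O(n²) algorithm (perplexity 30, 1000 iterations,
  early exaggeration, pinned seed), adequate at the sample counts involved;
  the alignment diagnostic compares the silhouette of the class labeling
  against that of the domain labeling on pooled features.
* Grad-CAM attributes through the convolution branch only (the token
  branch has no positional feature maps): channel weights are mean
  gradients of the class logit w.r.t. the post-ReLU maps; rectified
  weighted sums are linearly interpolated onto the wavenumber grid, summed
  over kernel scales, averaged over spectra, and min-max normalized; local
  maxima above 0.5 are the key characteristic peaks.

## Desk-scale experiment sizes

The end-to-end experiments (and the acceptance script) run on a single CPU
with a deliberately scaled instantiation: the `easy` preset at its default
cohort sizes, SMOTE to 300/class, and `compact_net_config()` — a wide,
shallow G (feature_dim 512, d_model 32, one encoder layer, 4-channel
convolutions at stride 4) trained for 100 epochs at the published batch
size and learning rate, three runs per mode. The width is not cosmetic: at
a pinned `lr = 1e-5` the number of RMSprop updates the softmax head needs
to escape its Xavier initialization scales inversely with `feature_dim`,
so a wide fusion layer trains in ~2×10³ updates where the narrow default
would need >10⁴. 100 epochs ≈ 1.9×10³ updates is roughly 2.6× that
requirement; by the same arithmetic the narrow default would need
proportionally more epochs (and compute) to reach the same regime.

## Known limitations

* The trainer implements one source/target batch pair per update with a
  single D-step and G/C-step from one forward pass; alternating multi-step
  D training is not implemented.
* Only the $f \otimes g$ multilinear conditioning is provided — no random
  projection or entropy weighting variants.
* Pseudo-labels are regenerated every epoch without curricula or ramped
  thresholds.
* The comparison backbone reported alongside the original method (a 1-D
  ResNet50) is out of scope; `cdan_mc` and `source_only` are the built-in
  ablations, and whether the three averaged experiments re-draw splits is
  unspecified in the source — here they re-seed training on fixed splits.
* CSV/TSV (plus JSON manifests) are the only interchange formats;
  vendor binary formats are out of scope.
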