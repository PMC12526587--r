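# cdanpl

Unsupervised domain adaptation for 1-D Raman spectra: a pseudo-label-based
conditional domain adversarial network (CDAN-PL) with the full serum-Raman
preprocessing stack, a two-domain synthetic spectrum generator, and
Grad-CAM interpretation — implemented in R with hand-written network
forward/backward passes (compiled attention kernels via Rcpp).

## The problem and who this is for

Raman spectra of serum can separate disease from healthy control, but
supervised classifiers need labeled cohorts that rarely exist for
autoimmune disease, and spectra acquired on a different spectrometer or for
a related disease follow a shifted distribution. `cdanpl` targets the
unsupervised setting: a labeled *source* cohort `D_s = {(x_s, y_s)}` and an
unlabeled *target* cohort `D_t = {x_t}` with `P_s != P_t`. It is intended
for chemometricians and methods researchers who want a tested,
reproducible implementation of conditional adversarial adaptation with
pseudo-label supervision on 1-D spectra.

## The method

Three components play a min-max game. A dual-branch feature extractor `G`
(self-attention encoder over spectral patches + multi-scale 1-D
convolutions, fused to one feature vector), a softmax classifier `C`, and a
conditional domain discriminator `D` that consumes the multilinear map
`phi(f, g) = f (x) g` of features and class probabilities:

- `D` descends the adversarial loss
  `L_adv = -E_s log(1 - D(phi(f_s, g_s))) - E_t log D(phi(f_t, g_t))`;
- `G`, `C` descend `L_cls + L_CE + lambda * (L_MC - L_adv)`
  (gradient reversal), where `L_MC` is a Fisher-style metric-constraint
  loss on pairwise feature distances (normalized by
  `T_m = (1/B) sum_{u != v} ||f_u - f_v||^2`) that preserves class
  separability during alignment;
- pseudo-labels for the target domain are regenerated each epoch by fusing
  the classifier's softmax output with KNN class frequencies in feature
  space (`w * neuron + (1 - w) * knn`), keeping only samples whose fused
  confidence exceeds `kappa`; the kept labels drive the cross-entropy term
  `L_CE` (and join the MC batch).

Training follows the published settings (RMSprop, Xavier initialization,
learning rate 1e-5, batch 32), with `source_only` (no adaptation) and
`cdan_mc` (no pseudo-labels) as built-in ablation modes. Preprocessing
implements iterative polynomial baseline correction (degree 3, 100
iterations, loss gradient 0.001), mean smoothing (window 9), per-spectrum
min-max normalization, 1:1 control splitting, stratified 7:3 train/test
splits, SMOTE balancing to 300 rows per class, and PCA harmonization onto
a shared 50-component basis when the two domains use different grids.

Because the clinical serum spectra behind the original study are not
distributable, the package ships a synthetic generator whose presets
emulate the study conditions (Gaussian serum bands with a disease
amplitude at designated peaks, cubic fluorescence baselines, gain, noise,
peak jitter, and per-peak response differences between acquisition
setups). See `vignette("cdanpl-methods")` for the model, parameter and
design-choice discussion.

## Worked example

```r
library(cdanpl)

# a complete synthetic transfer task: labeled source, unlabeled target,
# sealed target labels for evaluation only
pair <- generate_transfer_task("easy", seed = 1)
pair <- prepare_pair(pair, smote_count = 300, seed = 1)   # preprocess + SMOTE
pair
#> <domain_pair> source 600/32 train/test, target 600/42 train/test, 600 features

# train the full method at the published optimizer settings
net <- compact_net_config(ncol(pair$source_train$X))
cfg <- train_config(iterations = 100, iteration_unit = "epoch",
                    mode = "cdan_pl", seed = 1, net = net)
fit <- train(pair, cfg)
evaluate_model(fit$bundle, pair$target_test, pair$sealed$test)$accuracy
#> [1] 100

# against the unadapted baseline
cfg$mode <- "source_only"
fit0 <- train(pair, cfg)
evaluate_model(fit0$bundle, pair$target_test, pair$sealed$test)$accuracy
#> [1] 90.47619

# pseudo-label audit and spectral attribution
pls <- generate_pseudo_labels(fit$bundle, pair$source_train, pair$target_train)
pls
#> <pseudo_label_set> 600 samples, 578 kept (96.3%)
gradcam_spectrum(fit$bundle, pair$target_test, target_class = 1)
#> <attribution_map> 600 points, 6 key peak(s)
#>   757.9 cm^-1 (0.62)
#>   848.1 cm^-1 (0.56)
#>   998.3 cm^-1 (1.00)
#>   1308.8 cm^-1 (0.55)
#>   1439.1 cm^-1 (0.62)
#>   1649.4 cm^-1 (0.66)
```

The numbers read as follows: on the easy two-domain preset the
source-trained model drops to ~90% on the shifted target domain while
staying perfect on its own test set; adversarial alignment plus
confidence-filtered pseudo-labels recovers the target test set fully
(over three seeds the package reports 92.1% source-only vs 95.2% without
pseudo-labels vs 100% for the full method), and the surviving
pseudo-labels cover ~96% of the target training pool. The attribution
map's key peaks (contribution > 0.5) include the injected discriminative
bands near 991, 1317 and 1444 cm^-1 alongside the strongest background
serum bands.

`tsne_export(fit$bundle, pair)` writes the 2-D embedding of all features
with domain/class tags plus class-vs-domain silhouette diagnostics, and
`inst/cli/cdanpl.R` exposes the pipeline as
`Rscript cdanpl.R <synth|preprocess|train|eval|explain|tsne> config.yaml`.

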