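# grainclass

Grain-by-grain phenotyping and classification of commercial rice from
color images.

Rice is marketed as named classes (Koshihikari, Arborio, Basmati, black
rice, wild rice, …) that differ in kernel shape and pericarp color.
`grainclass` turns a photograph of kernels on a contrasting background
into per-grain measurements and class calls:

1. **Segmentation** — Otsu binarization on luminance with automatic
   polarity, morphological cleanup, and per-component distance-transform
   watershed to split touching kernels (`label_grains()`).
2. **Nine dimensionless morpho-colorimetric descriptors** per grain
   (`extract_features()`): box-counting fractal dimension FD, circularity
   Cir = 4πA/P², aspect ratio AR, extent Ext, batch-normalized
   area–perimeter index APIdx = [(A/P) − (A/P)min]/(A/P)max, CIELab L/a/b,
   and yellowness YI = 142.86·b/L. Dimensionless descriptors keep the
   pipeline independent of camera distance and resolution.
3. **Classification** — a 9-input, one-hidden-layer, 15-output feedforward
   network trained by Levenberg–Marquardt with Bayesian regularization
   (`grain_net()`): minimize β·E_D + α·E_W, re-estimating α, β each step
   from the effective number of parameters
   γ = N_w − 2α·tr(H⁻¹). No validation hold-out is needed; model selection
   is a neuron-trimming sweep over {10, 7, 5, 3} hidden units with
   under/over-fitting flags (`trim_neurons()`).
4. **Statistics** — per-descriptor one-way ANOVA with Tukey–Kramer compact
   letters, correlation-matrix PCA and Ward clustering of class means
   (`anova_tukey()`, `pca_features()`, `hcluster_classes()`).
5. **Deployment** — segment → extract → classify → annotated decision
   image with per-class accuracy report (`run_deploy()`).

Because image sets of this kind are proprietary, the package ships a
synthetic scene renderer with analytic ground truth
(`render_grain_scene()`, `sample_feature_table()`) and a packaged
catalogue of the 15 commercial classes' descriptor moments
(`read_class_specs()`); every pipeline stage is validated against that
truth. The methods vignette (`vignettes/grainclass-methods.Rmd`) explains
the model, the estimators, and what synthetic validation does and does
not show about real images.

## Worked example

```r
library(grainclass)
specs <- read_class_specs()                      # 15-class catalogue

# render a scene with known truth, segment it, extract descriptors
sc <- render_grain_scene(specs[c(1, 9, 14)], 5,  # KHO, BAS, BKR
                         image_size = c(480, 640), seed = 42)
lr <- label_grains(sc$image)
lr
#> labeled_regions: 15 grains on a dark background (480 x 640 px)
head(extract_features(sc$image, lr), 3)
#>   grain_id    FD   Cir    AR   Ext APIdx      L     a      b     YI
#> 1        1 1.534 0.648 3.105 0.530 0.115 55.625 1.505 -1.138 -2.923
#> 2        2 1.754 0.924 1.555 0.699 0.310 57.089 2.580 -2.683 -6.714
#> 3        3 1.549 0.643 3.102 0.448 0.234 59.653 1.780 -0.087 -0.209

# train the regularized network on feature-space samples at the
# catalogue moments and evaluate the 70/30 stages
tab <- sample_feature_table(specs, 100, seed = 49)
sp  <- split_dataset(tab, 0.7, seed = 42)
fit <- grain_net(class_id ~ ., sp$train, n_hidden = 10, seed = 42,
                 control = grain_net_control(max_epochs = 120))
fit
#> grain_net: 9-10-15 feedforward network (Bayesian regularization)
#>   265 weights; stop: max_epochs
#>   alpha 0.0001962  beta 81.73  gamma 250.4 (effective parameters)
evaluate_model(fit, sp$train, "training")
#> training   n = 1050   accuracy 94.6%  error 5.4%  MSE 0.0060
evaluate_model(fit, sp$test, "testing")
#> testing    n = 450    accuracy 80.9%  error 19.1%  MSE 0.0234
```

Row 1 is a slender translucent grain (AR 3.1, high L, negative b —
Basmati-like); row 2 a bold short grain (AR 1.6, Cir 0.92); grain 4 in the
full table is a black-rice kernel (L 30.9, a 15.1, YI 23.8). The fitted
network reports its Bayesian-regularization state: γ ≈ 250 of 265 weights
are effectively in use, and training/testing MSE (0.006 vs 0.023) show the
usual mild train/test gap at these class separations.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/grainclass.R` with subcommands `simulate`, `extract`,
`train`, `trim`, `deploy`, `stats`.

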