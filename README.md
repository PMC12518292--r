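# spectracae

Disentangling genotype and environment signals from plot-level
multispectral satellite imagery of replicated field trials — and using the
disentangled features to predict grain yield.

## The problem and who it is for

Breeding trials plant the same maize hybrids in replicated plots across
several locations. A plot's canopy reflectance mixes the hybrid's genetics
(G), the location's shared conditions (macro-environment, E), and
plot-local micro-environment differences between replicates. Yield depends
on G, E, and their interaction (G×E), which reorders hybrids across
locations; features that separate these factors predict yield and rank
hybrids better than features that blend them. This package is for
quantitative breeders and remote-sensing researchers who have plot-level
multi-band imagery (nominally 11 × 22 px × 6 bands at 30 cm, 12-bit) plus
plot metadata and yields.

## The model

A **compositional autoencoder** (CAE). Each preprocessed plot image is
flattened (length 1452) and encoded by an MLP
`1452 → 2200 → 2000 → 1000 → zg+ze+zp` (SELU hidden layers). The N = E·R
encodings of one genotype's group of plots are concatenated and passed
through a single affine **fusion** layer

    N(zg + ze + zp)  →  zg + E·ze + N·zp

whose output is partitioned into one genotype block `Zg` (shared by the
whole group), one macro-environment block `Ze_l` per location, and one
micro block `Zp_i` per plot. Each plot's latent `[Zg | Ze_l | Zp_i]` is
decoded by `zg+ze+zp → 2024 → 3000 → 2200 → 1452` (sigmoid output).
Training minimizes

    L = MSE(x, x̂) + λ · Σ_{i<j} |r_ij|

where `r_ij` is the Pearson correlation between latent dimensions i and j
across the batch — the correlation penalty drives the blocks toward
independence. A vanilla autoencoder with the same stacks and latent width
is the baseline, and 13 vegetation indices (NDVI, EVI, SAVI, NDRE, GLI,
NGRDI, VARI, VEG, RGBVI, ExG, ExR, GNDVI, RDVI) form a feature baseline.

Evaluation follows three protocols: PCA-3 + silhouette scores for
macro-/micro-environment separation against a raw-pixel baseline;
genotype-grouped 5-fold cross-validated yield prediction with gradient
boosted trees (R², RMSE in t/ha); leave-one-location-out top-25%/top-50%
rank overlap; and unseen-environment RMSE. A seeded synthetic generator
produces 12-bit multispectral trials with known G/E/micro factors and
G+E+G×E yields so every stage is testable without downloads.

## Worked example

```r
library(spectracae)

ds  <- simulate_dataset(sim_config(n_genotypes = 60, seed = 101))
pre <- preprocess(ds)                      # clip 3 sd, min-max per channel

raw_baseline_silhouette(pre)$score
#> [1] 0.2756933

fit <- train_cae(pre, latent_config(6, 6, 1),
                 training_config(epochs = 60, seed = 42))
lat <- extract_latents(fit, pre)
macro_env_silhouette(lat)$score
#> [1] 0.9720002
```

Raw pixels separate the five locations weakly (silhouette 0.28); the
trained macro-environment block separates them almost perfectly (0.97).
The disentangled features then feed the yield protocols:

```r
yt <- yield_table(ds)
cv <- experiment1(list(CAE = dplyr::select(lat, plot_id, dplyr::matches("^z[gep]_"))),
                  yt, k = 5, seed = 7)
glance(cv)
#> # A tibble: 1 × 6
#>   feature_set r2_mean  r2_sd rmse_mean rmse_sd folds
#>   <chr>         <dbl>  <dbl>     <dbl>   <dbl> <int>
#> 1 CAE           0.740 0.0461      1.14  0.0962     5
```

Mean out-of-sample R² ≈ 0.74 for unseen genotypes; RMSE ≈ 1.1 t/ha.
`run_pipeline(pipeline_config(...), out_dir)` chains every stage and
writes latents, loss histories, and JSON/CSV reports;
`inst/cli/spectracae.R` exposes the same stages as shell subcommands.

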