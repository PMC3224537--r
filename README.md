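# mammicad

Computer-aided diagnosis of mammogram regions of interest (ROIs) by
**efficient coding**: classify a grayscale tissue patch as *mass* vs
*non-mass* (and, secondarily, a mass as *benign* vs *malignant*) by
projecting it onto learned basis functions and applying a Fisher linear
discriminant.

The package is aimed at researchers in medical image analysis who want a
small, fully reproducible reference implementation of this classical CAD
pipeline — including a synthetic ROI generator, so every stage can be
exercised and benchmarked without access to clinical data.

## The pipeline

Every ROI is histogram-equalized, resized to 32 × 32 by bilinear
interpolation, and row-concatenated into a vector **x** ∈ ℝ¹⁰²⁴. Three
families of basis functions can represent it:

1. **PCA eigenimages.** The covariance Σ of the training vectors is
   eigendecomposed; samples are projected onto the top-*k* eigenvectors
   **V** (variance order): **y** = **Vᵀ**(**x** − μ).
2. **Independent components (efficient coding).** The generative model
   **x** = **As** with statistically independent coefficients **s** is fitted
   by a from-scratch fixed-point FastICA: training vectors are whitened, and
   each unit vector **wᵢ** is updated by
   **w** ← E[**z** g(**wᵀz**)] − E[g′(**wᵀz**)] **w** with symmetric
   re-orthonormalization, maximizing the negentropy approximation
   J(**wᵀz**) ≈ (E[G(**wᵀz**)] − E[G(ν)])², G = log cosh.
3. **Gabor wavelets.** A bank of M × k band-pass filters (Gaussian envelope ×
   sinusoidal carrier, rotated by θ = nπ/k and scaled geometrically;
   default 10 scales × 10 orientations = 100 filters), each rendered on the
   32 × 32 grid, DC-corrected and unit-normalized.

ICA and Gabor bases are ranked by a **greedy pursuit-style wrapper**: the
subspace Ψ grows one basis at a time, always adding the candidate whose
projection maximizes training-set classification accuracy. Classification is
**Fisher LDA**: β is the leading eigenvector of W⁻¹B (between- over
within-group scatter), with the midpoint of the projected class means as the
decision threshold. Configurations are scored by **stratified 10-fold
cross-validation** with accuracy, sensitivity TP/(TP+FN) and specificity
TN/(TN+FP).

## Worked example

```r
library(mammicad)

d <- generate_dataset(c(mass = 200, `non-mass` = 200),
                      synth_params(seed = 11, blob_contrast = 1.5))
d
#> <roi_dataset> 400 samples x 1024 pixels (32x32)
#>   labels: mass=200, non-mass=200

report <- crossvalidate(d, extractor_ica(), n_components = 20, k = 10, seed = 1)
report
#> <cad_eval> ica, 20 components, 10-fold CV (seed 1)
#>   accuracy 0.9825 | sensitivity 1.0000 | specificity 0.9650

glance(report)
#> # A tibble: 1 × 6
#>   method n_components     k accuracy sensitivity specificity
#>   <chr>         <dbl> <dbl>    <dbl>       <dbl>       <dbl>
#> 1 ica              20    10    0.982           1       0.965

tidy(report)   # per-fold confusion counts and metrics
#> # A tibble: 10 × 8
#>    fold    TP    TN    FP    FN accuracy sensitivity specificity
#>   <int> <int> <int> <int> <int>    <dbl>       <dbl>       <dbl>
#> 1     1    20    18     2     0     0.95           1         0.9
#> 2     2    20    18     2     0     0.95           1         0.9
#> 3     3    20    20     0     0     1              1         1
#> # ...
```

400 synthetic ROIs (half containing a bright blob-shaped "mass" over
correlated-noise texture, half texture only) are generated, preprocessed, and
cross-validated with the efficient-coding extractor: per held-out fold the
training portion is whitened, a FastICA basis is fitted, the 20 most
discriminative components are greedily selected, and a Fisher discriminant
classifies the held-out samples. At this separability (`blob_contrast = 1.5`)
the pipeline classifies 98.25% of patches correctly, catching every mass
(sensitivity 1.0) with 3.5% false alarms (specificity 0.965).

Component sweeps and plots follow the same grammar:

```r
sw <- component_sweep(d, extractor_pca(), 1:40, k = 10, seed = 1)
autoplot(sw)                      # metric curves vs component count
autoplot(gabor_bank(), n = 50)    # filter montage
```

A thin CLI over the same functions lives at
`system.file("cli", "mammicad.R", package = "mammicad")`:

```sh
Rscript mammicad.R --method ica --components 41 --folds 10 --seed 1 \
    --synthetic "mass=200,non-mass=200" --out results/
```

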