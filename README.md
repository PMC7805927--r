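# pointtex

Do you need a super-resolved microscope to tell two cell populations
apart, or is a cheap sub-resolved one enough? `pointtex` is an R package
for answering that question by simulation. It generates single-cell
fluorescence images whose marker fields differ in **density** or in
**spatial clustering**, blurs them with a tunable Gaussian point spread
function (PSF), and compares two kinds of feature spaces under one
identical classification protocol:

* **pointillist** — localize each marker, then describe the point
  pattern: maximum-likelihood parameters of the inter-marker, centroid
  and nearest-neighbor distance distributions (Rayleigh σ_R, exponential
  λ_E, GEV ξ_G, σ_G, μ_G, selected by BIC = −2 ln L + p ln n), and five
  descriptors of Besag's normalized Ripley K-function
  K̂(r, n) = √(K(r, n)/π) − r, where

      K(r, n) = |Ω| / (n(n−1)) · Σ_{x≠y} 1{|x−y| ≤ r} · f(x, y)

  with Ripley's isotropic edge correction f for the rectangular window;
* **textural** — describe the blurred image directly: radial-profile
  features of the Wiener–Khinchin autocorrelation G = F⁻¹[|F[i]|²],
  Haralick coefficients of four-orientation gray-level co-occurrence
  matrices on 72×72 windows, and 256-bin local-binary-pattern histograms
  reduced to 5 dimensions by PCA.

Every feature space ends in exactly 5 features and is scored by a linear
SVM with stratified 10-fold cross-validation (standardization and PCA
fitted per training fold), swept across PSF widths parameterized by the
resolution ratio **k = d_min / σ_psf** — super-resolved for k > 1,
sub-resolved for k < 1. It is aimed at microscopists and image-analysis
researchers who want to choose a PSF (or a microscope) for a detection
task before building the instrument, and at anyone who needs
well-tested implementations of these spatial and textural statistics
with their edge cases pinned down by oracle tests.

## Worked example

Simulate one "healthy" cell (class C1: 3,000 markers, i.i.d. normal
positions, density 0.30 markers/px), render it at both ends of the
resolution sweep, and look at it through both lenses:

```r
library(pointtex)

field <- with_seed(7, sample_gaussian_field(class_params("C1")))
img_super <- render_image(field, sigma_psf = 0.51, crop = 216)  # k = 2
img_sub   <- render_image(field, sigma_psf = 2.04, crop = 216)  # k = 0.5

det <- detect_markers(img_super, sigma_psf = 0.51)
evaluate_detection(det, img_super$truth)
#> detection_score: 1921/2439 matched (rate 0.788, tol 1.00 px)

round(distance_features(det$detected), 4)
#>  sigma_R lambda_E     xi_G  sigma_G     mu_G
#>  82.3309   0.0131  -0.0274   0.8180   2.5028

round(ripley_features(det$detected), 4)
#>      max_Khat  max_grad_pre min_grad_post      r_at_max      spearman
#>        1.1738        0.5535       -0.0088       53.4600        0.9951
```

In the super-resolved image the detector recovers 78.8% of the markers,
and the Rayleigh scale of their pairwise distances (σ_R ≈ 82 px) reflects
the ~100 px spread of the cloud. The K̂ curve stays barely above zero —
a near-Poisson pattern, as it should be for C1. The sub-resolved image is
pure texture; its autocorrelation profile never falls to half maximum
(the FWHM feature saturates, with a warning), which is itself a usable
regime signature.

Running the comparison proper — 30 images per class of C1 against the
clustered class C3, two PSF widths, two of the five methods:

```r
feats <- simulate_feature_table(
  n_per_class = 30, sigma_psf = c(0.51, 2.04),
  classes = c("C1", "C3"), methods = c("autocorrelation", "ripley"),
  seed = 7)
report <- run_sweep(feats, tasks = list(organization = c("C1", "C3")),
                    folds = 5, seed = 7)
report
#>           task          method sigma_psf   k accuracy accuracy_sd  n folds
#> 1 organization autocorrelation      0.51 2.0    0.983      0.0373 60     5
#> 2 organization autocorrelation      2.04 0.5    1.000      0.0000 60     5
#> 3 organization          ripley      0.51 2.0    0.967      0.0745 60     5
#> 4 organization          ripley      2.04 0.5    0.583      0.0833 60     5
```

Already at this toy size the regime structure is visible: the textural
method is near-perfect in **both** regimes, while the pointillist
K-function method collapses toward chance (0.58) exactly where the
markers stop being localizable. `plot_sweep(report)` draws the
accuracy-vs-k curves; `default_sigma_grid()` gives the full 11-point
sweep, and `generate_dataset()` writes full-scale image datasets (TIFF +
ground-truth CSV + JSON manifest) to disk. A command-line wrapper with
`simulate` / `detect` / `features` / `sweep` / `plot` subcommands lives
at `inst/cli/pointtex.R`.

## Scope notes

The simulator deliberately omits camera noise, PSF spatial variation and
fluorophore photophysics, and the spot detector is a simple
Laplacian-of-Gaussian surrogate rather than a published localization
algorithm — see the methods vignette
(`vignettes/pointillist-vs-textural.Rmd`) for the full account of the
model, the parameter defaults and the design decisions. Real
single-channel TIFF/PNG images can be pushed through the identical
feature and classification path via `ingest_real_images()`.
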