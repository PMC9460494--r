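# kapurseg

Optimization-driven multilevel thresholding segmentation for grayscale
medical images, with a noise-robustness benchmarking protocol and
cartilage morphology feature extraction.

## The problem

Multiregional segmentation of MR images (the motivating application is
knee articular cartilage) is commonly posed as multilevel histogram
thresholding: choose thresholds `T1 < T2 < ... < Tn` partitioning the
8-bit intensity axis into `L = n + 1` regions. Good thresholds are the
ones that maximize a separability criterion over the image histogram;
finding them for more than one or two thresholds is a combinatorial
optimization problem, which is where population metaheuristics come in.
Real MR data are noisy, so a segmentation method is only useful if its
label maps stay stable as noise grows — the package ships the full
evaluation protocol for measuring exactly that, on synthetic phantoms
with known ground truth, so no clinical data are needed to exercise any
part of the pipeline.

## The model

The fitness all the optimizers maximize is the **Kapur entropy** of the
thresholded histogram: with `p_j` the probability of intensity `j` and
region `l` spanning `[T_{l-1}, T_l)`,

    H_l = - sum_{j in region l} (p_j / w_l) ln(p_j / w_l),
    w_l = sum_{j in region l} p_j,
    fit(T1..Tn) = sum_l H_l  ->  max

Five metaheuristics drive the search — artificial bee colony (ABC),
particle swarm (PSO), fuzzy adaptive-inertia PSO (FPSO), Darwinian
multi-swarm PSO (DPSO) and a genetic algorithm (GA) — alongside two
conventional baselines (equal-area multi-Otsu, 1-D K-means). The
soft-thresholding variant (`abc_fuzzy`) optimizes the vertices of a
pseudo trapezoid-shaped (PTS) fuzzy membership partition of the
intensity axis and labels pixels by maximal membership; its fitness is
the Kapur entropy of the crisp-equivalent midpoint partition, so all
methods are scored by one unified objective.

Robustness is measured by re-segmenting noise-corrupted copies of an
image (Gaussian, speckle, salt-and-pepper and Rician generators, each
with a 20-level intensity grid) and comparing each noisy label map
against the same method's noise-free segmentation (its *gold standard*)
with global SSIM, Pearson correlation, SNR (dB) and MSE, followed by
one-sided Wilcoxon rank-sum tests against the baselines.

## Worked example

```r
library(kapurseg)

ph  <- generate_phantom(256, 256, n_regions = 4, texture_sd = 8, seed = 42)
fit <- mlseg(ph$image, method = "abc_fuzzy", regions = 4,
             control = optimizer_control(iterations = 100, population = 50,
                                         seed = 1))
print(fit)
#> Multilevel segmentation (abc_fuzzy), 4 regions, 256x256 px
#>   thresholds: 31, 108, 214
#>   PTS vertices: 17, 44, 171, 255
#>   Kapur entropy: 14.1791 nats
```

The fitted object reports the PTS vertex sequence found by the bee
colony, the crisp-equivalent thresholds, and the Kapur entropy of the
partition (larger = more uniform within-region intensity spread).
Scoring a noisy re-segmentation against this fit as gold standard:

```r
noisy <- add_rician_noise(ph$image, sigma2 = 0.1, seed = 2)
refit <- mlseg(noisy, method = "abc_fuzzy", regions = 4,
               control = optimizer_control(seed = 1))
evaluate_against_gold(fitted(fit), fitted(refit))[, c("ssim", "mse", "corr")]
#>        ssim      mse      corr
#> 1 0.3041872 2.313538 0.3695867
```

Heavy Rician noise (variance 0.1) drags SSIM down to 0.30 — the kind of
degradation the sweep protocol quantifies level by level. Cartilage
morphology of the ribbon region (region 3, largest lobe):

```r
mask <- extract_region_mask(fitted(fit), 3, top_k = 1)
region_features(mask)
#> $area_px      704
#> $perimeter_px 616
#> $skeleton_px  108
```

against the phantom's analytic truth (area 704, perimeter band 616,
skeleton 106): area and perimeter exact, skeleton within 2%.

For the full protocol, see `run_robustness_sweep()`,
`aggregate_sweep()` and `significance_matrix()`; the methods vignette
(`vignettes/multilevel-threshold-segmentation.Rmd`) documents the model
and every tunable parameter.

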