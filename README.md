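# specphasor

Spectral phasor analysis of hyperspectral (lambda-stack) autofluorescence
images, for label-free characterization of tissue — in particular the
discrimination of melanocytic lesions (benign nevi vs. melanoma) from the
endogenous fluorescence of collagen, elastin, NADH, FAD and melanin,
without any staining.

**Who it is for:** imaging scientists and computational pathologists with
multi-channel spectral stacks from a confocal microscope (e.g. a
423–723 nm window in 30 × 10 nm channels) who want a reproducible,
scriptable phasor pipeline: transform, denoise, segment, unmix, and compare
diagnosis groups statistically.

## The method

Each pixel's emission spectrum $I(\lambda)$ is reduced to its normalized
first-harmonic Fourier coefficients

$$
G = \frac{\int I\cos\big(2\pi\tfrac{\lambda-\lambda_{\min}}
{\lambda_{\max}-\lambda_{\min}}\big)d\lambda}{\int I\,d\lambda},\qquad
S = \frac{\int I\sin\big(2\pi\tfrac{\lambda-\lambda_{\min}}
{\lambda_{\max}-\lambda_{\min}}\big)d\lambda}{\int I\,d\lambda},
$$

a point in the unit disc. Its polar form — phase
$\theta = \operatorname{atan2}(S,G)$ (spectral centre of mass; at
harmonic 1, $\lambda = \lambda_{\min} + (\lambda_{\max}-\lambda_{\min})
\theta/360$, e.g. 90° ↔ 498 nm on the default axis) and modulation
$\rho = \sqrt{G^2+S^2}$ (spectral width) — summarizes spectral shape
independent of brightness. Mixtures of emitters fall on the segment (or in
the triangle) spanned by the pure components' phasors, giving geometric
unmixing; regions selected in phasor space map back to image pixels
(reciprocity), giving model-free segmentation. Samples are summarized by
the centre of mass of their lesion-ROI phase and modulation histograms and
compared across groups with pooled t-tests and covariance confidence
ellipses.

See the methods vignette (`vignettes/spectral-phasor-methods.Rmd`) for
discretization and calibration choices, parameter defaults, and what the
synthetic phantoms do and do not emulate.

## Worked example

A fully synthetic 5 + 5 cohort (nevus-like lesions weighted toward
NADH/elastin/collagen, melanoma-like toward FAD/melanin), transformed and
compared end to end:

```r
library(specphasor)

ax <- spectral_axis(423, 723, 30)
phase_to_wavelength(90, ax)
#> [1] 498

co  <- make_cohort(seed = 42)                       # 10 seeded phantoms
cmp <- cohort_compare(cohort_fields(co, intensity_threshold = 250))
cmp
#> Cohort comparison of phase/modulation centres of mass
#>   nevus      (n = 5): modulation 0.71 +/- 0.00, phase 79 +/- 1 deg
#>   melanoma   (n = 5): modulation 0.39 +/- 0.01, phase 177 +/- 2 deg
#>   t-test (pooled): modulation p = 1.3e-13, phase p = 3.3e-14 (alpha = 0.01)
#>   ellipse levels k = 1,2,3: 2-D coverage 39.3%/86.5%/98.9% (1-D sigma labels 68.5%/95.5%/99.7%)
```

The per-group lines are mean ± SD of the per-sample centres of mass: the
melanoma-like group sits at larger phase (red-shifted emission) and lower
modulation (broader spectra), and both variables separate the groups far
below the α = 0.01 threshold. `plot(cmp)` draws the modulation-vs-phase
scatter with the three confidence ellipses per group.

Single-image work uses the same building blocks:

```r
ph <- make_tissue_phantom(phantom_config(seed = 7))   # or read_stack(...)
f  <- phasor_transform(ph$stack)
f
#> <phasor_field> 96 x 96 pixels, harmonic 1, 7396/9216 valid (threshold 30)

component_centroid(phasor_of_roi(f, ph$labels == "lesion"), 1)
#>           G      S
#> [1,] 0.1294 0.7017                  # lesion cluster centroid

unmix_two(c(0.2, 0.6), c(0.8, 0.4), c(-0.2, 0.7))
#> $fraction_a  0.394   $fraction_b  0.606   $residual  0.0192
```

`run_pipeline(run_config(...))` (or the thin wrapper in
`inst/scripts/phasor-pipeline.R`) orchestrates manifest-driven runs —
read stacks and expert ROI masks, stitch, transform, median-filter,
compare — and writes a provenance-complete bundle (`config.json`,
`per_sample.csv`, `group_stats.json`, `comparison.png`).

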