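---
title: "Spectral phasor analysis of label-free tissue autofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phasor analysis of label-free tissue autofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specphasor)
```

## The model

A hyperspectral (lambda-stack) fluorescence image records, at every pixel,
an emission spectrum $I(\lambda)$ over a detection window
$[\lambda_{\min}, \lambda_{\max}]$. The spectral phasor transform reduces
each spectrum to its normalized first-harmonic Fourier coefficients

$$
G = \frac{\int I(\lambda)\cos\!\big(2\pi n \tfrac{\lambda -
\lambda_{\min}}{\lambda_{\max}-\lambda_{\min}}\big)\,d\lambda}
{\int I(\lambda)\,d\lambda},
\qquad
S = \frac{\int I(\lambda)\sin\!\big(2\pi n \tfrac{\lambda -
\lambda_{\min}}{\lambda_{\max}-\lambda_{\min}}\big)\,d\lambda}
{\int I(\lambda)\,d\lambda},
$$

with harmonic $n = 1$ throughout this package (higher harmonics are
accepted by `phasor_transform()` but not used by the downstream analysis).
In polar form, phase $\theta = \operatorname{atan2}(S, G)$ tracks the
spectral centre of mass (redder emission, larger phase) and modulation
$\rho = \sqrt{G^2 + S^2}$ tracks spectral width (narrower emission,
$\rho$ closer to 1; a flat spectrum sits at the origin). Because both
coefficients are normalized by total intensity, the phasor encodes spectral
*shape* only — two spectra differing by a positive scale factor map to the
same point, which is what makes cursor-based segmentation robust to
brightness variation.

Three Fourier-inherited properties carry the analysis:

* **uniqueness** — every spectrum has one $(G, S)$, so similar spectra
  cluster in phasor space;
* **linear combination** — a mixture of emitters lands at the
  intensity-weighted barycentre of the pure emitters' phasors, so
  `unmix_two()`/`unmix_three()` can read off component fractions
  geometrically;
* **reciprocity** — a region selected in phasor space (`select_by_cursor()`)
  highlights pixels in image space, and an image ROI yields a secondary
  phasor (`phasor_of_roi()`).

The fractions returned by the unmixing functions are *intensity* (emitted
photon) fractions. Converting them to molar fractions would require the
relative brightness of each species, which label-free tissue data does not
provide.

## Discretization and calibration

The integrals are evaluated as rectangle-rule sums over channel centres.
Centres follow the mid-bin convention,
$\lambda_k = \lambda_{\min} + (k - \tfrac12)\Delta$: on the default
423–723 nm, 30-channel axis they run 428, 438, …, 718 nm. Mid-bin centres
were chosen because (a) the sampled first-harmonic cosine and sine then sum
to zero exactly, so a spectrally flat spectrum maps to the origin rather
than acquiring a discretization artifact, and (b) the phase↔wavelength
calibration $\lambda = \lambda_{\min} + (\lambda_{\max} -
\lambda_{\min})\,\theta/360$ then reproduces the conventional anchor
points, e.g. 90° ↔ 498 nm (a channel centre) and 180° ↔ 573 nm on this
axis. The continuous calibration is identical under either convention; the
test suite checks the discrete transform against a dense-grid quadrature
reference and finds agreement at the $10^{-5}$ level for emission bands at
least two channels wide, comfortably inside the $10^{-3}$ bound the
analysis assumes.

A note on polar definitions: one occasionally sees modulation written as
$S/G$ and phase as $\arctan(G/S)$. Those forms are inconsistent with
modulation being bounded by 1 and with the phase values quoted for
calibrated wavelengths; this package uses the standard polar conversion
($\rho = \sqrt{G^2+S^2}$, $\theta = \operatorname{atan2}(S, G)$ wrapped to
$[0, 360)$), which reproduces both.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| spectral axis | 423–723 nm, 30 channels | nm | common single-photon autofluorescence window (405 nm excitation), 10 nm steps |
| harmonic | 1 | – | one-to-one phase/wavelength map; higher harmonics wrap |
| intensity threshold | 3 × modal total count | counts | masks glass/background pixels; the modal total of a slide with dark regions estimates background. Pass an explicit threshold for images without dark background |
| median filter | 3 × 3, 1 pass | px | tightens phasor clusters without mixing spectra; a constant region is provably unchanged |
| pseudocolor range | 45–180° | degrees | phase span of tissue autofluorescence on the default axis (≈460–573 nm) |
| histogram bins | 128 per axis | – | resolves clusters at typical pixel counts |
| k-means | seed 0, 10 restarts | – | reproducible centroids; RNG state is restored after the call |
| significance | α = 0.01 | – | conservative threshold for the two group t-tests |

Pixels with $G = S = 0$ (flat spectrum) have undefined phase and are
flagged invalid rather than silently assigned 0; they are excluded from
every downstream statistic, as are pixels below the intensity threshold.
Degenerate inputs follow explicit conventions: a zero-pooled-variance
t-test returns $p = 1$ for equal means and $p = 0$ (with a message) for
unequal means; near-collinear point clouds get a floored minor ellipse axis
and a warning; cursor membership is boundary-inclusive (ties break toward
selection).

## Group statistics

Per sample, the per-pixel phase and modulation over the lesion ROI are
reduced to centres of mass, $\mathrm{CM} = \sum f(x)\,x / \sum f(x)$, with
$f(x)$ read as the pixel-count distribution — i.e. an unweighted mean over
pixels (intensity weighting is available behind
`weight_by_intensity = TRUE`, but brightness is not a reliable quantity in
label-free slides, so it is off by default). Groups are compared with the
pooled-variance two-sided t-test, and each group's
(phase CM, modulation CM) scatter is drawn with $k = 1, 2, 3$ covariance
ellipses whose membership test is Mahalanobis distance $\le k$, so the
ellipses follow the cloud's orientation.

Two coverage conventions coexist for such ellipses: the per-axis 1-D labels
(68.5 / 95.5 / 99.7% for $k = 1, 2, 3$) and the actual 2-D Gaussian mass
inside the $k$-sigma ellipse, $1 - e^{-k^2/2}$ (39.3 / 86.5 / 98.9%). The
report prints both (`ellipse_coverage()`), and the test suite verifies the
2-D value by direct simulation.

## What the synthetic phantoms emulate — and what they do not

`make_tissue_phantom()` builds lambda stacks whose pixels are Poisson
realizations of region-wise expected spectra: linear mixtures of
configurable (skew-)Gaussian emission bands for collagen I–IV, elastin,
NADH, FAD and melanin, arranged in a tissue-like layout (dark background
frame, epidermis band, dermis, melanocytic-nest disc), scaled to a photon
budget (default 1000 counts/pixel), Poisson-noised and integer-quantized.
`make_cohort()` draws two groups of such phantoms whose lesion mixtures
follow group profiles — the nevus-like profile dominated by NADH, elastin
and collagen, the melanoma-like profile by FAD and melanin, i.e. a
red-shifted nest — with multiplicative lognormal weight jitter
(σ = 0.05) as between-sample variability. The default component peak
positions are literature-plausible stand-ins that preserve the blue
(structural proteins, NADH) → red (FAD, melanin) ordering; they are
configuration entries, not measured reference spectra, and no claim is made
that they reproduce any particular instrument's component positions.

Everything is seed-deterministic, and each phantom carries its ground truth
(label image, noiseless expected stack, exact per-region phasors and
per-sample lesion CMs), so pipeline correctness is established as
*parameter recovery*: cursors must re-segment the ground-truth labels,
centroids and unmixed fractions must match the generating mixture, and the
cohort comparison must recover the injected group separation while holding
its type-I error rate at nominal level under identical profiles.

The phantoms deliberately omit optics and histology: no point-spread
function, scattering, depth attenuation, fixation effects, spatial texture
within regions, or detector gain/offset. Passing tests therefore
demonstrate that the *computational* pipeline is correct and calibrated
under its stated noise model — not that real nevus/melanoma slides will
separate with any particular effect size. On real data the lesion ROI comes
from an expert annotation (`read_roi_mask()`) rather than from generator
labels, and red-shifted components beyond the configured library (e.g.
melanin variants) may place pixels away from every fingerprint.

## Problem sizes and numerical tolerances

The shipped tests run on deliberately small instances chosen as adequate
for their statistical purpose: 20–96 px phantoms, 5 + 5 cohorts of
48 px samples at 1000 counts/pixel, 200 replicate cohorts for the
type-I calibration, $10^5$ points for ellipse coverage, and $10^4$ random
spectra for the unit-disc property. Key tolerances: unit-disc containment
$10^{-9}$ (floating-point slack on an exact convexity property);
discrete-vs-quadrature agreement $10^{-3}$; noiseless fraction recovery
$10^{-6}$; Poisson fraction recovery 0.02 mean absolute error at 1000
counts; phase round-trip $10^{-9}$ degrees.

## Known limitations

* Stitching is geometric (grid plus overlap averaging); there is no
  registration-based alignment, so stage-coordinate errors larger than a
  pixel would seam the mosaic.
* The median filter is an $O(k^2)$ NA-aware implementation; on
  whole-slide mosaics a single 3 × 3 pass over a 1024² tile takes a few
  seconds, which is acceptable for batch use but not interactive.
* Wedge cursors do not wrap across 0°; a selection spanning the origin
  needs a polygon cursor.
* Unmixing assumes the components are exactly the supplied fingerprints;
  residual distance is reported but no model-selection is attempted.
* Phase statistics are computed on the $[0, 360)$ representative; cohorts
  whose phase distributions straddle 0° would need circular statistics,
  which the autofluorescence window (≈45–180°) does not require.
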