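---
title: "Phasor FLIM denoising and segmentation: methods"
author: "phasorFLIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor FLIM denoising and segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorFLIM)
```

## Scope

phasorFLIM implements a complete frequency-domain fluorescence lifetime
imaging (FD-FLIM) phasor workflow on synthetic data: simulation of
four-phase homodyne measurements with a realistic mixed Poisson–Gaussian
detector noise model, extraction of the uncalibrated real/imaginary (G, S)
measurement planes, image denoising of those planes (iterative median
filtering or a small residual CNN), per-pixel lifetime and phasor
computation, K-means segmentation of the phasor cloud, and quantitative
evaluation with PSNR/SSIM on 8-bit normalized lifetime images. This
vignette records the mathematical model and the design decisions; the
README shows a worked example.

## Measurement model

A fluorophore with mono-exponential lifetime $\tau$ excited by light
modulated at $f_{mod}$ (default 80 MHz) responds with modulation degree
and phase

$$ m = \frac{1}{\sqrt{1 + (\omega\tau)^2}}, \qquad
   \varphi = \arctan(\omega\tau), \qquad \omega = 2\pi f_{mod}. $$

`simulateFdPhases()` produces the four homodyne mixer outputs at phases
$\theta \in \{0, \tfrac{\pi}{2}, \pi, \tfrac{3\pi}{2}\}$:

$$ V_{IF}(\theta) = V_{dc} + A\, m \sin(\theta + \varphi), $$

summing component signals for bi-exponential pixels weighted by their
fractional amplitudes. `computeGS()` forms the complementary-phase
differences

$$ S = V_{IF}(0) - V_{IF}(\pi), \qquad
   G = V_{IF}(\tfrac{\pi}{2}) - V_{IF}(\tfrac{3\pi}{2}), $$

so that $S/G = \tan\varphi = \omega\tau$ and `lifetimeFromGS()` recovers

$$ \tau = \frac{S}{\omega\, G} $$

per pixel, independent of the unknown amplitude scale $2Am$ that both
differences share. On noiseless input this inversion is exact to floating
point (the test suite requires $10^{-9}$ relative error). A sign
convention worth recording: with the $\sin(\theta + \varphi)$ mixer
convention above, the $0$-vs-$\pi$ difference is the *sine* (S) channel
and the quadrature difference is the *cosine* (G) channel; this is the
assignment under which $\tau = S/(\omega G)$ holds with both planes
positive for physical lifetimes.

## Phasor coordinates

The phasor of a decay $I(t)$ at angular frequency $\omega$ is

$$ g = \frac{\int_0^\infty I(t)\cos(\omega t)\,dt}{\int_0^\infty I(t)\,dt},
   \qquad
   s = \frac{\int_0^\infty I(t)\sin(\omega t)\,dt}{\int_0^\infty I(t)\,dt}. $$

For a mono-exponential decay these evaluate in closed form
(`monoExpPhasor()`):

$$ g = \frac{1}{1 + (\omega\tau)^2}, \qquad
   s = \frac{\omega\tau}{1 + (\omega\tau)^2}, $$

which traces the *universal semicircle*
$s^2 + (g - \tfrac12)^2 = \tfrac14$ as $\tau$ runs from $0$ (point
$(1,0)$) to $\infty$ (origin). Mixtures lie on chords between their
component phasors; both properties are verified by the tests.

`phasorTD()` evaluates the integrals for TCSPC histograms with the
rectangle rule at bin centres — error $O(\Delta t^2)$, which at the 1 ps
test resolution leaves deviations near $10^{-8}$, far below the $10^{-4}$
tolerance; no higher-order quadrature is warranted.

### Placement of FD measurements on the phasor plot

The homodyne $G$ and $S$ planes carry an unknown common scale
$2Am$, so $\sqrt{G^2+S^2}$ is not the modulation degree $m$ — only the
phase $\varphi = \operatorname{atan2}(S, G)$ is directly meaningful.
`phasorFD()` therefore supports two modes:

* **Uncalibrated (default):** phase-only projection $m = \cos\varphi$,
  which places every mono-exponential pixel *exactly* on the universal
  semicircle while preserving the phase (and hence
  $\tau = \tan(\varphi)/\omega$) bit-for-bit. This is the normalization
  under which noiseless simulated pixels land on the closed-form phasor.
* **Calibrated:** given a reference measurement of known lifetime
  $\tau_{ref}$, a single complex correction factor maps the reference's
  mean $(G, S)$ onto `monoExpPhasor(tau_ref)` and is applied to every
  pixel — the standard instrument-calibration practice for absolute
  placement. Noise can push pixels left of the semicircle ($G < 0$);
  those entries are retained and flagged rather than dropped.

## Noise model

`addMpgNoise()` corrupts each phase sample $v$ independently as

$$ v \mapsto \text{gain} \cdot \text{Poisson}(v / \text{gain})
   + \mathcal{N}(0, \sigma_{read}^2), $$

i.e. photon shot noise at the detector gain plus Gaussian read noise. The
difference of two noisy phase planes is then (at gain 1, $\sigma = 0$)
Skellam-distributed with mean $\lambda_1 - \lambda_2$ and variance
$\lambda_1 + \lambda_2$ — the tests check both moments at
$\lambda_1 = 100$, $\lambda_2 = 60$ over $10^6$ pixels within three
standard errors, using the exact fourth central moment
$3\sigma^4 + \sigma^2$ for the variance band. The default DC offset is
chosen large enough that all expected photon counts stay positive.

## Denoisers

Both denoisers operate on single 2-D planes; volumes are processed plane
by plane (`runPipelinePlanes()`), with the Z axis as bookkeeping only.

**Iterative median.** `medianDenoise()` applies a $3\times3$ median
filter (replicate padding) for a configurable number of passes, default
three — repeated application beyond that yields no further benefit on
these images. Each output pixel is one of its input window's values, a
property the tests verify against a brute-force sorted-window oracle.

**Residual CNN.** `trainDenoiser()` trains a reduced DnCNN-style network:
`depth` (default 8) layers of $3\times3$ convolutions with ReLU
activations and `width` (default 32) channels, the final layer predicting
the noise residual so that the output is `input − residual`. Training
minimizes mean squared error with mini-batch Adam on $40\times40$
patches sampled from the G and S planes of training pairs; supervised
mode pairs noisy draws with noiseless (or averaged) targets, and
noise2noise mode pairs two independent noisy draws of one field of view.
The forward/backward pass is implemented in compiled code via im2col +
GEMM; *all* stochastic choices (He weight initialization, patch
locations, batch order) are drawn from R's RNG, which makes training and
inference bit-reproducible for a given seed. The default sizes train in
minutes on one CPU core; they are a deliberately small stand-in for
full-scale denoising networks, sized to demonstrate the methodology
rather than to compete with models trained on large microscopy corpora.

Before entering either denoiser, each plane is min–max scaled to
$[0, 1]$ (`rangeScale()`), and restored afterwards with its own
parameters (`rangeUnscale()`); G and S are scaled independently. In
training, the target plane is scaled with its *input's* parameters so the
network learns the residual in a consistent frame. Per-plane affine
scaling is exactly invertible, so the lifetime ratio $S/G$ is unaffected
at noiseless fixed points.

## Segmentation

`kmeansPhasor()` clusters the per-pixel $(g, s)$ coordinates — not the
binned histogram — so every cloud entry keeps its 1:1 mapping back to an
image pixel (`labelsToImage()`). The implementation is Lloyd's algorithm
with k-means++ seeding, `n_init = 10` restarts, and an asserted
monotonically non-increasing inertia; labels are renumbered by ascending
centroid $g$ so results are restart-order independent. On clouds of at
most 12 points with $k \le 3$ the returned inertia equals the global
optimum found by exhaustive enumeration of all label assignments (an
acceptance requirement). Background pixels are excluded beforehand by an
intensity threshold. `segmentationAccuracy()` scores label images
against ground truth by the best match over label permutations.

## Metrics and rendering

Following the evaluation protocol, PSNR and SSIM are always computed on
min–max 8-bit normalized lifetime images:

1. invalid pixels drop to the display-range floor,
2. lifetimes are clipped to the display range,
3. both images are mapped to 0–255 (`minmax8bit()`, round-half-up),
4. `psnr()` ($10\log_{10}(\max(Y)^2/\text{MSE})$, $+\infty$ on zero MSE)
   and `ssim()` ($8\times8$ box window, $C_1 = (0.01\cdot255)^2$,
   $C_2 = (0.03\cdot255)^2$, via integral images) are evaluated.

After min–max normalization $\max(Y) = 255$, so "peak of the reference"
and "fixed 255" definitions of PSNR coincide. The pipeline routes every
lifetime metric through this protocol; nothing is measured on raw
lifetimes. `compositeHSV()` renders lifetime maps with brightness
encoding intensity and hue running blue (short $\tau$) to red (long
$\tau$) across a configurable display range (default 0–3 ns);
`fitLifetimeGaussians()` fits a sum of Gaussians to the lifetime
histogram by least squares (curve fit, not pixel-level EM), with
deterministic percentile-based initial means.

## Artifact formats

G/S planes, lifetimes and histograms are float32 multi-page TIFFs. The
package writes these with its own minimal uncompressed little-endian
writer because the common R TIFF bindings clamp floating-point samples to
$[0, 1]$ on write, which would corrupt signed G/S difference planes; the
files are read back (by the package and by standard readers) with values
preserved exactly at float32 precision. Renders are PNG; tables are
tab-separated text.

## Reproducibility

Every stochastic step — scene textures, noise draws, training-pair
sub-seeds, CNN initialization and batch order, k-means++ restarts — flows
from explicit integer seeds, and the full pipeline writes bit-identical
artifacts when re-run with the same configuration. The acceptance study
(`scripts/acceptance.R`) re-derives all of its seeds from a single
`--seed` argument.

## Limitations

* The simulator is a stand-in for real acquisitions: flat or smoothly
  textured regions, ideal homodyne response, pixel-independent noise. It
  makes the methodology testable against ground truth but does not model
  instrument response functions, afterpulsing, or spatially correlated
  noise.
* The CNN is intentionally small; its gains on these synthetics
  (≈ 2.5–4 dB) demonstrate the training/inference machinery, not
  state-of-the-art denoising.
* The calibrated phasor path is implemented but only exercised against
  synthetic references with known offsets.
* Multi-harmonic phasors, FRET trajectory analysis and blind unmixing
  beyond K-means are out of scope.
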