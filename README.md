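# phasorFLIM

Phasor denoising and segmentation for frequency-domain fluorescence
lifetime imaging microscopy (FD-FLIM), as an R package built on
Bioconductor-style S4 classes.

Fluorescence lifetime imaging measures, per pixel, how long a fluorophore
stays excited — a label-free contrast that distinguishes molecular species
and environments where intensity alone cannot. In frequency-domain FLIM
the sample is excited with light modulated at `f_mod` (80 MHz by default)
and the detector mixes the emission with four reference phases; the
complementary-phase differences give the uncalibrated real and imaginary
measurement planes

    S = V(0) − V(π),    G = V(π/2) − V(3π/2),    τ = S / (ω G),

with `ω = 2π f_mod`. Mapping each pixel to phasor coordinates
`(g, s) = (m cos φ, m sin φ)` places mono-exponential lifetimes on the
*universal semicircle* and turns species separation into point clustering.
Photon shot noise plus detector read noise (mixed Poisson–Gaussian)
scatters the phasor cloud, degrading both lifetime maps and segmentation;
this package quantifies that and repairs it by denoising the G and S
planes before phasor analysis, with an iterative median filter or a small
residual (DnCNN-style) convolutional network trained on simulated pairs
(supervised or Noise2Noise). See `vignettes/phasor-denoising.Rmd` for the
full methods description.

What's inside:

* **Simulator** — seeded synthetic scenes (disks/ellipses/rects/texture
  fields, mono- or bi-exponential), four-phase homodyne synthesis, mixed
  Poisson–Gaussian noise, TCSPC decay stacks, and training-pair
  generation (`generateScene`, `simulateFdPhases`, `addMpgNoise`,
  `simulateTcspc`, `makePairSet`).
* **Phasor** — G/S extraction, per-pixel lifetimes, closed-form
  mono-exponential phasor, time-domain transform, calibrated/uncalibrated
  FD phasor clouds, 2-D phasor histograms (`computeGS`, `lifetimeFromGS`,
  `monoExpPhasor`, `phasorTD`, `phasorFD`, `phasorHistogram`).
* **Denoising** — iterative 3×3 median filtering and a residual CNN with
  bit-deterministic CPU training (`medianDenoise`, `trainDenoiser`,
  `denoiseGS`).
* **Segmentation** — restarted k-means++ on the phasor cloud with
  canonical label order, label back-mapping, overlays, and
  permutation-matched accuracy (`kmeansPhasor`, `labelsToImage`,
  `segmentationAccuracy`).
* **Metrics & rendering** — PSNR/SSIM on min–max 8-bit normalized
  lifetime images, HSV composite renders, Gaussian fits to lifetime
  histograms (`psnr`, `ssim`, `minmax8bit`, `compositeHSV`,
  `fitLifetimeGaussians`).
* **Pipeline** — the end-to-end noisy-vs-denoised comparison with a file
  manifest (`runPipeline`, `runPipelinePlanes`,
  `evaluateAgainstReference`), plus a command-line front end in
  `inst/scripts/flimtool.R`.

## Worked example

A 128×128 scene with a 1 ns background and a 3 ns disk, noisy acquisition
at photon gain 1 and read sigma 3, denoised with the default median×3:

```r
library(phasorFLIM)

scene <- generateScene(128, 128, list(
  list(shape = "full", tau = 1, amplitude = 100),
  list(shape = "disk", center = c(64, 64), radius = 36, tau = 3,
       amplitude = 100)))
cfg <- flimConfig(kmeans_k = 2L, seed = 1L,
                  tau_display_range_ns = c(0, 4))
res <- runPipeline(cfg, scene = scene, outDir = "run_artifacts")
res@metrics
#>     branch   psnr_db       ssim  accuracy
#> 1    noisy  9.816409 0.06580812 0.9037476
#> 2 denoised 14.151648 0.10041626 0.9972534
```

Median filtering the G/S planes lifts the lifetime-image PSNR by 4.3 dB
and the two-cluster phasor segmentation accuracy from 90.4% to 99.7%.
The denoised cluster centroids recover the true phasor positions of the
two species:

```r
segCentroids(res@denoisedSeg)
#>           [,1]      [,2]
#> [1,] 0.3144375 0.4571985
#> [2,] 0.7934594 0.4015556
monoExpPhasor(c(3, 1))
#>              g         s
#> [1,] 0.3054408 0.4605939
#> [2,] 0.7983000 0.4012694
```

`run_artifacts/` now holds the noisy/denoised lifetime TIFFs, phasor
histograms, label images, HSV composites, overlays, a centroid table and
the metric table — every file listed in `res@manifest`.

To train and apply the CNN denoiser instead:

```r
pairs <- makePairSet(scene, noiseParams(1, 3), nPairs = 4,
                     mode = "supervised", seed = 555)
cnn <- trainDenoiser(pairs, "supervised", epochs = 16L, nPatches = 320L,
                     seed = 999L)
res <- runPipeline(flimConfig(denoiser = "cnn", kmeans_k = 2L, seed = 1L),
                   scene = scene, model = cnn)
```

The same workflow is scriptable without R code via the CLI:

```sh
Rscript inst/scripts/flimtool.R run --config config.yaml \
    --scene scene.yaml --out run_artifacts
```

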