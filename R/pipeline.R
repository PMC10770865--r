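# End-to-end orchestration: (simulate or load) -> G/S extraction ->
# [branch A: raw] and [branch B: denoised] -> lifetime + phasor ->
# histogram -> K-means segmentation -> renders and metrics for both
# branches. Every run produces the before/after pair; 3-D data are
# processed plane by plane by the caller (the Z axis is bookkeeping only).

# The metric protocol for lifetime images: invalid pixels drop to the clip
# floor, lifetimes are clipped to the display range, and both images are
# min-max normalized to 8-bit before PSNR/SSIM. All pipeline metrics go
# through here; nothing is ever measured on unnormalized lifetimes.
lifetimeMetricPair <- function(x, y, clipNs) {
  prep <- function(li) {
    t <- li@tauNs
    t[!li@valid] <- clipNs[1]
    minmax8bit(clipRange(t, clipNs[1], clipNs[2]))
  }
  X <- prep(x); Y <- prep(y)
  c(psnr = psnr(X, Y), ssim = ssim(X, Y))
}

#' Lifetime image from a ground-truth scene
#'
#' @param scene a [SceneTruth-class]
#' @return the true (mono-exponential component-1) lifetimes as a
#'   [LifetimeImage-class]; background pixels are invalid
#' @export
sceneLifetime <- function(scene) {
  stopifnot(is(scene, "SceneTruth"))
  valid <- scene@label > 0L
  tau <- scene@tauNs
  tau[!valid] <- NA_real_
  new("LifetimeImage", tauNs = tau, valid = valid)
}

#' Run the full denoise-and-segment pipeline
#'
#' Exactly one input source must be given: a ground-truth `scene` (which is
#' simulated and corrupted with mixed Poisson-Gaussian noise), a noisy
#' four-phase `phases` stack, or a ready [FlimMeasurement-class] `meas`.
#' Both the raw and the denoised branch are always produced, mirroring the
#' before/after comparisons every evaluation relies on. Deterministic given
#' `config@seed`.
#'
#' @param config a [RunConfig-class]
#' @param scene optional [SceneTruth-class]
#' @param phases optional [PhaseStack-class]
#' @param meas optional [FlimMeasurement-class]
#' @param noise [NoiseParams-class] for scene simulation (its seed is
#'   overridden by `config@seed`); default gain 1 V/photon, read sigma 3
#' @param model [DenoiserModel-class]; required when `config@denoiser` is
#'   "cnn", built internally for "median", ignored for "none"
#' @param dcOffset DC baseline for scene simulation
#' @param outDir optional output directory; when given, lifetime TIFFs,
#'   phasor histogram TIFFs, label TIFFs, render PNGs, the centroid table
#'   and a metric table are written and listed in the manifest
#' @return a [PipelineResult-class]
#' @export
runPipeline <- function(config, scene = NULL, phases = NULL, meas = NULL,
                        noise = NULL, model = NULL, dcOffset = NULL,
                        outDir = NULL) {
  stopifnot(is(config, "RunConfig"))
  nIn <- (!is.null(scene)) + (!is.null(phases)) + (!is.null(meas))
  if (nIn != 1L) stop("exactly one of scene, phases, meas must be given")

  if (!is.null(scene)) {
    clean <- simulateFdPhases(scene, config@fModHz, dcOffset)
    if (is.null(noise)) noise <- noiseParams(1, 3, config@seed)
    noise@seed <- config@seed
    phases <- addMpgNoise(clean, noise)
  }
  noisy <- if (!is.null(phases)) computeGS(phases) else meas

  model <- switch(config@denoiser,
    median = if (is.null(model)) medianModel(3L, config@medianIterations)
             else model,
    cnn = {
      if (is.null(model) || model@kind != "cnn" ||
          length(model@weights) == 0L)
        stop("denoiser 'cnn' requires a trained CNN model")
      model
    },
    none = NULL)
  denoised <- if (is.null(model)) noisy else denoiseGS(noisy, model)

  thr <- config@intensityThreshold
  branch <- function(m, seedOffset) {
    tau <- lifetimeFromGS(m, thr)
    cloud <- phasorFD(m, intensityThreshold = thr)
    hist <- phasorHistogram(cloud)
    seg <- kmeansPhasor(cloud, config@kmeansK,
                        seed = config@seed + seedOffset)
    labels <- labelsToImage(seg, cloud, dim(m@g))
    list(tau = tau, cloud = cloud, hist = hist, seg = seg, labels = labels)
  }
  bn <- branch(noisy, 0L)
  bd <- branch(denoised, 1L)

  metrics <- data.frame()
  if (!is.null(scene)) {
    ref <- sceneLifetime(scene)
    clip <- config@tauDisplayRangeNs
    mn <- lifetimeMetricPair(bn$tau, ref, clip)
    md <- lifetimeMetricPair(bd$tau, ref, clip)
    metrics <- data.frame(
      branch = c("noisy", "denoised"),
      psnr_db = c(mn["psnr"], md["psnr"]),
      ssim = c(mn["ssim"], md["ssim"]),
      accuracy = c(segmentationAccuracy(bn$labels, scene@label),
                   segmentationAccuracy(bd$labels, scene@label)),
      row.names = NULL)
  }

  manifest <- data.frame(file = character(), what = character())
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(fname, what, writer) {
      path <- file.path(outDir, fname)
      writer(path)
      manifest <<- rbind(manifest, data.frame(file = fname, what = what))
    }
    writeTau <- function(li, path) {
      t <- li@tauNs; t[!li@valid] <- 0
      writeStack(imageStack(t), path)
    }
    emit("tau_noisy.tif", "noisy lifetime (ns)",
         function(p) writeTau(bn$tau, p))
    emit("tau_denoised.tif", "denoised lifetime (ns)",
         function(p) writeTau(bd$tau, p))
    emit("phasor_hist_noisy.tif", "noisy phasor histogram",
         function(p) writeStack(imageStack(bn$hist@counts), p))
    emit("phasor_hist_denoised.tif", "denoised phasor histogram",
         function(p) writeStack(imageStack(bd$hist@counts), p))
    emit("labels_noisy.tif", "noisy cluster labels",
         function(p) writeStack(imageStack(bn$labels * 1.0), p))
    emit("labels_denoised.tif", "denoised cluster labels",
         function(p) writeStack(imageStack(bd$labels * 1.0), p))
    emit("composite_noisy.png", "noisy HSV composite", function(p)
      writeRenderPNG(compositeHSV(noisy@intensity, bn$tau,
                                  config@tauDisplayRangeNs), p))
    emit("composite_denoised.png", "denoised HSV composite", function(p)
      writeRenderPNG(compositeHSV(denoised@intensity, bd$tau,
                                  config@tauDisplayRangeNs), p))
    emit("overlay_noisy.png", "noisy cluster overlay", function(p)
      writeRenderPNG(overlaySegments(bn$labels, noisy@intensity), p))
    emit("overlay_denoised.png", "denoised cluster overlay", function(p)
      writeRenderPNG(overlaySegments(bd$labels, denoised@intensity), p))
    emit("centroids.tsv", "cluster centroid table", function(p) {
      df <- rbind(data.frame(branch = "noisy", cluster = seq_len(bn$seg@k),
                             g = bn$seg@centroids[, 1],
                             s = bn$seg@centroids[, 2]),
                  data.frame(branch = "denoised",
                             cluster = seq_len(bd$seg@k),
                             g = bd$seg@centroids[, 1],
                             s = bd$seg@centroids[, 2]))
      utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    })
    if (nrow(metrics))
      emit("metrics.tsv", "PSNR/SSIM/accuracy table", function(p)
        utils::write.table(metrics, p, sep = "\t", row.names = FALSE,
                           quote = FALSE))
  }

  new("PipelineResult", noisy = noisy, denoised = denoised,
      noisyTau = bn$tau, denoisedTau = bd$tau,
      noisyHist = bn$hist, denoisedHist = bd$hist,
      noisySeg = bn$seg, denoisedSeg = bd$seg,
      noisyLabels = bn$labels, denoisedLabels = bd$labels,
      metrics = metrics, manifest = manifest, config = config)
}

#' Run the pipeline plane-by-plane over a 3-D acquisition
#'
#' Volumes are processed as independent 2-D planes (the denoisers operate
#' on single planes); the Z axis is bookkeeping only. Per-plane lifetime
#' maps are stacked back to the input Z length; when `outDir` is given the
#' stacked noisy/denoised lifetime volumes are written alongside per-plane
#' subdirectories.
#'
#' @param config a [RunConfig-class]
#' @param phasesList list of [PhaseStack-class] planes (Z order)
#' @param model optional [DenoiserModel-class] (required for "cnn")
#' @param outDir optional output directory
#' @return `list(planes = list of PipelineResult, noisyTauStack,
#'   denoisedTauStack = ImageStack with Z = length(phasesList))`
#' @export
runPipelinePlanes <- function(config, phasesList, model = NULL,
                              outDir = NULL) {
  stopifnot(length(phasesList) >= 1L)
  results <- lapply(seq_along(phasesList), function(z) {
    sub <- if (is.null(outDir)) NULL
           else file.path(outDir, sprintf("plane_%03d", z))
    runPipeline(config, phases = phasesList[[z]], model = model,
                outDir = sub)
  })
  stackOf <- function(get) {
    planes <- lapply(results, function(r) {
      t <- get(r); t@tauNs[!t@valid] <- 0; t@tauNs
    })
    vol <- aperm(simplify2array(planes), c(3L, 1L, 2L))
    imageStack(vol)
  }
  noisyStack <- stackOf(function(r) r@noisyTau)
  denoisedStack <- stackOf(function(r) r@denoisedTau)
  if (!is.null(outDir)) {
    writeStack(noisyStack, file.path(outDir, "tau_noisy_volume.tif"))
    writeStack(denoisedStack, file.path(outDir, "tau_denoised_volume.tif"))
  }
  list(planes = results, noisyTauStack = noisyStack,
       denoisedTauStack = denoisedStack)
}

#' Compare both pipeline branches against a reference lifetime image
#'
#' PSNR and SSIM of noisy-vs-reference and denoised-vs-reference, computed
#' on min-max 8-bit normalized lifetime images (lifetimes clipped to the
#' run's display range first), plus the dB improvement
#' (denoised - noisy).
#'
#' @param result a [PipelineResult-class]
#' @param reference a [LifetimeImage-class] of matching shape
#' @return data.frame with one row per branch and an `improvement_db`
#'   attribute column on the denoised row
#' @export
evaluateAgainstReference <- function(result, reference) {
  stopifnot(is(result, "PipelineResult"), is(reference, "LifetimeImage"))
  if (!identical(dim(reference@tauNs), dim(result@noisyTau@tauNs)))
    stop("reference shape mismatch")
  clip <- result@config@tauDisplayRangeNs
  mn <- lifetimeMetricPair(result@noisyTau, reference, clip)
  md <- lifetimeMetricPair(result@denoisedTau, reference, clip)
  data.frame(branch = c("noisy", "denoised"),
             psnr_db = c(mn["psnr"], md["psnr"]),
             ssim = c(mn["ssim"], md["ssim"]),
             improvement_db = c(0, md["psnr"] - mn["psnr"]),
             row.names = NULL)
}
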