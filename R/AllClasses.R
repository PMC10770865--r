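#' @import methods
NULL

# ---------------------------------------------------------------------------
# Central containers. Images are stored as plain numeric matrices (Y rows,
# X columns) or (Z, Y, X) arrays; pixel coordinates are 0-based (row, col)
# at the user interface, 1-based internally as usual in R.
# ---------------------------------------------------------------------------

#' ImageStack: a 2-D plane or 3-D volume of intensities
#'
#' Container for measured or simulated image data. `pixels` is a numeric
#' matrix (axes Y, X) or a 3-D array (axes Z, Y, X); the axis order is fixed
#' and never silently reordered. Optional physical calibration is carried in
#' micrometres.
#'
#' @slot pixels numeric matrix (Y, X) or array (Z, Y, X)
#' @slot axes character vector of axis labels, `c("Y","X")` or `c("Z","Y","X")`
#' @slot pixelSizeUm physical pixel width in micrometres (NA if unknown)
#' @slot planeDepthUm Z step in micrometres (NA if unknown)
#' @export
setClass("ImageStack",
  representation(pixels = "array", axes = "character",
                 pixelSizeUm = "numeric", planeDepthUm = "numeric"),
  prototype(pixelSizeUm = NA_real_, planeDepthUm = NA_real_))

setValidity("ImageStack", function(object) {
  d <- dim(object@pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    return("pixels must be a 2-D matrix (Y, X) or 3-D array (Z, Y, X)")
  want <- if (length(d) == 2L) c("Y", "X") else c("Z", "Y", "X")
  if (!identical(object@axes, want))
    return(sprintf("axes must be (%s)", paste(want, collapse = ", ")))
  if (any(d < 1L)) return("all axis lengths must be >= 1")
  if (!all(is.finite(object@pixels))) return("pixel values must be finite")
  TRUE
})

#' RunConfig: pipeline run configuration
#'
#' @slot fModHz laser modulation frequency in Hz (default 8e7)
#' @slot denoiser one of "median", "cnn", "none"
#' @slot medianIterations number of median-filter passes
#' @slot kmeansK number of phasor clusters
#' @slot seed integer seed for all stochastic steps
#' @slot tauDisplayRangeNs length-2 numeric, lifetime range (ns) mapped to hue
#' @slot intensityThreshold fraction of max intensity below which pixels are
#'   excluded from phasor extraction and segmentation
#' @export
setClass("RunConfig",
  representation(fModHz = "numeric", denoiser = "character",
                 medianIterations = "integer", kmeansK = "integer",
                 seed = "integer", tauDisplayRangeNs = "numeric",
                 intensityThreshold = "numeric"))

setValidity("RunConfig", function(object) {
  if (length(object@fModHz) != 1L || !is.finite(object@fModHz) ||
      object@fModHz <= 0) return("fModHz must be a positive number")
  if (!object@denoiser %in% c("median", "cnn", "none"))
    return("denoiser must be one of 'median', 'cnn', 'none'")
  if (object@medianIterations < 0L) return("medianIterations must be >= 0")
  if (object@kmeansK < 1L) return("kmeansK must be >= 1")
  if (length(object@tauDisplayRangeNs) != 2L ||
      diff(object@tauDisplayRangeNs) <= 0)
    return("tauDisplayRangeNs must be an increasing (min, max) pair")
  if (object@intensityThreshold < 0 || object@intensityThreshold >= 1)
    return("intensityThreshold must lie in [0, 1)")
  TRUE
})

#' SceneTruth: ground-truth description of a simulated scene
#'
#' Per-pixel true lifetime (ns), expected brightness and integer fluorophore
#' label (0 = background). Bi-exponential pixels carry a second component
#' lifetime in `tau2Ns` and the fractional amplitude of the first component
#' in `frac` (`frac = 1` marks mono-exponential pixels).
#'
#' @slot tauNs numeric matrix of component-1 lifetimes (ns)
#' @slot tau2Ns numeric matrix of component-2 lifetimes (ns; 0 where absent)
#' @slot frac numeric matrix, fractional amplitude of component 1 in [0, 1]
#' @slot amplitude numeric matrix of mean brightness (expected photon level)
#' @slot label integer matrix of fluorophore ids (0 = background)
#' @export
setClass("SceneTruth",
  representation(tauNs = "matrix", tau2Ns = "matrix", frac = "matrix",
                 amplitude = "matrix", label = "matrix"))

setValidity("SceneTruth", function(object) {
  d <- dim(object@tauNs)
  for (s in c("tau2Ns", "frac", "amplitude", "label"))
    if (!identical(dim(slot(object, s)), d))
      return("all truth maps must share one shape")
  fg <- object@label > 0L
  if (any(fg & !(object@tauNs > 0)))
    return("tauNs must be > 0 wherever label > 0")
  if (any(object@amplitude < 0)) return("amplitude must be >= 0")
  if (any(object@frac < 0 | object@frac > 1))
    return("fractional amplitudes must lie in [0, 1]")
  TRUE
})

#' PhaseStack: the four homodyne mixer images of one plane
#'
#' Intermediate-frequency voltage images V_IF(phi) at the fixed phase order
#' phi = 0, pi/2, pi, 3*pi/2.
#'
#' @slot vIf numeric array (Y, X, 4), third index following the phase order
#' @slot fModHz modulation frequency in Hz
#' @export
setClass("PhaseStack",
  representation(vIf = "array", fModHz = "numeric"))

setValidity("PhaseStack", function(object) {
  d <- dim(object@vIf)
  if (length(d) != 3L || d[3] != 4L)
    return("vIf must be a (Y, X, 4) array of the four phase images")
  if (object@fModHz <= 0) return("fModHz must be > 0")
  TRUE
})

#' NoiseParams: mixed Poisson-Gaussian detector noise description
#'
#' @slot photonGain volts per detected photon
#' @slot readSigma standard deviation of additive Gaussian read noise (volts)
#' @slot seed integer RNG seed
#' @export
setClass("NoiseParams",
  representation(photonGain = "numeric", readSigma = "numeric",
                 seed = "integer"))

setValidity("NoiseParams", function(object) {
  if (object@photonGain <= 0) return("photonGain must be > 0")
  if (object@readSigma < 0) return("readSigma must be >= 0")
  TRUE
})

#' TcspcStack: per-pixel TCSPC decay histograms
#'
#' @slot counts numeric array (Y, X, nBins) of photon counts per time bin
#' @slot binWidthNs time-bin width in ns
#' @slot nBins number of time bins
#' @export
setClass("TcspcStack",
  representation(counts = "array", binWidthNs = "numeric", nBins = "integer"))

setValidity("TcspcStack", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L) return("counts must be a (Y, X, nBins) array")
  if (d[3] != object@nBins) return("third dimension must equal nBins")
  if (object@binWidthNs <= 0) return("binWidthNs must be > 0")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' FlimMeasurement: G, S and intensity planes of one FLIM measurement
#'
#' The real (G) and imaginary (S) complementary-phase difference images plus
#' the DC intensity estimate; the object every denoiser acts on.
#'
#' @slot g numeric matrix, real-axis plane (signed volts)
#' @slot s numeric matrix, imaginary-axis plane (signed volts)
#' @slot intensity numeric matrix, non-negative brightness
#' @slot fModHz modulation frequency in Hz
#' @export
setClass("FlimMeasurement",
  representation(g = "matrix", s = "matrix", intensity = "matrix",
                 fModHz = "numeric"))

setValidity("FlimMeasurement", function(object) {
  if (!identical(dim(object@g), dim(object@s)) ||
      !identical(dim(object@g), dim(object@intensity)))
    return("g, s and intensity must share one shape")
  if (object@fModHz <= 0) return("fModHz must be > 0")
  if (any(object@intensity < 0)) return("intensity must be >= 0")
  TRUE
})

#' LifetimeImage: per-pixel lifetime map with validity mask
#'
#' Invalid pixels (near-zero G or sub-threshold intensity) carry NA and are
#' excluded from all downstream statistics.
#'
#' @slot tauNs numeric matrix of lifetimes in ns (NA where invalid)
#' @slot valid logical matrix marking pixels with a defined lifetime
#' @export
setClass("LifetimeImage",
  representation(tauNs = "matrix", valid = "matrix"))

setValidity("LifetimeImage", function(object) {
  if (!identical(dim(object@tauNs), dim(object@valid)))
    return("tauNs and valid must share one shape")
  if (!is.logical(object@valid)) return("valid must be logical")
  if (any(!is.finite(object@tauNs[object@valid])))
    return("tauNs must be finite wherever valid")
  TRUE
})

#' PhasorCloud: per-pixel phasor coordinates
#'
#' One entry per valid pixel; `(gCoord, sCoord) = (m*cos(phi), m*sin(phi))`
#' holds exactly for every entry. `pixelIndex` maps entries back to pixels
#' as 0-based (z, y, x) rows.
#'
#' @slot gCoord,sCoord numeric vectors of normalized phasor coordinates
#' @slot m numeric vector, modulation degree (signed projection when the raw
#'   G plane is negative; such entries are flagged in `negG`)
#' @slot phi numeric vector, phase in radians
#' @slot pixelIndex integer matrix with columns z, y, x (0-based)
#' @slot negG logical vector flagging entries whose raw G was negative
#' @export
setClass("PhasorCloud",
  representation(gCoord = "numeric", sCoord = "numeric", m = "numeric",
                 phi = "numeric", pixelIndex = "matrix", negG = "logical"))

setValidity("PhasorCloud", function(object) {
  n <- length(object@gCoord)
  if (length(object@sCoord) != n || length(object@m) != n ||
      length(object@phi) != n || nrow(object@pixelIndex) != n ||
      length(object@negG) != n)
    return("all cloud fields must have one common length")
  if (ncol(object@pixelIndex) != 3L)
    return("pixelIndex must have columns (z, y, x)")
  if (n > 0) {
    err <- max(abs(object@gCoord - object@m * cos(object@phi)),
               abs(object@sCoord - object@m * sin(object@phi)))
    if (err > 1e-9) return("(gCoord, sCoord) must equal (m cos phi, m sin phi)")
  }
  TRUE
})

#' PhasorHistogram: 2-D binned phasor density
#'
#' @slot counts numeric matrix of bin counts; rows follow the g axis, columns
#'   the s axis
#' @slot gEdges,sEdges numeric vectors of bin boundaries
#' @slot clipped number of cloud entries outside the histogram window
#' @export
setClass("PhasorHistogram",
  representation(counts = "matrix", gEdges = "numeric", sEdges = "numeric",
                 clipped = "integer"))

setValidity("PhasorHistogram", function(object) {
  if (nrow(object@counts) != length(object@gEdges) - 1L ||
      ncol(object@counts) != length(object@sEdges) - 1L)
    return("counts shape must match bin edges")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' ScaleParams: per-plane min-max scaling record
#'
#' @slot lo,hi minimum and maximum of the plane before scaling to [0, 1]
#' @export
setClass("ScaleParams", representation(lo = "numeric", hi = "numeric"))

setValidity("ScaleParams", function(object) {
  if (object@hi < object@lo) return("hi must be >= lo")
  TRUE
})

#' DenoiserModel: median-filter or residual-CNN denoiser
#'
#' @slot kind "median" or "cnn"
#' @slot medianKernel odd window size for the median filter
#' @slot medianIterations number of sequential median passes
#' @slot cnnDepth,cnnWidth layer and feature-channel counts of the CNN
#' @slot weights list of trained parameter matrices (empty until trained)
#' @slot trainSeed integer seed the model was trained with
#' @slot trainingMode "supervised" or "noise2noise"
#' @export
setClass("DenoiserModel",
  representation(kind = "character", medianKernel = "integer",
                 medianIterations = "integer", cnnDepth = "integer",
                 cnnWidth = "integer", weights = "list",
                 trainSeed = "integer", trainingMode = "character"),
  prototype(medianKernel = 3L, medianIterations = 3L, cnnDepth = 8L,
            cnnWidth = 32L, weights = list(), trainSeed = 0L,
            trainingMode = "supervised"))

setValidity("DenoiserModel", function(object) {
  if (!object@kind %in% c("median", "cnn"))
    return("kind must be 'median' or 'cnn'")
  if (object@kind == "median") {
    if (object@medianKernel < 3L || object@medianKernel %% 2L == 0L)
      return("medianKernel must be odd and >= 3")
    if (object@medianIterations < 0L)
      return("medianIterations must be >= 0")
  } else {
    if (object@cnnDepth < 3L) return("cnnDepth must be >= 3")
    if (object@cnnWidth < 1L) return("cnnWidth must be >= 1")
  }
  TRUE
})

#' Segmentation: K-means clustering of a phasor cloud
#'
#' @slot k number of clusters
#' @slot centroids k x 2 matrix of cluster centres in (g, s) space, ordered
#'   by ascending g (ties by ascending s)
#' @slot labels integer vector, cluster id in 1..k per cloud entry
#' @slot inertia total within-cluster sum of squared distances
#' @slot seed integer seed used for initialization
#' @export
setClass("Segmentation",
  representation(k = "integer", centroids = "matrix", labels = "integer",
                 inertia = "numeric", seed = "integer"))

setValidity("Segmentation", function(object) {
  if (nrow(object@centroids) != object@k || ncol(object@centroids) != 2L)
    return("centroids must be a k x 2 matrix")
  if (any(!is.finite(object@centroids))) return("centroids must be finite")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    return("labels must lie in 1..k")
  if (object@inertia < 0) return("inertia must be >= 0")
  TRUE
})

#' CompositeImage: HSV composite lifetime render
#'
#' @slot rgb numeric array (Y, X, 3) with channels in [0, 1]
#' @slot tauRangeNs lifetime range (ns) mapped onto the hue axis
#' @slot hueConvention description of the hue endpoints
#' @export
setClass("CompositeImage",
  representation(rgb = "array", tauRangeNs = "numeric",
                 hueConvention = "character"))

setValidity("CompositeImage", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L) return("rgb must be a (Y, X, 3) array")
  if (any(object@rgb < 0 | object@rgb > 1)) return("channels must be in [0, 1]")
  TRUE
})

#' GaussianMixFit: Gaussian components fitted to a lifetime histogram
#'
#' @slot nComponents number of Gaussian components
#' @slot meansNs,sigmasNs,weights per-component parameters (means ascending,
#'   weights normalized to sum to 1)
#' @slot rSquared goodness of fit of the summed curve to the histogram
#' @export
setClass("GaussianMixFit",
  representation(nComponents = "integer", meansNs = "numeric",
                 sigmasNs = "numeric", weights = "numeric",
                 rSquared = "numeric"))

setValidity("GaussianMixFit", function(object) {
  n <- object@nComponents
  if (length(object@meansNs) != n || length(object@sigmasNs) != n ||
      length(object@weights) != n)
    return("component parameter lengths must equal nComponents")
  if (any(object@sigmasNs <= 0)) return("sigmas must be > 0")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-6)
    return("weights must be >= 0 and sum to 1")
  TRUE
})

#' PipelineResult: all artefacts of one end-to-end run
#'
#' @slot noisy,denoised the raw and denoised [FlimMeasurement]s
#' @slot noisyTau,denoisedTau the corresponding [LifetimeImage]s
#' @slot noisyHist,denoisedHist phasor histograms of both branches
#' @slot noisySeg,denoisedSeg phasor segmentations of both branches
#' @slot noisyLabels,denoisedLabels back-mapped label images
#' @slot metrics data.frame of PSNR/SSIM rows (empty without a reference)
#' @slot manifest data.frame listing every file written
#' @slot config the [RunConfig] of the run
#' @export
setClass("PipelineResult",
  representation(noisy = "FlimMeasurement", denoised = "FlimMeasurement",
                 noisyTau = "LifetimeImage", denoisedTau = "LifetimeImage",
                 noisyHist = "PhasorHistogram",
                 denoisedHist = "PhasorHistogram",
                 noisySeg = "Segmentation", denoisedSeg = "Segmentation",
                 noisyLabels = "matrix", denoisedLabels = "matrix",
                 metrics = "data.frame", manifest = "data.frame",
                 config = "RunConfig"))

# --------------------------------------------------------------------------
# show() methods
# --------------------------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  cat(sprintf("ImageStack: %s [%s]\n",
              paste(dim(object@pixels), collapse = " x "),
              paste(object@axes, collapse = ", ")))
  cat(sprintf("  range: [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  cat(sprintf("  fModHz: %g  denoiser: %s  medianIterations: %d\n",
              object@fModHz, object@denoiser, object@medianIterations))
  cat(sprintf("  kmeansK: %d  seed: %d  intensityThreshold: %g\n",
              object@kmeansK, object@seed, object@intensityThreshold))
  cat(sprintf("  tauDisplayRangeNs: [%g, %g]\n",
              object@tauDisplayRangeNs[1], object@tauDisplayRangeNs[2]))
})

setMethod("show", "FlimMeasurement", function(object) {
  cat(sprintf("FlimMeasurement: %d x %d at %.3g MHz\n",
              nrow(object@g), ncol(object@g), object@fModHz / 1e6))
  cat(sprintf("  G range [%.4g, %.4g]; S range [%.4g, %.4g]\n",
              min(object@g), max(object@g), min(object@s), max(object@s)))
})

setMethod("show", "PhaseStack", function(object) {
  d <- dim(object@vIf)
  cat(sprintf("PhaseStack: %d x %d, four phases (0, pi/2, pi, 3pi/2) at %.3g MHz\n",
              d[1], d[2], object@fModHz / 1e6))
})

setMethod("show", "LifetimeImage", function(object) {
  v <- object@tauNs[object@valid]
  cat(sprintf("LifetimeImage: %d x %d, %d/%d valid pixels\n",
              nrow(object@tauNs), ncol(object@tauNs),
              sum(object@valid), length(object@valid)))
  if (length(v))
    cat(sprintf("  tau (ns): median %.3f, range [%.3f, %.3f]\n",
                stats::median(v), min(v), max(v)))
})

setMethod("show", "PhasorCloud", function(object) {
  cat(sprintf("PhasorCloud: %d entries", length(object@gCoord)))
  if (length(object@gCoord))
    cat(sprintf("; g in [%.3f, %.3f], s in [%.3f, %.3f]",
                min(object@gCoord), max(object@gCoord),
                min(object@sCoord), max(object@sCoord)))
  cat("\n")
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: k = %d, %d entries, inertia %.5g\n",
              object@k, length(object@labels), object@inertia))
  for (i in seq_len(object@k))
    cat(sprintf("  cluster %d: centroid (%.4f, %.4f), n = %d\n", i,
                object@centroids[i, 1], object@centroids[i, 2],
                sum(object@labels == i)))
})

setMethod("show", "DenoiserModel", function(object) {
  if (object@kind == "median")
    cat(sprintf("DenoiserModel: median %dx%d, %d iteration(s)\n",
                object@medianKernel, object@medianKernel,
                object@medianIterations))
  else
    cat(sprintf("DenoiserModel: residual CNN depth %d, width %d (%s%s)\n",
                object@cnnDepth, object@cnnWidth, object@trainingMode,
                if (length(object@weights)) ", trained" else ", untrained"))
})

setMethod("show", "GaussianMixFit", function(object) {
  cat(sprintf("GaussianMixFit: %d component(s), R^2 = %.4f\n",
              object@nComponents, object@rSquared))
  for (i in seq_len(object@nComponents))
    cat(sprintf("  mean %.3f ns, sigma %.3f ns, weight %.3f\n",
                object@meansNs[i], object@sigmasNs[i], object@weights[i]))
})

# --------------------------------------------------------------------------
# Accessors
# --------------------------------------------------------------------------

#' Accessors for phasorFLIM containers
#'
#' Small functions extracting the commonly used parts of the S4 containers:
#' pixel arrays, G/S/intensity planes, lifetime maps and masks, phasor
#' coordinates, segmentation labels and centroids.
#'
#' @param x an object of the documented class
#' @return the requested slot content (see individual functions)
#' @name accessors
NULL

#' @rdname accessors
#' @export
stackPixels <- function(x) { stopifnot(is(x, "ImageStack")); x@pixels }

#' @rdname accessors
#' @export
stackAxes <- function(x) { stopifnot(is(x, "ImageStack")); x@axes }

#' @rdname accessors
#' @export
gPlane <- function(x) { stopifnot(is(x, "FlimMeasurement")); x@g }

#' @rdname accessors
#' @export
sPlane <- function(x) { stopifnot(is(x, "FlimMeasurement")); x@s }

#' @rdname accessors
#' @export
intensityPlane <- function(x) { stopifnot(is(x, "FlimMeasurement")); x@intensity }

#' @rdname accessors
#' @export
tauMap <- function(x) { stopifnot(is(x, "LifetimeImage")); x@tauNs }

#' @rdname accessors
#' @export
validMask <- function(x) { stopifnot(is(x, "LifetimeImage")); x@valid }

#' @rdname accessors
#' @export
phasorCoords <- function(x) {
  stopifnot(is(x, "PhasorCloud"))
  cbind(g = x@gCoord, s = x@sCoord)
}

#' @rdname accessors
#' @export
cloudPixelIndex <- function(x) { stopifnot(is(x, "PhasorCloud")); x@pixelIndex }

#' @rdname accessors
#' @export
segLabels <- function(x) { stopifnot(is(x, "Segmentation")); x@labels }

#' @rdname accessors
#' @export
segCentroids <- function(x) { stopifnot(is(x, "Segmentation")); x@centroids }

#' @rdname accessors
#' @export
segInertia <- function(x) { stopifnot(is(x, "Segmentation")); x@inertia }
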