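# Denoising of the G and S measurement planes: iterative median filtering
# and a small residual CNN with supervised or Noise2Noise training, both
# wrapped in per-plane min-max scaling so the CNN always sees [0, 1] input
# and results are mapped back to the original (signed) voltage scale.

#' Iterated 2-D median filter
#'
#' `iterations` sequential passes of a `kernel x kernel` median filter with
#' edge-replication padding; `iterations = 0` is the identity. More than
#' three passes brings no further benefit on phasor planes while costing
#' time, hence the package default of three elsewhere.
#'
#' @param image numeric matrix
#' @param kernel odd window size (default 3)
#' @param iterations number of passes (>= 0)
#' @return filtered matrix
#' @export
medianDenoise <- function(image, kernel = 3L, iterations = 1L) {
  assertMatrix(image)
  kernel <- as.integer(kernel); iterations <- as.integer(iterations)
  if (kernel %% 2L == 0L || kernel < 3L) stop("kernel must be odd and >= 3")
  if (iterations < 0L) stop("iterations must be >= 0")
  out <- image
  for (i in seq_len(iterations)) out <- median_filter_pass(out, kernel)
  out
}

#' Min-max scale a plane into [0, 1]
#'
#' @param image numeric matrix with at least two distinct values
#' @return `list(image = scaled matrix, params = ScaleParams)`
#' @export
rangeScale <- function(image) {
  assertMatrix(image)
  lo <- min(image); hi <- max(image)
  if (hi <= lo) stop("degenerate range: constant image cannot be scaled")
  list(image = (image - lo) / (hi - lo),
       params = new("ScaleParams", lo = lo, hi = hi))
}

#' Invert min-max scaling
#'
#' @param scaled matrix in [0, 1]
#' @param params the [ScaleParams-class] recorded by [rangeScale()]
#' @return matrix on the original scale
#' @export
rangeUnscale <- function(scaled, params) {
  stopifnot(is(params, "ScaleParams"))
  scaled * (params@hi - params@lo) + params@lo
}

#' Construct a median-filter denoiser model
#'
#' @param kernel odd window size
#' @param iterations pass count (default 3; further passes bring no
#'   additional advantage on phasor planes)
#' @return a [DenoiserModel-class]
#' @export
medianModel <- function(kernel = 3L, iterations = 3L) {
  new("DenoiserModel", kind = "median", medianKernel = as.integer(kernel),
      medianIterations = as.integer(iterations))
}

# He-normal initial weights for the conv stack, drawn from the current
# RNG stream.
cnnInitWeights <- function(depth, width) {
  sizes <- c(1L, rep(width, depth - 1L), 1L)
  lapply(seq_len(depth), function(l) {
    cin <- sizes[l]; cout <- sizes[l + 1L]
    fanIn <- 9L * cin
    list(W = matrix(stats::rnorm(fanIn * cout, 0, sqrt(2 / fanIn)),
                    fanIn, cout),
         b = rep(0, cout))
  })
}

# Extract nPatches seeded random patchSize x patchSize crops from each
# plane pair; planes are scaled with the INPUT plane's min-max parameters
# so input and target live on one scale (residual learning requirement).
extractPatchPairs <- function(pairs, patchSize, nPatches) {
  xs <- list(); ts <- list(); k <- 0L
  perPair <- ceiling(nPatches / (2L * length(pairs)))
  for (p in pairs) {
    for (plane in c("g", "s")) {
      inp <- slot(p$input, plane); tgt <- slot(p$target, plane)
      sc <- rangeScale(inp)
      tgtS <- (tgt - sc$params@lo) / (sc$params@hi - sc$params@lo)
      h <- nrow(inp); w <- ncol(inp)
      if (h < patchSize || w < patchSize) {
        k <- k + 1L; xs[[k]] <- sc$image; ts[[k]] <- tgtS
        next
      }
      for (i in seq_len(perPair)) {
        y0 <- sample.int(h - patchSize + 1L, 1L)
        x0 <- sample.int(w - patchSize + 1L, 1L)
        k <- k + 1L
        xs[[k]] <- sc$image[y0:(y0 + patchSize - 1L),
                            x0:(x0 + patchSize - 1L)]
        ts[[k]] <- tgtS[y0:(y0 + patchSize - 1L),
                        x0:(x0 + patchSize - 1L)]
      }
    }
  }
  keep <- seq_len(min(k, nPatches))
  list(inputs = xs[keep], targets = ts[keep])
}

#' Train the residual denoising CNN
#'
#' Trains a DnCNN-style stack of 3x3 convolution + ReLU layers whose last
#' layer predicts the noise residual (denoised = input - residual),
#' minimizing mean squared error to the target plane with mini-batch Adam.
#' In supervised mode the targets are clean (or averaged) planes; in
#' noise2noise mode they are second independent noisy draws of the same
#' field of view. Training patches are sampled from the G and S planes of
#' `pairs`, each plane min-max scaled to [0, 1] (the target with its
#' input's parameters). Bit-deterministic given `seed`.
#'
#' @param pairs list of `list(input=, target=)` [FlimMeasurement-class]
#'   pairs, e.g. from [makePairSet()], or of `list(input=, target=)`
#'   numeric matrices already scaled to [0, 1]
#' @param mode "supervised" or "noise2noise" (recorded on the model; the
#'   pairing itself is fixed by `pairs`)
#' @param depth number of convolution layers (>= 3)
#' @param width feature channels of the hidden layers
#' @param epochs training epochs
#' @param patchSize square patch side in pixels
#' @param nPatches total number of training patches
#' @param batchSize mini-batch size
#' @param lr Adam learning rate
#' @param seed integer seed for weight init, patch sampling and batch order
#' @return a trained [DenoiserModel-class]
#' @export
trainDenoiser <- function(pairs, mode = c("supervised", "noise2noise"),
                          depth = 8L, width = 32L, epochs = 20L,
                          patchSize = 40L, nPatches = 400L, batchSize = 16L,
                          lr = 1e-3, seed = 0L) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) stop("empty pair list")
  depth <- as.integer(depth); width <- as.integer(width)
  if (depth < 3L) stop("depth must be >= 3")
  rawPlanes <- is.matrix(pairs[[1L]]$input)
  prep <- withSeed(seed, {
    if (rawPlanes) {
      ins <- lapply(pairs, `[[`, "input")
      tgs <- lapply(pairs, `[[`, "target")
      rng <- range(unlist(lapply(c(ins, tgs), range)))
      if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
        stop("plane pairs must be scaled to [0, 1]; see rangeScale()")
      list(inputs = ins, targets = tgs)
    } else {
      extractPatchPairs(pairs, patchSize, nPatches)
    }
  })
  n <- length(prep$inputs)
  h <- nrow(prep$inputs[[1L]]); w <- ncol(prep$inputs[[1L]])
  inputs <- array(unlist(prep$inputs), c(h, w, n))
  targets <- array(unlist(prep$targets), c(h, w, n))
  fit <- withSeed(seed + 1L, {
    w0 <- cnnInitWeights(depth, width)
    order <- vapply(seq_len(epochs), function(e) sample.int(n),
                    integer(n))
    cnn_train_cpp(inputs, targets, w0, as.integer(epochs),
                  as.integer(batchSize), lr, order)
  })
  model <- new("DenoiserModel", kind = "cnn", cnnDepth = depth,
               cnnWidth = width, weights = fit$weights,
               trainSeed = as.integer(seed), trainingMode = mode)
  attr(model@weights, "loss") <- as.numeric(fit$loss)
  model
}

#' Apply a denoiser model to one plane
#'
#' Median models dispatch to [medianDenoise()]; CNN models return
#' `input - predicted residual`, computed on the [0, 1]-scaled plane. The
#' CNN is fully convolutional, so any input size is accepted.
#'
#' @param image numeric matrix (for CNN models: scaled to [0, 1])
#' @param model a [DenoiserModel-class]
#' @return denoised matrix of the same shape
#' @export
applyDenoiser <- function(image, model) {
  assertMatrix(image)
  stopifnot(is(model, "DenoiserModel"))
  if (model@kind == "median")
    return(medianDenoise(image, model@medianKernel, model@medianIterations))
  if (length(model@weights) == 0L) stop("CNN model carries no weights")
  cnn_predict_cpp(image, model@weights)
}

#' Denoise the G and S planes of a measurement
#'
#' Each of G and S independently: min-max scale to [0, 1], apply the model,
#' map back with that plane's own scale parameters. The intensity plane
#' passes through unchanged. With a zero-effect model the chain is the
#' identity to machine precision.
#'
#' @param meas a [FlimMeasurement-class]
#' @param model a [DenoiserModel-class]
#' @return a [FlimMeasurement-class] with denoised G and S
#' @export
denoiseGS <- function(meas, model) {
  stopifnot(is(meas, "FlimMeasurement"), is(model, "DenoiserModel"))
  doPlane <- function(p) {
    sc <- rangeScale(p)
    rangeUnscale(applyDenoiser(sc$image, model), sc$params)
  }
  out <- meas
  out@g <- doPlane(meas@g)
  out@s <- doPlane(meas@s)
  out
}
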