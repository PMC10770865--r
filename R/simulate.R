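# Synthetic FD-FLIM scene and measurement generator.
#
# Scenes are labelled multi-fluorophore fields (disks, ellipses, rectangles,
# full-frame fills, optionally textured lifetime ranges) with per-pixel
# mono- or bi-exponential decays. Measurements follow the four-phase
# homodyne mixer convention V_IF(theta) = dc + A * m * sin(theta + phi),
# where m = 1/sqrt(1 + (w*tau)^2) and phi = arctan(w*tau); the complementary
# phase differences then give S/G = tan(phi) = w*tau exactly, so the
# noiseless pipeline recovers mono-exponential lifetimes to machine
# precision. Detector noise is mixed Poisson-Gaussian applied per phase
# channel, which makes the G and S differences Skellam-distributed.

#' Construct mixed Poisson-Gaussian noise parameters
#'
#' @param photonGain volts per detected photon (Poisson conversion)
#' @param readSigma standard deviation of additive Gaussian read noise
#' @param seed integer RNG seed
#' @return a [NoiseParams-class]
#' @export
noiseParams <- function(photonGain = 1, readSigma = 0, seed = 0L) {
  new("NoiseParams", photonGain = as.numeric(photonGain),
      readSigma = as.numeric(readSigma), seed = as.integer(seed))
}

#' Generate a ground-truth scene from a region specification
#'
#' Regions are painted in order (later regions win on overlap) onto a
#' background of zero amplitude and label 0. Each region is a list with
#' fields:
#' \describe{
#'   \item{shape}{"full", "disk", "ellipse" or "rect"}
#'   \item{center}{(y, x) centre, 0-based pixels (disk/ellipse)}
#'   \item{radius}{disk radius, or (ry, rx) semi-axes for an ellipse}
#'   \item{corner / size}{(y, x) corner and extent for "rect"}
#'   \item{tau}{lifetime in ns: a scalar, or a (min, max) range filled with
#'     a smooth seeded texture field}
#'   \item{tau2, frac}{optional second-component lifetime and fractional
#'     amplitude of the first component for bi-exponential regions}
#'   \item{amplitude}{mean brightness (expected photon level)}
#' }
#'
#' @param width,height image size in pixels (X, Y)
#' @param regions list of region specifications (non-empty)
#' @param seed integer seed controlling texture-field draws only; region
#'   geometry is fully determined by the region list
#' @return a [SceneTruth-class]
#' @export
generateScene <- function(width, height, regions, seed = 0L) {
  if (length(regions) == 0L) stop("scene specification has no regions")
  tau  <- matrix(0, height, width)
  tau2 <- matrix(0, height, width)
  frac <- matrix(1, height, width)
  amp  <- matrix(0, height, width)
  lab  <- matrix(0L, height, width)
  yy <- matrix(seq_len(height) - 1L, height, width)
  xx <- matrix(rep(seq_len(width) - 1L, each = height), height, width)
  withSeed(seed, {
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      shape <- if (is.null(r$shape)) "full" else r$shape
      inside <- switch(shape,
        full = matrix(TRUE, height, width),
        disk = {
          c0 <- r$center
          (yy - c0[1])^2 + (xx - c0[2])^2 <= r$radius^2
        },
        ellipse = {
          c0 <- r$center
          ((yy - c0[1]) / r$radius[1])^2 + ((xx - c0[2]) / r$radius[2])^2 <= 1
        },
        rect = {
          yy >= r$corner[1] & yy < r$corner[1] + r$size[1] &
          xx >= r$corner[2] & xx < r$corner[2] + r$size[2]
        },
        stop("unknown region shape: ", shape))
      if (any(unlist(r$tau) <= 0)) stop("region lifetimes must be positive")
      tvals <- if (length(r$tau) == 2L)
        textureField(height, width, r$tau[1], r$tau[2])[inside]
      else r$tau
      tau[inside] <- tvals
      tau2[inside] <- if (!is.null(r$tau2)) r$tau2 else 0
      frac[inside] <- if (!is.null(r$frac)) r$frac else 1
      amp[inside] <- if (!is.null(r$amplitude)) r$amplitude else 1
      lab[inside] <- i
    }
  })
  new("SceneTruth", tauNs = tau, tau2Ns = tau2, frac = frac,
      amplitude = amp, label = lab)
}

# Smooth random field in [lo, hi]: white noise, 5x5 box smoothing, min-max
# rescale. Uses the current RNG stream (seeded by the caller).
textureField <- function(h, w, lo, hi) {
  f <- matrix(stats::runif(h * w), h, w)
  f <- boxSmooth(f, 2L)
  if (max(f) > min(f)) f <- (f - min(f)) / (max(f) - min(f))
  lo + f * (hi - lo)
}

boxSmooth <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w); n <- matrix(0, h, w)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- clipRange(seq_len(h) + dy, 1L, h)
    xs <- clipRange(seq_len(w) + dx, 1L, w)
    out <- out + m[ys, xs]
    n <- n + 1
  }
  out / n
}

# Per-pixel complex modulated signal A * m * exp(i*phi) summed over decay
# components; returns list(re, im) matrices.
sceneModulation <- function(scene, fModHz) {
  w <- omegaOf(fModHz)
  comp <- function(tauNs, weight) {
    wt <- w * tauNs * 1e-9
    m <- 1 / sqrt(1 + wt^2)
    phi <- atan(wt)
    amp <- scene@amplitude * weight * m
    list(re = amp * cos(phi), im = amp * sin(phi))
  }
  c1 <- comp(scene@tauNs, scene@frac)
  re <- c1$re; im <- c1$im
  bi <- scene@tau2Ns > 0 & scene@frac < 1
  if (any(bi)) {
    c2 <- comp(pmax(scene@tau2Ns, 1e-12), 1 - scene@frac)
    re[bi] <- re[bi] + c2$re[bi]
    im[bi] <- im[bi] + c2$im[bi]
  }
  # zero-amplitude pixels contribute nothing
  re[scene@amplitude == 0] <- 0
  im[scene@amplitude == 0] <- 0
  list(re = re, im = im)
}

#' Simulate the noiseless four-phase homodyne readout of a scene
#'
#' Per pixel with mono-exponential lifetime tau and amplitude A the mixer
#' output is `V_IF(theta) = dc + A * m * sin(theta + phi)` with
#' `m = 1/sqrt(1 + (w tau)^2)`, `phi = arctan(w tau)` and `w = 2 pi f_mod`.
#' Bi-exponential pixels sum component signals weighted by fractional
#' amplitude. Applying the complementary-phase differences and the ratio
#' `tau = S/(w G)` to this output recovers mono-exponential lifetimes
#' exactly.
#'
#' @param scene a [SceneTruth-class]
#' @param fModHz modulation frequency in Hz (default 80 MHz)
#' @param dcOffset constant DC baseline in volts; the default, five times
#'   the largest modulated amplitude, guarantees non-negative photon rates
#'   under Poisson noise
#' @return a noiseless [PhaseStack-class]
#' @export
simulateFdPhases <- function(scene, fModHz = 8.0e7, dcOffset = NULL) {
  stopifnot(is(scene, "SceneTruth"), fModHz > 0)
  mod <- sceneModulation(scene, fModHz)
  if (is.null(dcOffset)) dcOffset <- 5 * max(scene@amplitude, 1)
  h <- nrow(scene@tauNs); w <- ncol(scene@tauNs)
  v <- array(0, c(h, w, 4L))
  thetas <- c(0, 0.5, 1, 1.5) * pi
  # A*m*sin(theta + phi) = A*m*(sin(theta)cos(phi) + cos(theta)sin(phi))
  for (k in 1:4)
    v[, , k] <- dcOffset + sin(thetas[k]) * mod$re + cos(thetas[k]) * mod$im
  new("PhaseStack", vIf = v, fModHz = fModHz)
}

#' Add mixed Poisson-Gaussian noise to a phase stack
#'
#' Each sample v becomes `gain * Poisson(v / gain) + Normal(0, sigma^2)`,
#' drawn independently per phase channel (the channels are separate mixer
#' outputs, which is what makes the G and S differences Skellam-
#' distributed). Deterministic given the seed in `noise`.
#'
#' @param phases a [PhaseStack-class] with non-negative expected rates
#' @param noise a [NoiseParams-class]
#' @return a noisy [PhaseStack-class]
#' @export
addMpgNoise <- function(phases, noise) {
  stopifnot(is(phases, "PhaseStack"), is(noise, "NoiseParams"))
  lam <- phases@vIf / noise@photonGain
  if (any(lam < 0)) stop("negative expected photon count; raise dcOffset")
  n <- length(lam)
  v <- withSeed(noise@seed, {
    x <- noise@photonGain * stats::rpois(n, as.vector(lam))
    if (noise@readSigma > 0) x <- x + stats::rnorm(n, 0, noise@readSigma)
    x
  })
  out <- phases
  out@vIf <- array(v, dim(phases@vIf))
  out
}

#' Simulate TCSPC decay histograms for a scene
#'
#' Noiseless mode (`photonsPerPixel = Inf`) evaluates the multi-exponential
#' decay at bin centres; noisy mode draws independent Poisson counts per bin
#' with per-pixel expected total `photonsPerPixel`.
#'
#' @param scene a [SceneTruth-class]
#' @param binWidthNs time-bin width in ns
#' @param nBins number of bins; the span `nBins * binWidthNs` must cover at
#'   least five times the largest simulated lifetime
#' @param photonsPerPixel expected photon count per pixel, or `Inf` for the
#'   noiseless limit
#' @param seed integer RNG seed (noisy mode)
#' @return a [TcspcStack-class]
#' @export
simulateTcspc <- function(scene, binWidthNs, nBins, photonsPerPixel = Inf,
                          seed = 0L) {
  stopifnot(is(scene, "SceneTruth"))
  nBins <- as.integer(nBins)
  tmax <- max(scene@tauNs, scene@tau2Ns)
  if (nBins * binWidthNs < 5 * tmax)
    stop("bin span must cover at least 5x the largest lifetime")
  h <- nrow(scene@tauNs); w <- ncol(scene@tauNs)
  tc <- (seq_len(nBins) - 0.5) * binWidthNs
  counts <- array(0, c(h, w, nBins))
  decay <- function(tau, t) exp(-t / tau)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (scene@amplitude[y, x] == 0) next
    f <- scene@frac[y, x]
    d <- f * decay(scene@tauNs[y, x], tc)
    if (scene@tau2Ns[y, x] > 0 && f < 1)
      d <- d + (1 - f) * decay(scene@tau2Ns[y, x], tc)
    counts[y, x, ] <- scene@amplitude[y, x] * d
  }
  if (is.finite(photonsPerPixel)) {
    counts <- withSeed(seed, {
      out <- counts
      for (y in seq_len(h)) for (x in seq_len(w)) {
        d <- counts[y, x, ]
        if (sum(d) == 0) next
        lam <- photonsPerPixel * d / sum(d)
        out[y, x, ] <- stats::rpois(nBins, lam)
      }
      out
    })
  }
  new("TcspcStack", counts = counts, binWidthNs = binWidthNs, nBins = nBins)
}

#' Build a TcspcStack directly from decay counts
#'
#' @param counts numeric vector (one pixel), matrix (rows = pixels) or
#'   (Y, X, nBins) array of per-bin counts
#' @param binWidthNs time-bin width in ns
#' @return a [TcspcStack-class]
#' @export
tcspcStack <- function(counts, binWidthNs) {
  if (is.null(dim(counts))) counts <- array(counts, c(1L, 1L, length(counts)))
  else if (length(dim(counts)) == 2L)
    counts <- array(counts, c(nrow(counts), 1L, ncol(counts)))
  new("TcspcStack", counts = counts, binWidthNs = binWidthNs,
      nBins = dim(counts)[3L])
}

#' Generate training pairs of noisy / target measurements
#'
#' Three pairing modes mirror the denoiser-training protocols:
#' \describe{
#'   \item{supervised}{each noisy draw is paired with the noiseless G/S}
#'   \item{noise2noise}{two independent noisy draws of the same field of
#'     view form input and target}
#'   \item{averaged}{the target is the mean of `nAverage` independent
#'     draws, emulating repeated-acquisition averaging of one FOV}
#' }
#'
#' @param scene a [SceneTruth-class]
#' @param noise a [NoiseParams-class] (its seed is ignored; `seed` rules)
#' @param nPairs number of pairs to generate
#' @param mode "supervised", "noise2noise" or "averaged"
#' @param fModHz modulation frequency in Hz
#' @param dcOffset DC baseline passed to [simulateFdPhases()]
#' @param nAverage number of draws averaged per target in "averaged" mode
#' @param seed integer RNG seed
#' @return list of `list(input = FlimMeasurement, target = FlimMeasurement)`
#' @export
makePairSet <- function(scene, noise, nPairs, mode = c("supervised",
                        "noise2noise", "averaged"), fModHz = 8.0e7,
                        dcOffset = NULL, nAverage = 5L, seed = 0L) {
  mode <- match.arg(mode)
  if (nPairs < 1L) stop("nPairs must be >= 1")
  if (mode == "averaged" && nAverage < 2L)
    stop("averaged mode needs nAverage >= 2")
  clean <- simulateFdPhases(scene, fModHz, dcOffset)
  cleanGs <- computeGS(clean)
  draw <- function(s) {
    np <- noise; np@seed <- as.integer(s)
    computeGS(addMpgNoise(clean, np))
  }
  subSeeds <- withSeed(seed, sample.int(2^30, nPairs * (1L + nAverage)))
  k <- 0L
  nextSeed <- function() { k <<- k + 1L; subSeeds[k] }
  lapply(seq_len(nPairs), function(i) {
    input <- draw(nextSeed())
    target <- switch(mode,
      supervised = cleanGs,
      noise2noise = draw(nextSeed()),
      averaged = {
        acc <- draw(nextSeed())
        for (j in seq_len(nAverage - 1L)) {
          d <- draw(nextSeed())
          acc@g <- acc@g + d@g; acc@s <- acc@s + d@s
          acc@intensity <- acc@intensity + d@intensity
        }
        acc@g <- acc@g / nAverage; acc@s <- acc@s / nAverage
        acc@intensity <- acc@intensity / nAverage
        acc
      })
    list(input = input, target = target)
  })
}
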