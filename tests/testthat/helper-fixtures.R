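# Shared fixtures: synthetic scenes, a phasor-cloud builder, the lifetime
# metric protocol shortcut, and a lazily trained CNN reused by every file
# that needs one (training is the expensive step; it runs at most once).

tauClip <- c(0, 4)

# Two-fluorophore study scene: 1 ns background with two 3 ns disks, equal
# brightness, on a 256 x 256 frame.
twoFluorScene <- function(size = 256L) {
  f <- size / 256
  generateScene(size, size, list(
    list(shape = "full", tau = 1, amplitude = 100),
    list(shape = "disk", center = c(128, 128) * f, radius = 70 * f,
         tau = 3, amplitude = 100),
    list(shape = "disk", center = c(60, 190) * f, radius = 30 * f,
         tau = 3, amplitude = 100)))
}

noisyMeasurement <- function(scene, seed) {
  computeGS(addMpgNoise(simulateFdPhases(scene), noiseParams(1, 3, seed)))
}

tauPsnrVsTruth <- function(tau, scene, clip = tauClip) {
  phasorFLIM:::lifetimeMetricPair(tau, sceneLifetime(scene),
                                  clip)[["psnr"]]
}

# Bare (g, s) point cloud with dummy pixel bookkeeping, for clustering
# tests that do not come from an image.
pointCloud <- function(pts) {
  n <- nrow(pts)
  phasorFLIM:::makeCloud(pts[, 1], pts[, 2],
                         m = sqrt(pts[, 1]^2 + pts[, 2]^2),
                         phi = atan2(pts[, 2], pts[, 1]),
                         pixelIndex = cbind(z = rep(0L, n),
                                            y = seq_len(n) - 1L,
                                            x = rep(0L, n)))
}

# Exact minimum within-cluster sum of squares by exhaustive enumeration of
# all k^n label assignments (vectorized over assignments).
bruteForceInertia <- function(pts, k) {
  n <- nrow(pts)
  labs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  x <- pts[, 1]; y <- pts[, 2]; sq <- x^2 + y^2
  total <- numeric(nrow(labs))
  for (j in seq_len(k)) {
    Z <- labs == j
    nj <- rowSums(Z)
    sx <- as.numeric(Z %*% x)
    sy <- as.numeric(Z %*% y)
    ss <- as.numeric(Z %*% sq)
    wss <- ss - (sx^2 + sy^2) / pmax(nj, 1)
    wss[nj == 0] <- 0
    total <- total + wss
  }
  min(total)
}

.fixtureCache <- new.env(parent = emptyenv())

# Small residual CNN trained supervised on MPG-noisy pairs of the study
# scene. Shared across test files via the cache.
trainedCnn <- function() {
  if (is.null(.fixtureCache$cnn)) {
    pairs <- makePairSet(twoFluorScene(), noiseParams(1, 3), nPairs = 4,
                         mode = "supervised", seed = 555)
    .fixtureCache$cnn <- trainDenoiser(
      pairs, "supervised", depth = 8L, width = 32L, epochs = 16L,
      patchSize = 40L, nPatches = 320L, batchSize = 16L, seed = 999L)
  }
  .fixtureCache$cnn
}
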