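# simulator: scene generation, homodyne phase synthesis, mixed
# Poisson-Gaussian noise, TCSPC decays and training-pair construction.

test_that("full-frame single region fills lifetime and label maps", {
  sc <- generateScene(32, 24, list(list(shape = "full", tau = 2,
                                        amplitude = 100)))
  expect_true(all(sc@tauNs == 2))
  expect_true(all(sc@label == 1L))
  expect_true(all(sc@amplitude == 100))
})

test_that("three-region textured scene stays inside declared lifetime ranges", {
  sc <- generateScene(64, 64, list(
    list(shape = "full", tau = c(2, 2.8), amplitude = 50),
    list(shape = "disk", center = c(32, 20), radius = 10, tau = c(1.5, 2),
         amplitude = 80),
    list(shape = "disk", center = c(32, 48), radius = 10, tau = c(2.9, 3.4),
         amplitude = 60)))
  expect_setequal(unique(as.vector(sc@label)), 1:3)
  for (i in 1:3) {
    rng <- switch(i, c(2, 2.8), c(1.5, 2), c(2.9, 3.4))
    tv <- sc@tauNs[sc@label == i]
    expect_true(all(tv >= rng[1] - 1e-12 & tv <= rng[2] + 1e-12))
  }
})

test_that("scene geometry is seed-independent; texture draws are not", {
  spec <- list(list(shape = "full", tau = c(1, 2), amplitude = 10),
               list(shape = "rect", corner = c(4, 4), size = c(8, 8),
                    tau = 3, amplitude = 20))
  a <- generateScene(32, 32, spec, seed = 1L)
  b <- generateScene(32, 32, spec, seed = 2L)
  expect_identical(a@label, b@label)
  expect_identical(a@tauNs[a@label == 2L], b@tauNs[b@label == 2L])
  expect_false(identical(a@tauNs[a@label == 1L], b@tauNs[b@label == 1L]))
  expect_identical(generateScene(32, 32, spec, seed = 1L)@tauNs, a@tauNs)
})

test_that("scene generator rejects empty or unphysical specifications", {
  expect_error(generateScene(8, 8, list()), "region")
  expect_error(generateScene(8, 8, list(list(shape = "full", tau = -1,
                                             amplitude = 1))), "positive")
})

test_that("noiseless homodyne phases invert to the exact scene lifetime", {
  sc <- generateScene(16, 16, list(list(shape = "full", tau = 2,
                                        amplitude = 1)))
  phases <- simulateFdPhases(sc, dcOffset = 0)
  tau <- lifetimeFromGS(computeGS(phases))
  expect_true(all(validMask(tau)))
  expect_lt(max(abs(tauMap(tau) - 2) / 2), 1e-9)
})

test_that("short-lifetime limit collapses to dc + A sin(theta)", {
  sc <- generateScene(4, 4, list(list(shape = "full", tau = 1e-6,
                                      amplitude = 2)))
  phases <- simulateFdPhases(sc, dcOffset = 10)
  theta <- c(0, 0.5, 1, 1.5) * pi
  for (k in 1:4)
    expect_equal(phases@vIf[, , k],
                 matrix(10 + 2 * sin(theta[k]), 4, 4), tolerance = 1e-5)
})

test_that("zero-amplitude pixels emit the DC offset in all four phases", {
  sc <- generateScene(8, 8, list(
    list(shape = "rect", corner = c(0, 0), size = c(4, 8), tau = 2,
         amplitude = 0),
    list(shape = "rect", corner = c(4, 0), size = c(4, 8), tau = 2,
         amplitude = 1)))
  phases <- simulateFdPhases(sc, dcOffset = 7)
  for (k in 1:4)
    expect_true(all(phases@vIf[1:4, , k] == 7))
})

test_that("MPG noise reproduces Poisson and Gaussian channel moments", {
  # pure Poisson channel at rate 100 (gain 1, sigma 0), 1e6 samples
  sc <- generateScene(1000, 1000, list(list(shape = "full", tau = 1e-9,
                                            amplitude = 1)))
  phases <- simulateFdPhases(sc, dcOffset = 100)
  noisy <- addMpgNoise(phases, noiseParams(1, 0, 7L))
  v <- as.vector(noisy@vIf[, , 2])      # theta = pi/2 plane, mean 100 + m~1
  mu <- mean(phases@vIf[, , 2])
  n <- length(v)
  expect_lt(abs(mean(v) - mu), 3 * sqrt(mu / n))
  expect_lt(abs(var(v) - mu), 3 * mu * sqrt(2 / n))

  # pure Gaussian channel: zero signal, sigma = 2
  phases0 <- simulateFdPhases(sc, dcOffset = 0)
  phases0@vIf[] <- 0
  g <- as.vector(addMpgNoise(phases0, noiseParams(1, 2, 8L))@vIf)
  expect_lt(abs(mean(g)), 3 * 2 / sqrt(length(g)))
  expect_lt(abs(var(g) - 4), 3 * 4 * sqrt(2 / length(g)))
})

test_that("MPG noise is seed-deterministic and rejects negative rates", {
  sc <- generateScene(16, 16, list(list(shape = "full", tau = 2,
                                        amplitude = 5)))
  phases <- simulateFdPhases(sc)
  a <- addMpgNoise(phases, noiseParams(1, 3, 11L))
  b <- addMpgNoise(phases, noiseParams(1, 3, 11L))
  expect_identical(a@vIf, b@vIf)
  expect_false(identical(a@vIf, addMpgNoise(phases,
                                            noiseParams(1, 3, 12L))@vIf))
  neg <- simulateFdPhases(sc, dcOffset = 0)
  neg@vIf[] <- -1
  expect_error(addMpgNoise(neg, noiseParams(1, 0, 1L)), "negative")
})

test_that("noiseless TCSPC decays are exact exponentials and mix linearly", {
  sc1 <- generateScene(2, 2, list(list(shape = "full", tau = 2,
                                       amplitude = 1)))
  d <- simulateTcspc(sc1, binWidthNs = 0.01, nBins = 5000)
  cts <- d@counts[1, 1, ]
  ratios <- cts[-1] / cts[-length(cts)]
  expect_equal(ratios, rep(exp(-0.01 / 2), length(ratios)),
               tolerance = 1e-12)

  # 50/50 amplitude mix of 1 ns and 4 ns = average of the pure decays
  mk <- function(tau, fr = NULL, tau2 = NULL) {
    r <- list(shape = "full", tau = tau, amplitude = 1)
    if (!is.null(tau2)) { r$tau2 <- tau2; r$frac <- fr }
    generateScene(1, 1, list(r))
  }
  dm <- simulateTcspc(mk(1, 0.5, 4), binWidthNs = 0.02, nBins = 2500)
  d1 <- simulateTcspc(mk(1), binWidthNs = 0.02, nBins = 2500)
  d4 <- simulateTcspc(mk(4), binWidthNs = 0.02, nBins = 2500)
  expect_equal(dm@counts[1, 1, ],
               (d1@counts[1, 1, ] + d4@counts[1, 1, ]) / 2,
               tolerance = 1e-12)
})

test_that("noisy TCSPC totals follow the Poisson budget and span is checked", {
  sc <- generateScene(8, 8, list(list(shape = "full", tau = 2,
                                      amplitude = 1)))
  d <- simulateTcspc(sc, binWidthNs = 0.05, nBins = 400,
                     photonsPerPixel = 1e4, seed = 3L)
  tot <- apply(d@counts, c(1, 2), sum)
  expect_true(all(abs(tot - 1e4) < 3 * sqrt(1e4) + 3 * sqrt(1e4)))
  expect_lt(abs(mean(tot) - 1e4), 3 * sqrt(1e4 / 64))
  expect_error(simulateTcspc(sc, binWidthNs = 0.05, nBins = 100), "span")
})

test_that("averaged-mode targets shrink variance about fivefold", {
  sc <- generateScene(64, 64, list(list(shape = "full", tau = 2,
                                        amplitude = 50)))
  clean <- computeGS(simulateFdPhases(sc))
  pairs <- makePairSet(sc, noiseParams(1, 0), nPairs = 3,
                       mode = "averaged", nAverage = 5L, seed = 21L)
  vSingle <- mean(vapply(pairs, function(p)
    var(as.vector(gPlane(p$input) - gPlane(clean))), 0))
  vTarget <- mean(vapply(pairs, function(p)
    var(as.vector(gPlane(p$target) - gPlane(clean))), 0))
  expect_gt(vSingle / vTarget, 4)
  expect_lt(vSingle / vTarget, 6.5)
})

test_that("noise2noise pairs differ but share expectations; supervised targets are clean", {
  sc <- generateScene(64, 64, list(list(shape = "full", tau = 2,
                                        amplitude = 50)))
  clean <- computeGS(simulateFdPhases(sc))
  n2n <- makePairSet(sc, noiseParams(1, 1), nPairs = 1,
                     mode = "noise2noise", seed = 5L)[[1]]
  expect_false(identical(gPlane(n2n$input), gPlane(n2n$target)))
  se <- sd(gPlane(n2n$input)) / sqrt(length(gPlane(n2n$input)))
  expect_lt(abs(mean(gPlane(n2n$input)) - mean(gPlane(n2n$target))),
            6 * se)

  sup <- makePairSet(sc, noiseParams(1, 1), nPairs = 1,
                     mode = "supervised", seed = 5L)[[1]]
  expect_identical(gPlane(sup$target), gPlane(clean))
  expect_identical(sPlane(sup$target), sPlane(clean))
})
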