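# phasor: G/S extraction, lifetime inversion, closed-form mono-exponential
# phasor, time-domain transform, FD cloud construction and 2-D histogram.

omega <- 2 * pi * 8.0e7

test_that("computeGS implements the complementary-phase differences", {
  # equal phases cancel exactly
  v <- array(3.5, c(4, 4, 4))
  m0 <- computeGS(new("PhaseStack", vIf = v, fModHz = 8.0e7))
  expect_true(all(gPlane(m0) == 0) && all(sPlane(m0) == 0))
  expect_true(all(intensityPlane(m0) == 3.5))

  # noiseless tau = 2 ns pixel: s/g = omega * tau = 1.00531
  sc <- generateScene(4, 4, list(list(shape = "full", tau = 2,
                                      amplitude = 1)))
  phases <- simulateFdPhases(sc)
  m <- computeGS(phases)
  expect_equal(unique(as.vector(sPlane(m) / gPlane(m))),
               omega * 2e-9, tolerance = 1e-9)
  expect_equal(sPlane(m)[1, 1] / gPlane(m)[1, 1], 1.00531,
               tolerance = 1e-5)

  # swapping the 0 and pi planes negates s only
  sw <- phases
  sw@vIf[, , c(1, 3)] <- sw@vIf[, , c(3, 1)]
  msw <- computeGS(sw)
  expect_equal(sPlane(msw), -sPlane(m))
  expect_equal(gPlane(msw), gPlane(m))
})

test_that("lifetimeFromGS inverts tau = s/(omega g) and guards degeneracies", {
  m <- flimMeasurement(g = matrix(1, 2, 2),
                       s = matrix(omega * 2e-9, 2, 2))
  expect_equal(tauMap(lifetimeFromGS(m)), matrix(2, 2, 2),
               tolerance = 1e-12)

  gz <- matrix(c(1, 0, 1, 1), 2, 2)
  mz <- flimMeasurement(g = gz, s = matrix(1, 2, 2))
  tz <- lifetimeFromGS(mz)
  expect_identical(validMask(tz), gz != 0)
  expect_true(is.na(tauMap(tz)[2, 1]))

  # intensity threshold marks dim pixels invalid
  mi <- flimMeasurement(g = matrix(1, 2, 2), s = matrix(1, 2, 2),
                        intensity = matrix(c(1, 0.01, 1, 1), 2, 2))
  expect_identical(validMask(lifetimeFromGS(mi, 0.05)),
                   matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
})

test_that("noiseless multi-region scene lifetimes are recovered to 1e-9 relative", {
  sc <- generateScene(40, 40, list(
    list(shape = "full", tau = 0.5, amplitude = 1),
    list(shape = "rect", corner = c(0, 10), size = c(40, 10), tau = 1,
         amplitude = 2),
    list(shape = "rect", corner = c(0, 20), size = c(40, 10), tau = 2,
         amplitude = 3),
    list(shape = "rect", corner = c(0, 30), size = c(40, 10), tau = 4,
         amplitude = 4)))
  tau <- lifetimeFromGS(computeGS(simulateFdPhases(sc)))
  expect_true(all(validMask(tau)))
  expect_lt(max(abs(tauMap(tau) - sc@tauNs) / sc@tauNs), 1e-9)
})

test_that("monoExpPhasor matches its closed form, limits and the semicircle", {
  expect_equal(monoExpPhasor(0), cbind(g = 1, s = 0))
  expect_equal(as.vector(monoExpPhasor(1e9)), c(0, 0), tolerance = 1e-6)
  p2 <- monoExpPhasor(2)
  wt <- omega * 2e-9
  expect_equal(as.vector(p2), c(1 / (1 + wt^2), wt / (1 + wt^2)),
               tolerance = 1e-12)
  expect_equal(round(as.vector(p2), 5), c(0.49735, 0.49999))

  taus <- c(0, 0.1, 0.5, 1, 2, 4, 10, 100)
  p <- monoExpPhasor(taus)
  expect_lt(max(abs(p[, "s"]^2 + (p[, "g"] - 0.5)^2 - 0.25)), 1e-14)
})

test_that("monoExpPhasor agrees with numerical integration of the decay transform", {
  # independent oracle: adaptive quadrature of the decay transforms
  w <- omega * 1e-9
  quad <- function(f, tau) stats::integrate(f, 0, 80 * tau,
                                            rel.tol = 1e-12,
                                            subdivisions = 2000L)$value
  for (tau in c(0.7, 2, 3.5)) {
    tot <- quad(function(t) exp(-t / tau), tau)
    num <- c(quad(function(t) exp(-t / tau) * cos(w * t), tau) / tot,
             quad(function(t) exp(-t / tau) * sin(w * t), tau) / tot)
    expect_equal(as.vector(monoExpPhasor(tau)), num, tolerance = 1e-8)
  }
})

test_that("phasorTD reproduces the closed-form phasor on fine decays", {
  mkDecay <- function(tau) {
    sc <- generateScene(1, 1, list(list(shape = "full", tau = tau,
                                        amplitude = 1)))
    simulateTcspc(sc, binWidthNs = 0.001, nBins = 50000)
  }
  for (tau in c(0.5, 1, 2, 4)) {
    cl <- phasorTD(mkDecay(tau))
    ref <- as.vector(monoExpPhasor(tau))
    expect_lt(max(abs(c(phasorCoords(cl)[, "g"], phasorCoords(cl)[, "s"]) - ref)),
              1e-4)
  }

  # 1 photon in bin 0 only: delta decay at the first bin centre
  cts <- array(0, c(1, 1, 100)); cts[1, 1, 1] <- 1
  d <- tcspcStack(cts, binWidthNs = 0.001)
  cl <- phasorTD(d)
  expect_equal(as.numeric(phasorCoords(cl)[, "g"]), 1, tolerance = 1e-6)
  expect_equal(as.numeric(phasorCoords(cl)[, "s"]), 0, tolerance = 1e-3)

  expect_error(phasorTD(tcspcStack(array(0, c(2, 2, 10)), 0.1)), "zero")
})

test_that("mixture phasors stay on the chord between component phasors", {
  sc1 <- generateScene(1, 1, list(list(shape = "full", tau = 1,
                                       amplitude = 1)))
  sc4 <- generateScene(1, 1, list(list(shape = "full", tau = 4,
                                       amplitude = 1)))
  d1 <- simulateTcspc(sc1, 0.002, 25000)@counts[1, 1, ]
  d4 <- simulateTcspc(sc4, 0.002, 25000)@counts[1, 1, ]
  p1 <- as.vector(monoExpPhasor(1)); p4 <- as.vector(monoExpPhasor(4))
  chord <- p4 - p1
  for (wgt in seq(0, 1, by = 0.1)) {
    mix <- wgt * d1 / sum(d1) + (1 - wgt) * d4 / sum(d4)
    cl <- phasorTD(tcspcStack(array(mix, c(1, 1, length(mix))), 0.002))
    p <- c(phasorCoords(cl)[, "g"], phasorCoords(cl)[, "s"])
    # signed distance from the chord through p1 and p4
    cross <- (p[1] - p1[1]) * chord[2] - (p[2] - p1[2]) * chord[1]
    expect_lt(abs(cross) / sqrt(sum(chord^2)), 1e-4)
    along <- sum((p - p1) * chord) / sum(chord^2)
    expect_gte(along, -1e-6); expect_lte(along, 1 + 1e-6)
  }
})

test_that("uncalibrated phasorFD puts noiseless mono-exponentials on the semicircle", {
  sc <- generateScene(12, 12, list(list(shape = "full", tau = 2,
                                        amplitude = 3)))
  cl <- phasorFD(computeGS(simulateFdPhases(sc)))
  co <- phasorCoords(cl)
  ref <- as.vector(monoExpPhasor(2))
  expect_lt(max(abs(co[, "g"] - ref[1])), 1e-6)
  expect_lt(max(abs(co[, "s"] - ref[2])), 1e-6)
  # definitional identity of the cloud entries
  expect_lt(max(abs(co[, "g"] - cl@m * cos(cl@phi))), 1e-12)
  expect_lt(max(abs(co[, "s"] - cl@m * sin(cl@phi))), 1e-12)
  # phase route and ratio route agree on valid pixels
  tauPhase <- tan(cl@phi) / (omega * 1e-9)
  tau <- lifetimeFromGS(computeGS(simulateFdPhases(sc)))
  expect_equal(tauPhase, tauMap(tau)[cbind(cl@pixelIndex[, "y"] + 1L,
                                           cl@pixelIndex[, "x"] + 1L)],
               tolerance = 1e-9)
})

test_that("calibration cancels a known instrumental phase offset", {
  sc <- generateScene(6, 6, list(list(shape = "full", tau = 2,
                                      amplitude = 1)))
  meas <- computeGS(simulateFdPhases(sc))
  rot <- exp(1i * 0.1)                  # +0.1 rad instrumental offset
  offset <- function(m) {
    z <- complex(real = gPlane(m), imaginary = sPlane(m)) * rot
    flimMeasurement(matrix(Re(z), nrow(gPlane(m))),
                    matrix(Im(z), nrow(gPlane(m))),
                    intensityPlane(m), m@fModHz)
  }
  shifted <- offset(meas)
  cl <- phasorFD(shifted, calibration = list(reference = shifted,
                                             tauRefNs = 2))
  ref <- as.vector(monoExpPhasor(2))
  co <- phasorCoords(cl)
  expect_lt(max(abs(co[, "g"] - ref[1])), 1e-9)
  expect_lt(max(abs(co[, "s"] - ref[2])), 1e-9)
})

test_that("masked pixels never reach the phasor cloud", {
  inten <- matrix(1, 8, 8); inten[1:4, ] <- 0.001
  m <- flimMeasurement(g = matrix(0.5, 8, 8), s = matrix(0.4, 8, 8),
                       intensity = inten)
  cl <- phasorFD(m, intensityThreshold = 0.05)
  expect_equal(nrow(cloudPixelIndex(cl)), 32L)
  expect_true(all(cloudPixelIndex(cl)[, "y"] >= 4L))
})

test_that("phasorHistogram bins, conserves and clips correctly", {
  one <- pointCloud(cbind(0.31, 0.42))
  h1 <- phasorHistogram(one, nBins = 16L)
  expect_equal(sum(h1@counts), 1)
  expect_equal(sum(h1@counts > 0), 1L)
  expect_equal(h1@clipped, 0L)

  set.seed(9)
  pts <- cbind(runif(500, -0.2, 1.2), runif(500, -0.1, 0.8))
  h <- phasorHistogram(pointCloud(pts), nBins = 32L)
  expect_equal(sum(h@counts) + h@clipped, 500)
  expect_gt(h@clipped, 0L)

  expect_error(phasorHistogram(one, nBins = 1L), "nBins|bins")
})

test_that("a two-lifetime noiseless scene occupies exactly two histogram bins", {
  sc <- generateScene(20, 20, list(
    list(shape = "full", tau = 1, amplitude = 1),
    list(shape = "rect", corner = c(0, 10), size = c(20, 10), tau = 3,
         amplitude = 1)))
  cl <- phasorFD(computeGS(simulateFdPhases(sc)))
  h <- phasorHistogram(cl, nBins = 256L)
  expect_equal(sum(h@counts > 0), 2L)
  expect_equal(sum(h@counts), 400)
})
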