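# denoise: iterative median filtering, per-plane scaling, residual CNN
# training/inference and the G/S denoising chain.

test_that("median filter matches a brute-force sorted-window oracle", {
  # independent oracle: explicit replicate-pad + sort over each 3x3 window
  bruteMedian <- function(img, kernel) {
    r <- (kernel - 1L) %/% 2L
    h <- nrow(img); w <- ncol(img)
    out <- img
    for (i in seq_len(h)) for (j in seq_len(w)) {
      ys <- pmin(pmax(i + (-r:r), 1L), h)
      xs <- pmin(pmax(j + (-r:r), 1L), w)
      win <- sort(as.vector(img[ys, xs]))
      out[i, j] <- win[(length(win) + 1L) %/% 2L]
    }
    out
  }
  set.seed(13)
  for (trial in 1:4) {
    img <- matrix(rnorm(16 * 16), 16, 16)
    got <- medianDenoise(img, kernel = 3L, iterations = 1L)
    expect_identical(got, bruteMedian(img, 3L))
    # membership: every output value existed in its input window
    r <- 1L
    ok <- vapply(seq_len(256), function(idx) {
      i <- (idx - 1L) %% 16L + 1L; j <- (idx - 1L) %/% 16L + 1L
      ys <- pmin(pmax(i + (-r:r), 1L), 16L)
      xs <- pmin(pmax(j + (-r:r), 1L), 16L)
      got[i, j] %in% img[ys, xs]
    }, logical(1))
    expect_true(all(ok))
  }
  img5 <- matrix(rnorm(12 * 12), 12, 12)
  expect_identical(medianDenoise(img5, 5L, 1L), bruteMedian(img5, 5L))
})

test_that("median filter basics: constants, impulses, composition, identity", {
  cons <- matrix(4, 9, 9)
  expect_identical(medianDenoise(cons, 3L, 2L), cons)

  imp <- matrix(0, 9, 9); imp[5, 5] <- 100
  expect_identical(medianDenoise(imp, 3L, 1L), matrix(0, 9, 9))

  set.seed(2)
  x <- matrix(rnorm(100), 10, 10)
  expect_identical(medianDenoise(x, 3L, 3L),
                   medianDenoise(medianDenoise(medianDenoise(x, 3L, 1L),
                                               3L, 1L), 3L, 1L))
  expect_identical(medianDenoise(x, 3L, 0L), x)
  expect_error(medianDenoise(x, 4L), "odd")
})

test_that("range scaling hits [0, 1] exactly and inverts to 1e-12", {
  m <- matrix(c(-3, 1, 0, -1), 2, 2)
  sc <- rangeScale(m)
  expect_equal(sc$params@lo, -3)
  expect_equal(sc$params@hi, 1)
  expect_equal(range(sc$image), c(0, 1))
  expect_lt(max(abs(rangeUnscale(sc$image, sc$params) - m)), 1e-12)

  expect_equal(rangeUnscale(matrix(0, 3, 3), sc$params), matrix(-3, 3, 3))
  expect_equal(rangeUnscale(matrix(1, 3, 3), sc$params), matrix(1, 3, 3))
  expect_error(rangeScale(matrix(5, 4, 4)), "constant|distinct")

  # signed G plane from the simulator scales to exact [0, 1]
  g <- gPlane(noisyMeasurement(twoFluorScene(32L), seed = 3L))
  expect_identical(range(rangeScale(g)$image), c(0, 1))
})

test_that("CNN training learns the identity on zero-noise pairs and is deterministic", {
  set.seed(31)
  smooth <- function() {
    f <- matrix(runif(48 * 48), 48, 48)
    rangeScale(phasorFLIM:::boxSmooth(f, 3L))$image
  }
  planes <- replicate(6, smooth(), simplify = FALSE)
  pairs <- lapply(planes[1:5], function(p) list(input = p, target = p))
  mA <- trainDenoiser(pairs, "supervised", depth = 3L, width = 8L,
                      epochs = 300L, batchSize = 2L, lr = 3e-3,
                      seed = 4L)
  held <- planes[[6]]
  expect_lt(mean(abs(applyDenoiser(held, mA) - held)), 0.01)

  mB <- trainDenoiser(pairs, "supervised", depth = 3L, width = 8L,
                      epochs = 300L, batchSize = 2L, lr = 3e-3,
                      seed = 4L)
  expect_identical(mA@weights[], mB@weights[])
  expect_identical(applyDenoiser(held, mA), applyDenoiser(held, mB))

  expect_error(trainDenoiser(list(), "supervised"), "empty")
  bad <- list(list(input = held * 3, target = held))
  expect_error(trainDenoiser(bad, "supervised"), "scaled")
})

test_that("trained CNN raises PSNR of held-out noisy G planes", {
  model <- trainedCnn()
  scene <- twoFluorScene()
  clean <- computeGS(simulateFdPhases(scene))
  held <- noisyMeasurement(scene, seed = 4242L)   # seed unseen in training

  sCl <- rangeScale(gPlane(held))
  cleanScaled <- (gPlane(clean) - sCl$params@lo) /
    (sCl$params@hi - sCl$params@lo)
  den <- applyDenoiser(sCl$image, model)
  expect_lt(mean((den - cleanScaled)^2),
            mean((sCl$image - cleanScaled)^2))
  expect_gt(psnr(minmax8bit(den), minmax8bit(cleanScaled)),
            psnr(minmax8bit(sCl$image), minmax8bit(cleanScaled)))
})

test_that("applyDenoiser dispatch, shape contract and error guards hold", {
  x <- matrix(runif(20 * 28), 20, 28)
  med <- medianModel(3L, 2L)
  expect_identical(applyDenoiser(x, med), medianDenoise(x, 3L, 2L))

  model <- trainedCnn()
  for (d in list(c(17L, 23L), c(40L, 40L))) {
    y <- applyDenoiser(matrix(runif(prod(d)), d[1], d[2]), model)
    expect_identical(dim(y), d)
  }
  untrained <- new("DenoiserModel", kind = "cnn", cnnDepth = 8L,
                   cnnWidth = 32L, weights = list(), trainSeed = 0L,
                   trainingMode = "supervised")
  expect_error(applyDenoiser(x, untrained), "weights|train")
})

test_that("denoiseGS is the per-plane scale/apply/unscale chain with identity cases", {
  meas <- noisyMeasurement(twoFluorScene(48L), seed = 5L)

  # zero-iteration median model is the identity to 1e-12
  out0 <- denoiseGS(meas, medianModel(3L, 0L))
  expect_lt(max(abs(gPlane(out0) - gPlane(meas))), 1e-12)
  expect_lt(max(abs(sPlane(out0) - sPlane(meas))), 1e-12)
  expect_identical(intensityPlane(out0), intensityPlane(meas))

  # noiseless piecewise-constant measurement is a median fixed point
  sc <- generateScene(24, 24, list(
    list(shape = "rect", corner = c(0, 0), size = c(24, 12), tau = 1,
         amplitude = 1),
    list(shape = "rect", corner = c(0, 12), size = c(24, 12), tau = 3,
         amplitude = 1)))
  cleanMeas <- computeGS(simulateFdPhases(sc))
  outM <- denoiseGS(cleanMeas, medianModel(3L, 3L))
  expect_equal(gPlane(outM), gPlane(cleanMeas), tolerance = 1e-12)
  expect_equal(sPlane(outM), sPlane(cleanMeas), tolerance = 1e-12)
})

test_that("denoising sharpens the phasor histogram at the true positions", {
  scene <- twoFluorScene(128L)
  meas <- noisyMeasurement(scene, seed = 6L)
  den <- denoiseGS(meas, medianModel(3L, 3L))
  thr <- 0.05
  hN <- phasorHistogram(phasorFD(meas, intensityThreshold = thr))
  hD <- phasorHistogram(phasorFD(den, intensityThreshold = thr))
  peakAt <- function(h, tau) {
    p <- as.vector(monoExpPhasor(tau))
    gi <- findInterval(p[1], h@gEdges, rightmost.closed = TRUE)
    si <- findInterval(p[2], h@sEdges, rightmost.closed = TRUE)
    max(h@counts[pmin(pmax(gi + (-1:1), 1), nrow(h@counts)),
                 pmin(pmax(si + (-1:1), 1), ncol(h@counts))])
  }
  expect_gt(peakAt(hD, 1), peakAt(hN, 1))
  expect_gt(peakAt(hD, 3), peakAt(hN, 3))
})
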