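# Image-quality metrics. Following the evaluation protocol for lifetime
# images, PSNR and SSIM are computed after scaling to 8-bit by min-max
# normalization; the pipeline enforces this.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max(Y)^2 / MSE(X, Y))` with the MSE taken over all pixels.
#' The measure is reference-asymmetric: `y` is the reference whose maximum
#' defines the peak. A zero MSE returns `Inf` (identical images are a
#' legitimate comparison).
#'
#' @param x image under test
#' @param y reference image of the same shape
#' @return PSNR in decibels
#' @export
psnr <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(y)^2 / mse)
}

#' Structural similarity index
#'
#' Standard SSIM with an 8x8 sliding box window and stabilizing constants
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`, averaged over all window
#' positions. Inputs are expected on the 8-bit scale (see [minmax8bit()]).
#' Symmetric in its arguments.
#'
#' @param x,y images of one shape, at least 8 x 8
#' @param window box window side (default 8)
#' @return SSIM score (1 = identical)
#' @export
ssim <- function(x, y, window = 8L) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (nrow(x) < window || ncol(x) < window)
    stop("image smaller than the SSIM window")
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  mx <- boxMean(x, window); my <- boxMean(y, window)
  sxx <- boxMean(x * x, window) - mx^2
  syy <- boxMean(y * y, window) - my^2
  sxy <- boxMean(x * y, window) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

# Mean over all w x w windows (valid positions) via integral images.
boxMean <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  ii <- apply(m, 2L, cumsum)              # cumulate down rows
  ii <- t(apply(ii, 1L, cumsum))          # then across columns
  ii <- rbind(0, cbind(0, ii))
  nY <- h - w + 1L; nX <- wd - w + 1L
  i1 <- seq_len(nY); j1 <- seq_len(nX)
  (ii[i1 + w, j1 + w, drop = FALSE] + ii[i1, j1, drop = FALSE] -
   ii[i1 + w, j1, drop = FALSE] - ii[i1, j1 + w, drop = FALSE]) / (w * w)
}

#' Min-max normalization to the 8-bit range
#'
#' Affine map of `[min, max]` onto `[0, 255]`, rounded half-up to integers;
#' a monotone map, so pixel ordering is preserved.
#'
#' @param image numeric matrix with at least two distinct values
#' @return integer-valued matrix in 0..255
#' @export
minmax8bit <- function(image) {
  rng <- range(image)
  if (diff(rng) <= 0) stop("constant image cannot be min-max normalized")
  floor((image - rng[1]) / diff(rng) * 255 + 0.5)
}

#' Fit a sum of Gaussians to a lifetime histogram
#'
#' Least-squares fit of `sum_i A_i exp(-(x - mu_i)^2 / (2 sigma_i^2))` to
#' the binned histogram of valid lifetimes (curve fit to the histogram, not
#' pixel-level EM). Initial means sit at histogram percentiles, making the
#' fit deterministic; `seed` only feeds the jittered restarts attempted if
#' the first fit fails to converge. Components are reported in ascending
#' mean order with area-normalized weights.
#'
#' @param tau a [LifetimeImage-class] or numeric vector of lifetimes (ns)
#' @param nComponents number of Gaussian components
#' @param bins histogram bin count
#' @param seed integer seed for restart jitter
#' @return a [GaussianMixFit-class]
#' @export
fitLifetimeGaussians <- function(tau, nComponents = 2L, bins = 100L,
                                 seed = 0L) {
  vals <- if (is(tau, "LifetimeImage")) tau@tauNs[tau@valid] else tau
  vals <- vals[is.finite(vals)]
  nComponents <- as.integer(nComponents)
  if (length(vals) < 10L * nComponents)
    stop("need at least 10 valid pixels per component")
  hst <- graphics::hist(vals, breaks = bins, plot = FALSE)
  x <- hst$mids; yc <- hst$counts
  qs <- stats::quantile(vals, probs = seq_len(nComponents) /
                          (nComponents + 1L))
  sig0 <- max(stats::sd(vals) / (2 * nComponents), diff(range(x)) / bins)
  fitOnce <- function(mu0) {
    start <- list()
    for (i in seq_len(nComponents)) {
      start[[paste0("A", i)]] <- max(yc)
      start[[paste0("m", i)]] <- unname(mu0[i])
      start[[paste0("s", i)]] <- sig0
    }
    terms <- paste0("A", seq_len(nComponents), " * exp(-(x - m",
                    seq_len(nComponents), ")^2 / (2 * s",
                    seq_len(nComponents), "^2))")
    form <- stats::as.formula(paste("yc ~", paste(terms, collapse = " + ")))
    minpack.lm::nlsLM(form, data = data.frame(x = x, yc = yc),
                      start = start,
                      lower = rep(c(0, min(x), 1e-4), nComponents),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(fitOnce(qs), error = function(e) e)
  if (inherits(fit, "error")) {
    fit <- withSeed(seed, {
      f <- NULL
      for (r in 1:5) {
        mu0 <- sort(stats::runif(nComponents, min(x), max(x)))
        f <- tryCatch(fitOnce(mu0), error = function(e) NULL)
        if (!is.null(f)) break
      }
      f
    })
    if (is.null(fit)) stop("Gaussian fit failed to converge")
  }
  cf <- stats::coef(fit)
  A <- cf[paste0("A", seq_len(nComponents))]
  mu <- cf[paste0("m", seq_len(nComponents))]
  sg <- abs(cf[paste0("s", seq_len(nComponents))])
  area <- A * sg
  wts <- if (sum(area) > 0) area / sum(area) else rep(1 / nComponents,
                                                      nComponents)
  ord <- order(mu)
  pred <- stats::predict(fit)
  r2 <- 1 - sum((yc - pred)^2) / max(sum((yc - mean(yc))^2),
                                     .Machine$double.eps)
  new("GaussianMixFit", nComponents = nComponents,
      meansNs = unname(mu[ord]), sigmasNs = unname(sg[ord]),
      weights = unname(wts[ord]), rSquared = r2)
}
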