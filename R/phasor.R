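# G/S extraction, lifetimes and phasor coordinates.
#
# The complementary mixer-phase differences give the raw measurement planes
#   S = V_IF(0) - V_IF(pi),   G = V_IF(pi/2) - V_IF(3pi/2),
# and the per-pixel lifetime is the scale-free ratio tau = S / (w * G) with
# w = 2 pi f_mod. Phasor coordinates (g, s) = (m cos phi, m sin phi) place
# mono-exponential decays on the universal semicircle of radius 1/2 centred
# at (1/2, 0).

#' Construct a FlimMeasurement from G/S/intensity planes
#'
#' @param g,s signed real/imaginary planes (numeric matrices)
#' @param intensity non-negative brightness plane
#' @param fModHz modulation frequency in Hz
#' @return a [FlimMeasurement-class]
#' @export
flimMeasurement <- function(g, s, intensity = NULL, fModHz = 8.0e7) {
  assertMatrix(g, "g"); assertMatrix(s, "s")
  if (is.null(intensity)) intensity <- matrix(1, nrow(g), ncol(g))
  new("FlimMeasurement", g = g, s = s, intensity = intensity,
      fModHz = fModHz)
}

#' Extract G, S and intensity from a four-phase stack
#'
#' `s = V_IF(0) - V_IF(pi)`, `g = V_IF(pi/2) - V_IF(3pi/2)`; the intensity
#' plane is the mean of the four phase images (the DC estimate). The
#' modulation frequency is carried through.
#'
#' @param phases a [PhaseStack-class]
#' @return a [FlimMeasurement-class]
#' @export
computeGS <- function(phases) {
  stopifnot(is(phases, "PhaseStack"))
  v <- phases@vIf
  s <- v[, , 1L] - v[, , 3L]
  g <- v[, , 2L] - v[, , 4L]
  intensity <- (v[, , 1L] + v[, , 2L] + v[, , 3L] + v[, , 4L]) / 4
  intensity[intensity < 0] <- 0   # read noise can push the DC estimate below 0
  new("FlimMeasurement", g = g, s = s, intensity = intensity,
      fModHz = phases@fModHz)
}

#' Per-pixel lifetime from a FlimMeasurement
#'
#' `tau = s / (w * g)` with `w = 2 pi f_mod`, reported in ns. Pixels with
#' `|g|` below 1e-12 of the plane maximum, or with intensity below
#' `intensityThreshold * max(intensity)`, are marked invalid (NA) rather
#' than raising errors.
#'
#' @param meas a [FlimMeasurement-class]
#' @param intensityThreshold fraction of the maximum intensity below which
#'   pixels are invalidated (default 0)
#' @return a [LifetimeImage-class]
#' @export
lifetimeFromGS <- function(meas, intensityThreshold = 0) {
  stopifnot(is(meas, "FlimMeasurement"))
  w <- omegaOf(meas@fModHz)
  eps <- 1e-12 * max(abs(meas@g))
  valid <- abs(meas@g) > eps &
    meas@intensity >= intensityThreshold * max(meas@intensity)
  tau <- matrix(NA_real_, nrow(meas@g), ncol(meas@g))
  tau[valid] <- meas@s[valid] / (w * meas@g[valid]) * 1e9
  new("LifetimeImage", tauNs = tau, valid = valid)
}

#' Closed-form phasor of a mono-exponential decay
#'
#' `g = 1 / (1 + (w tau)^2)`, `s = w tau / (1 + (w tau)^2)` — the universal
#' semicircle parameterization; tau = 0 maps to (1, 0) and tau -> Inf to
#' (0, 0).
#'
#' @param tauNs lifetime in ns (vectorized, >= 0)
#' @param fModHz modulation frequency in Hz
#' @return matrix with columns g and s
#' @export
monoExpPhasor <- function(tauNs, fModHz = 8.0e7) {
  stopifnot(all(tauNs >= 0))
  wt <- omegaOf(fModHz) * tauNs * 1e-9
  cbind(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

# Build a PhasorCloud from coordinate vectors plus bookkeeping.
makeCloud <- function(gc, sc, m, phi, pixelIndex, negG = NULL) {
  if (is.null(negG)) negG <- rep(FALSE, length(gc))
  new("PhasorCloud", gCoord = as.numeric(gc), sCoord = as.numeric(sc),
      m = as.numeric(m), phi = as.numeric(phi),
      pixelIndex = pixelIndex, negG = negG)
}

# 0-based (z, y, x) index matrix for the TRUE entries of a logical matrix.
pixelIndexOf <- function(validMat, z = 0L) {
  idx <- which(validMat, arr.ind = TRUE)
  cbind(z = rep(as.integer(z), nrow(idx)),
        y = as.integer(idx[, 1L]) - 1L, x = as.integer(idx[, 2L]) - 1L)
}

#' Time-domain phasor transform of TCSPC decays
#'
#' Discrete approximation of the cosine/sine transforms of the decay
#' histogram at `w = 2 pi f_mod`, using the rectangle rule at bin centres
#' (error O(dt^2)). Zero-count pixels are excluded from the cloud.
#'
#' @param decays a [TcspcStack-class]
#' @param fModHz modulation frequency in Hz
#' @return a [PhasorCloud-class]
#' @export
phasorTD <- function(decays, fModHz = 8.0e7) {
  stopifnot(is(decays, "TcspcStack"))
  w <- omegaOf(fModHz) * 1e-9           # rad per ns
  tc <- (seq_len(decays@nBins) - 0.5) * decays@binWidthNs
  cw <- cos(w * tc); sw <- sin(w * tc)
  h <- dim(decays@counts)[1L]; wd <- dim(decays@counts)[2L]
  flat <- matrix(decays@counts, h * wd, decays@nBins)
  tot <- rowSums(flat)
  if (all(tot == 0)) stop("all-zero decay stack")
  keep <- tot > 0
  gc <- (flat %*% cw)[keep] / tot[keep]
  sc <- (flat %*% sw)[keep] / tot[keep]
  keepMat <- matrix(keep, h, wd)
  makeCloud(gc, sc, m = sqrt(gc^2 + sc^2), phi = atan2(sc, gc),
            pixelIndex = pixelIndexOf(keepMat))
}

#' Frequency-domain phasor extraction from a FlimMeasurement
#'
#' Per valid pixel the raw phase is `phi = atan2(s, g)`. Absolute phasor
#' placement requires a calibration constant the raw homodyne G/S do not
#' carry (they are scaled by an unknown per-pixel amplitude), so two modes
#' are provided:
#' \describe{
#'   \item{uncalibrated (default)}{the modulation degree is taken from the
#'     phase as `m = cos(phi)`, which places every mono-exponential pixel
#'     exactly on the universal semicircle (phase-only projection; phase
#'     information, and hence `tau = tan(phi)/w`, is preserved bit-for-bit).}
#'   \item{calibrated}{a reference measurement of a fluorophore of known
#'     lifetime `tauRefNs` supplies a complex correction factor mapping the
#'     mean reference phasor onto its theoretical semicircle position; the
#'     factor is applied to all pixels.}
#' }
#' Pixels whose raw G is negative (noise can push points left of the
#' semicircle) are retained but flagged in the cloud.
#'
#' @param meas a [FlimMeasurement-class]
#' @param calibration optional `list(reference = FlimMeasurement,
#'   tauRefNs = numeric)`
#' @param intensityThreshold fraction of max intensity below which pixels
#'   are excluded from the cloud
#' @return a [PhasorCloud-class]
#' @export
phasorFD <- function(meas, calibration = NULL, intensityThreshold = 0) {
  stopifnot(is(meas, "FlimMeasurement"))
  valid <- meas@intensity >= intensityThreshold * max(meas@intensity)
  valid <- valid & !(meas@g == 0 & meas@s == 0)
  gv <- meas@g[valid]; sv <- meas@s[valid]
  if (!is.null(calibration)) {
    ref <- calibration$reference
    stopifnot(is(ref, "FlimMeasurement"), is.numeric(calibration$tauRefNs))
    zRef <- complex(real = mean(ref@g), imaginary = mean(ref@s))
    if (Mod(zRef) == 0) stop("calibration reference has zero modulation")
    target <- monoExpPhasor(calibration$tauRefNs, meas@fModHz)
    corr <- complex(real = target[1, "g"], imaginary = target[1, "s"]) / zRef
    z <- complex(real = gv, imaginary = sv) * corr
    gc <- Re(z); sc <- Im(z)
    m <- Mod(z); phi <- Arg(z)
  } else {
    phi <- atan2(sv, gv)
    m <- cos(phi)               # semicircle projection; signed when G < 0
    gc <- m * cos(phi); sc <- m * sin(phi)
  }
  makeCloud(gc, sc, m, phi, pixelIndexOf(valid), negG = gv < 0)
}

#' Bin a phasor cloud into a 2-D histogram
#'
#' The default window `[0, 1] x [0, 0.6]` covers the universal semicircle.
#' Entries outside the window are excluded from the grid and tallied in the
#' `clipped` count, so `sum(counts) + clipped` equals the cloud size.
#'
#' @param cloud a non-empty [PhasorCloud-class]
#' @param nBins number of bins per axis (>= 2)
#' @param gLim,sLim axis limits
#' @return a [PhasorHistogram-class]
#' @export
phasorHistogram <- function(cloud, nBins = 128L, gLim = c(0, 1),
                            sLim = c(0, 0.6)) {
  stopifnot(is(cloud, "PhasorCloud"))
  if (length(cloud@gCoord) == 0L) stop("empty phasor cloud")
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  gE <- seq(gLim[1], gLim[2], length.out = nBins + 1L)
  sE <- seq(sLim[1], sLim[2], length.out = nBins + 1L)
  inWin <- cloud@gCoord >= gLim[1] & cloud@gCoord <= gLim[2] &
           cloud@sCoord >= sLim[1] & cloud@sCoord <= sLim[2]
  gi <- pmin(findInterval(cloud@gCoord[inWin], gE, rightmost.closed = TRUE),
             nBins)
  si <- pmin(findInterval(cloud@sCoord[inWin], sE, rightmost.closed = TRUE),
             nBins)
  counts <- matrix(0, nBins, nBins)
  tab <- table(factor(gi, levels = seq_len(nBins)),
               factor(si, levels = seq_len(nBins)))
  counts[] <- as.numeric(tab)
  new("PhasorHistogram", counts = counts, gEdges = gE, sEdges = sE,
      clipped = as.integer(sum(!inWin)))
}

#' Export a phasor cloud as a delimited table
#'
#' @param cloud a [PhasorCloud-class]
#' @param path optional output path; when given, a tab-separated file with
#'   columns g, s, z, y, x is written
#' @return data.frame of the table (invisibly when written to file)
#' @export
cloudAsTable <- function(cloud, path = NULL) {
  df <- data.frame(g = cloud@gCoord, s = cloud@sCoord,
                   z = cloud@pixelIndex[, 1L], y = cloud@pixelIndex[, 2L],
                   x = cloud@pixelIndex[, 3L])
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(df))
  }
  df
}
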