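# Composite HSV lifetime rendering: pixel brightness (value) encodes
# intensity, hue encodes lifetime from blue (short) to red (long) across a
# configurable display range.

#' Composite HSV lifetime render
#'
#' Value channel = min-max normalized intensity; hue = lifetime clipped to
#' `tauRangeNs` and mapped linearly from blue (`tau_min`) to red
#' (`tau_max`); saturation = 1 at valid pixels. Invalid pixels render
#' black, as do zero-intensity pixels.
#'
#' @param intensity numeric intensity matrix
#' @param tau a [LifetimeImage-class] of the same shape
#' @param tauRangeNs (min, max) lifetime range in ns mapped to hue
#' @return a [CompositeImage-class]
#' @export
compositeHSV <- function(intensity, tau, tauRangeNs = c(0, 3)) {
  stopifnot(is(tau, "LifetimeImage"),
            identical(dim(intensity), dim(tau@tauNs)))
  if (diff(tauRangeNs) <= 0) stop("degenerate lifetime display range")
  rng <- range(intensity)
  # constant positive intensity renders at full brightness, not black
  val <- if (diff(rng) > 0) (intensity - rng[1]) / diff(rng)
         else (intensity > 0) * 1.0
  tcl <- clipRange(tau@tauNs, tauRangeNs[1], tauRangeNs[2])
  frac <- (tcl - tauRangeNs[1]) / diff(tauRangeNs)
  hue <- (2 / 3) * (1 - frac)        # 2/3 = blue, 0 = red
  h <- nrow(intensity); w <- ncol(intensity)
  out <- array(0, c(h, w, 3L))
  ok <- tau@valid & val > 0
  if (any(ok)) {
    cols <- grDevices::hsv(hue[ok], s = 1, v = val[ok])
    rgbv <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[ok] <- rgbv[ch, ]
      out[, , ch] <- plane
    }
  }
  new("CompositeImage", rgb = out, tauRangeNs = as.numeric(tauRangeNs),
      hueConvention = "blue (tau_min) -> red (tau_max)")
}

#' Write an RGB array or CompositeImage as PNG
#'
#' @param x a [CompositeImage-class] or numeric (Y, X, 3) array in [0, 1]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeRenderPNG <- function(x, path) {
  arr <- if (is(x, "CompositeImage")) x@rgb else x
  png::writePNG(arr, path)
  invisible(path)
}
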