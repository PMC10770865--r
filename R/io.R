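# Stack and configuration I/O. Measured data travel as grayscale TIFF
# (uint8/uint16/float32 on read; float32 on write); run configuration is a
# flat YAML key-value file with hard errors on unknown keys.

#' Construct an ImageStack from a pixel array
#'
#' @param pixels numeric matrix (Y, X) or 3-D array (Z, Y, X)
#' @param pixelSizeUm optional physical pixel width in micrometres
#' @param planeDepthUm optional Z step in micrometres
#' @return an [ImageStack-class]
#' @export
imageStack <- function(pixels, pixelSizeUm = NA_real_, planeDepthUm = NA_real_) {
  if (is.matrix(pixels)) {
    axes <- c("Y", "X")
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    axes <- c("Z", "Y", "X")
  } else stop("pixels must be a 2-D matrix or a 3-D array")
  new("ImageStack", pixels = pixels * 1.0, axes = axes,
      pixelSizeUm = pixelSizeUm, planeDepthUm = planeDepthUm)
}

#' Read a single- or multi-page TIFF into an ImageStack
#'
#' Pages become Z planes in (Z, Y, X) order; a single page yields a 2-D
#' (Y, X) stack. Sample values are preserved exactly for lossless
#' (integer or float32) inputs.
#'
#' @param path path to a grayscale TIFF file
#' @param asIs logical; keep integer samples at their stored scale instead
#'   of the [0, 1] convention (default TRUE)
#' @return an [ImageStack-class]
#' @export
readStack <- function(path, asIs = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = asIs),
    error = function(e) {
      # float32 pages reject as.is; re-read at their native scale
      if (grepl("as.is", conditionMessage(e), fixed = TRUE))
        return(tiff::readTIFF(path, all = TRUE, as.is = FALSE))
      stop("not a readable TIFF: ", path, " (",
           conditionMessage(e), ")", call. = FALSE)
    })
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] > 1L)
        stop("only grayscale TIFF stacks are supported")
      p <- p[, , 1L]
    }
    p
  })
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("TIFF pages have inconsistent shapes")
  if (length(pages) == 1L) return(imageStack(pages[[1L]]))
  vol <- aperm(simplify2array(pages), c(3L, 1L, 2L))  # (Z, Y, X)
  imageStack(vol)
}

#' Write an ImageStack as a 32-bit float multi-page TIFF
#'
#' One page per Z plane. Samples are stored as IEEE float32, which preserves
#' signed values (valid for G/S difference planes); doubles beyond float32
#' precision are rounded. `readStack` inverts the operation.
#'
#' @param stack an [ImageStack-class] or a numeric matrix / 3-D array
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeStack <- function(stack, path) {
  if (is(stack, "ImageStack")) px <- stack@pixels else px <- stack
  planes <- if (is.matrix(px)) list(px)
            else lapply(seq_len(dim(px)[1L]), function(z) px[z, , ])
  writeFloatTiff(planes, path)
  invisible(path)
}

# Minimal uncompressed little-endian float32 grayscale multi-page TIFF
# writer. (The CRAN tiff package clamps float samples into [0, 1] on write,
# which would destroy signed difference planes; reading is still done
# through tiff::readTIFF, which handles arbitrary float values.)
writeFloatTiff <- function(planes, path) {
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  nP <- length(planes)
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  dataBytes <- 4L * h * w
  ifdBytes <- 2L + 10L * 12L + 4L
  # layout: 8-byte header, then per page [pixel strip][IFD]
  stripOff <- integer(nP); ifdOff <- integer(nP)
  pos <- 8L
  for (i in seq_len(nP)) {
    stripOff[i] <- pos; pos <- pos + dataBytes
    ifdOff[i] <- pos;   pos <- pos + ifdBytes
  }
  writeBin(charToRaw("II"), con); u16(42L); u32(ifdOff[1L])
  tag <- function(id, type, count, value) {
    u16(id); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  for (i in seq_len(nP)) {
    writeBin(as.numeric(t(planes[[i]])), con, size = 4L, endian = "little")
    u16(10L)                      # entry count
    tag(256L, 4L, 1L, w)          # ImageWidth
    tag(257L, 4L, 1L, h)          # ImageLength
    tag(258L, 3L, 1L, 32L)        # BitsPerSample
    tag(259L, 3L, 1L, 1L)         # Compression: none
    tag(262L, 3L, 1L, 1L)         # Photometric: BlackIsZero
    tag(273L, 4L, 1L, stripOff[i])# StripOffsets
    tag(277L, 3L, 1L, 1L)         # SamplesPerPixel
    tag(278L, 4L, 1L, h)          # RowsPerStrip
    tag(279L, 4L, 1L, dataBytes)  # StripByteCounts
    tag(339L, 3L, 1L, 3L)         # SampleFormat: IEEE float
    u32(if (i < nP) ifdOff[i + 1L] else 0L)
  }
  invisible(path)
}

# --------------------------------------------------------------------------
# Run configuration
# --------------------------------------------------------------------------

configDefaults <- function() list(
  f_mod_hz = 8.0e7,
  denoiser = "median",
  median_iterations = 3L,
  kmeans_k = 2L,
  seed = 0L,
  tau_display_range_ns = c(0, 3),
  intensity_threshold = 0.05
)

#' Construct a RunConfig
#'
#' @param f_mod_hz modulation frequency in Hz (default 80 MHz)
#' @param denoiser one of "median", "cnn", "none"
#' @param median_iterations median-filter pass count (default 3)
#' @param kmeans_k phasor cluster count
#' @param seed integer seed
#' @param tau_display_range_ns (min, max) lifetime range for hue mapping (ns)
#' @param intensity_threshold fraction of max intensity below which pixels
#'   are excluded from phasor extraction and segmentation
#' @return a [RunConfig-class]
#' @export
flimConfig <- function(f_mod_hz = 8.0e7, denoiser = "median",
                       median_iterations = 3L, kmeans_k = 2L, seed = 0L,
                       tau_display_range_ns = c(0, 3),
                       intensity_threshold = 0.05) {
  new("RunConfig", fModHz = as.numeric(f_mod_hz),
      denoiser = as.character(denoiser),
      medianIterations = as.integer(median_iterations),
      kmeansK = as.integer(kmeans_k), seed = as.integer(seed),
      tauDisplayRangeNs = as.numeric(tau_display_range_ns),
      intensityThreshold = as.numeric(intensity_threshold))
}

#' Load a RunConfig from a flat YAML file
#'
#' Unspecified keys fall back to documented defaults (80 MHz modulation,
#' three median iterations, seed 0); unknown keys are hard errors so that
#' typos in denoiser settings cannot silently corrupt comparisons.
#'
#' @param path path to a YAML configuration file
#' @return a [RunConfig-class]
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  defs <- configDefaults()
  unknown <- setdiff(names(vals), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defs, vals)
  do.call(flimConfig, merged)
}
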