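# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# RNG stream. All seeded operations in the package go through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Round a numeric vector/array to IEEE float32 precision (the TIFF sample
# format used on disk).
quantizeFloat32 <- function(x) {
  d <- dim(x)
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  dim(q) <- d
  q
}

# Angular modulation frequency (rad/s) of a measurement or raw Hz value.
omegaOf <- function(fModHz) 2 * pi * fModHz

assertMatrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  invisible(x)
}

# Clip values into [lo, hi].
clipRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)
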