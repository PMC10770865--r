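# Unsupervised segmentation of the phasor cloud: Lloyd's K-means with
# k-means++ seeding, restarts and canonical relabelling, plus back-mapping
# of cluster ids to image pixels. The algorithm is implemented here (rather
# than delegated) because reproducibility requires control over
# initialization, restart selection and per-iteration inertia monotonicity;
# stats::kmeans serves as an independent cross-check in the test suite.

kppInit <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(0, k, 2L)
  centers[1L, ] <- pts[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((pts - matrix(centers[1L, ], n, 2L, byrow = TRUE))^2)
    for (j in 2L:k) {
      if (sum(d2) == 0) {
        centers[j, ] <- pts[sample.int(n, 1L), ]
      } else {
        pick <- sample.int(n, 1L, prob = d2)
        centers[j, ] <- pts[pick, ]
      }
      d2 <- pmin(d2, rowSums((pts - matrix(centers[j, ], n, 2L,
                                           byrow = TRUE))^2))
    }
  }
  centers
}

# Squared distances of points to each center: n x k matrix.
dist2 <- function(pts, centers) {
  cross <- pts %*% t(centers)
  pn <- rowSums(pts^2); cn <- rowSums(centers^2)
  pmax(outer(pn, cn, "+") - 2 * cross, 0)
}

lloyd <- function(pts, centers, maxIter) {
  k <- nrow(centers)
  prevInertia <- Inf
  labels <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- dist2(pts, centers)
    labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(pts)), labels)])
    # Lloyd monotonicity invariant, asserted on every run
    stopifnot(inertia <= prevInertia + 1e-9 * max(1, prevInertia))
    if (prevInertia - inertia <= 1e-12 * max(1, prevInertia) && it > 1L)
      break
    prevInertia <- inertia
    for (j in seq_len(k)) {
      sel <- labels == j
      if (any(sel)) {
        centers[j, ] <- colMeans(pts[sel, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the point farthest from its center
        far <- which.max(d2[cbind(seq_len(nrow(pts)), labels)])
        centers[j, ] <- pts[far, ]
      }
    }
  }
  d2 <- dist2(pts, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(pts)), labels)])
  list(centers = centers, labels = labels, inertia = inertia)
}

#' K-means clustering of a phasor cloud
#'
#' Lloyd's algorithm on the (g, s) coordinates with k-means++ seeding, the
#' best of `nInit` restarts by inertia. Cluster ids are renumbered by
#' ascending centroid g (ties by ascending s) so the labelling is
#' independent of restart order; deterministic given `seed`.
#'
#' @param cloud a [PhasorCloud-class] with at least `k` entries
#' @param k number of clusters (>= 1)
#' @param seed integer RNG seed
#' @param nInit number of restarts (default 10)
#' @param maxIter iteration cap per restart (default 300)
#' @return a [Segmentation-class]
#' @export
kmeansPhasor <- function(cloud, k, seed = 0L, nInit = 10L, maxIter = 300L) {
  stopifnot(is(cloud, "PhasorCloud"))
  k <- as.integer(k)
  pts <- cbind(cloud@gCoord, cloud@sCoord)
  if (k < 1L) stop("k must be >= 1")
  if (nrow(pts) < k) stop("cloud smaller than k")
  best <- withSeed(seed, {
    b <- NULL
    for (r in seq_len(nInit)) {
      fit <- lloyd(pts, kppInit(pts, k), maxIter)
      if (is.null(b) || fit$inertia < b$inertia) b <- fit
    }
    b
  })
  ord <- order(best$centers[, 1L], best$centers[, 2L])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  new("Segmentation", k = k,
      centroids = best$centers[ord, , drop = FALSE],
      labels = relabel[best$labels], inertia = best$inertia,
      seed = as.integer(seed))
}

#' Map cluster labels back onto the image grid
#'
#' Inverts the cloud's pixel bookkeeping: valid pixels receive their
#' cluster id, everything else (masked/background pixels) is 0.
#'
#' @param seg a [Segmentation-class]
#' @param cloud the [PhasorCloud-class] the segmentation was computed on
#' @param shape (height, width) of the target image
#' @return integer label matrix
#' @export
labelsToImage <- function(seg, cloud, shape) {
  stopifnot(is(seg, "Segmentation"), is(cloud, "PhasorCloud"))
  h <- shape[1L]; w <- shape[2L]
  yx <- cloud@pixelIndex[, c("y", "x"), drop = FALSE]
  if (nrow(yx) && (max(yx[, 1L]) >= h || max(yx[, 2L]) >= w))
    stop("cloud pixel indices exceed the requested shape")
  img <- matrix(0L, h, w)
  img[cbind(yx[, 1L] + 1L, yx[, 2L] + 1L)] <- seg@labels
  img
}

#' Render cluster labels over an intensity image
#'
#' Each cluster's palette colour is modulated by the min-max normalized
#' intensity; label 0 (background/invalid) renders black.
#'
#' @param labelImage integer matrix of cluster ids (0 = background)
#' @param baseIntensity numeric intensity matrix of the same shape
#' @param palette vector of colours, at least `max(labelImage)` long
#' @return numeric (Y, X, 3) RGB array in [0, 1]
#' @export
overlaySegments <- function(labelImage, baseIntensity,
                            palette = c("red", "blue", "green", "magenta",
                                        "cyan", "yellow")) {
  stopifnot(identical(dim(labelImage), dim(baseIntensity)))
  mx <- max(labelImage)
  if (mx > length(palette)) stop("palette too short for label range")
  rng <- range(baseIntensity)
  # constant positive intensity renders at full brightness, not black
  norm <- if (diff(rng) > 0) (baseIntensity - rng[1]) / diff(rng)
          else (baseIntensity > 0) * 1.0
  rgbCols <- grDevices::col2rgb(palette) / 255
  out <- array(0, c(dim(labelImage), 3L))
  for (lab in seq_len(mx)) {
    sel <- labelImage == lab
    if (!any(sel)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- rgbCols[ch, lab] * norm[sel]
      out[, , ch] <- plane
    }
  }
  out
}

#' Permutation-matched segmentation accuracy
#'
#' Best fraction, over all assignments of predicted cluster ids to truth
#' labels, of valid (truth > 0) pixels whose id matches the truth. Label
#' permutation invariance makes the measure independent of cluster
#' numbering.
#'
#' @param segLabels integer matrix of predicted labels
#' @param truthLabels integer matrix of true labels (0 = ignore)
#' @return fraction in [0, 1]
#' @export
segmentationAccuracy <- function(segLabels, truthLabels) {
  stopifnot(identical(dim(segLabels), dim(truthLabels)))
  sel <- truthLabels > 0L
  if (!any(sel)) stop("truth has no valid pixels")
  pred <- segLabels[sel]; truth <- truthLabels[sel]
  predIds <- sort(unique(pred)); truthIds <- sort(unique(truth))
  if (length(predIds) > 7L)
    stop("permutation matching supports at most 7 predicted labels")
  # contingency table, then best one-to-one assignment over permutations
  tab <- table(factor(pred, levels = predIds),
               factor(truth, levels = truthIds))
  nP <- length(predIds); nT <- length(truthIds)
  sz <- max(nP, nT)
  m <- matrix(0, sz, sz)
  m[seq_len(nP), seq_len(nT)] <- tab
  perms <- allPerms(sz)
  bestHits <- 0
  for (i in seq_len(nrow(perms)))
    bestHits <- max(bestHits, sum(m[cbind(seq_len(sz), perms[i, ])]))
  bestHits / length(truth)
}

allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) for (i in seq_len(nrow(sub))) {
    r <- r + 1L
    out[r, ] <- c(k, setdiff(seq_len(n), k)[sub[i, ]])
  }
  out
}

#' Cluster-count diagnostics for a phasor cloud
#'
#' Optional report of inertia (elbow curve) and mean silhouette width over
#' a range of K; it never changes the K the user requested.
#'
#' @param cloud a [PhasorCloud-class]
#' @param kRange integer vector of candidate cluster counts
#' @param seed integer RNG seed
#' @param maxPoints subsample cap for the silhouette computation
#' @return data.frame with columns k, inertia, silhouette
#' @export
clusterCountReport <- function(cloud, kRange = 2:6, seed = 0L,
                               maxPoints = 2000L) {
  pts <- cbind(cloud@gCoord, cloud@sCoord)
  sub <- withSeed(seed, {
    if (nrow(pts) > maxPoints) pts[sample.int(nrow(pts), maxPoints), ]
    else pts
  })
  rows <- lapply(kRange, function(k) {
    seg <- kmeansPhasor(cloud, k, seed = seed)
    d2 <- dist2(sub, seg@centroids)
    lab <- max.col(-d2, ties.method = "first")
    sil <- meanSilhouette(sub, lab, k)
    data.frame(k = k, inertia = seg@inertia, silhouette = sil)
  })
  do.call(rbind, rows)
}

meanSilhouette <- function(pts, lab, k) {
  if (k < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(pts))
  n <- nrow(pts)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(seq_len(k), lab[i]), function(j) {
      sel <- lab == j
      if (any(sel)) mean(d[i, sel]) else Inf
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
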