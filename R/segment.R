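## Four parallel plaque segmentation methods, the active-contour reference
## tracer, the Dice score and connected-component labelling.

#' Otsu threshold segmentation
#'
#' Finds the histogram split maximizing the between-class variance of the
#' two induced intensity classes and returns the pixels strictly above the
#' threshold as plaque foreground. Intensities are binned over the image's
#' own min-max range.
#'
#' @param img intensity matrix with at least two distinct values.
#' @param nBins number of histogram bins (default 256).
#' @return list with `threshold` (intensity units) and `mask` (logical
#'   matrix).
#' @export
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' o <- otsuSegment(img)
#' sum(o$mask) # the 50 bright pixels
otsuSegment <- function(img, nBins = 256L) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  if (rng[1] == rng[2])
    stop("constant image: no threshold exists")
  nBins <- as.integer(nBins)
  b <- pmin(floor((img - rng[1]) / (rng[2] - rng[1]) * nBins), nBins - 1L)
  counts <- tabulate(as.vector(b) + 1L, nBins)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nBins) - 1))
  muT <- mu[nBins]
  t <- seq_len(nBins - 1L)
  sigmaB <- (muT * omega[t] - mu[t])^2 / (omega[t] * (1 - omega[t]))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  tbest <- which.max(sigmaB)
  thr <- rng[1] + tbest * (rng[2] - rng[1]) / nBins
  list(threshold = thr, mask = img > thr)
}

#' Independent foam-cell thresholding (IFCT)
#'
#' Segments each candidate foam-cell cluster independently: a permissive
#' global seed threshold at `candidateQuantile` proposes candidate
#' components; for each candidate's bounding region a local Otsu threshold
#' re-segments that region on its own; the per-region masks are unioned and
#' components smaller than `minArea` discarded.
#'
#' A candidate region whose bounding box shows no genuine
#' foreground/background contrast (Otsu separability below
#' `minSeparability`) is discarded, so pure-noise images yield an empty
#' mask.
#'
#' @param img intensity matrix.
#' @param candidateQuantile seed-threshold quantile in (0, 1), default
#'   0.75.
#' @param minArea minimum component size in pixels, default 10.
#' @param minSeparability Otsu-effectiveness floor for a candidate's
#'   bounding region (default 0.8).
#' @return logical mask (possibly empty).
#' @export
ifctSegment <- function(img, candidateQuantile = 0.75, minArea = 10L,
                        minSeparability = 0.8) {
  stopifnot(is.matrix(img),
            candidateQuantile > 0, candidateQuantile < 1)
  seedThr <- quantile(img, candidateQuantile, names = FALSE)
  seedMask <- img > seedThr
  out <- matrix(FALSE, nrow(img), ncol(img))
  if (!any(seedMask)) return(out)
  lab <- labelComponents(seedMask, connectivity = 8L)
  for (k in seq_len(lab$n)) {
    px <- which(lab$labels == k, arr.ind = TRUE)
    r <- range(px[, 1]); c <- range(px[, 2])
    sub <- img[r[1]:r[2], c[1]:c[2], drop = FALSE]
    if (length(unique(as.vector(sub))) < 2L) {
      # saturated or flat candidate: keep the seed component itself
      out[lab$labels == k] <- TRUE
    } else if (otsuSeparability(sub) >= minSeparability) {
      loc <- otsuSegment(sub)
      out[r[1]:r[2], c[1]:c[2]] <- out[r[1]:r[2], c[1]:c[2]] | loc$mask
    }
  }
  removeSmallComponents(out, minArea)
}

#' Marker-controlled watershed segmentation (MCW)
#'
#' Watershed of the gradient magnitude, flooded from foreground markers at
#' regional maxima of the Gaussian-smoothed image (sigma 2 px, maxima
#' separated by at least `markerMinDistance`) and from a background marker
#' covering all pixels below the image's global Otsu threshold. The output
#' is the union of the non-background catchment basins, with one-pixel
#' watershed lines kept between distinct foreground basins and components
#' below `minArea` removed.
#'
#' @param img intensity matrix.
#' @param markerMinDistance minimum separation between foreground markers,
#'   pixels (default 13).
#' @param minArea minimum component size in pixels (default 10).
#' @return logical mask; a constant image yields an empty mask.
#' @export
mcwSegment <- function(img, markerMinDistance = 13L, minArea = 10L) {
  stopifnot(is.matrix(img))
  empty <- matrix(FALSE, nrow(img), ncol(img))
  if (diff(range(img)) == 0) return(empty)
  thr <- otsuSegment(img)$threshold
  sm <- as.matrix(EBImage::gblur(img, sigma = 2))
  side <- 2L * (as.integer(markerMinDistance) %/% 2L) + 1L
  brush <- EBImage::makeBrush(max(side, 3L), shape = "disc")
  mx <- (sm == as.matrix(EBImage::dilate(sm, brush))) & (img > thr)
  if (!any(mx)) return(empty)
  mxl <- labelComponents(mx, 8L)$labels
  seeds <- matrix(0L, nrow(img), ncol(img))
  seeds[img < thr] <- 1L
  seeds[mxl > 0] <- mxl[mxl > 0] + 1L
  if (all(seeds > 0)) return(removeSmallComponents(mx, minArea))
  basins <- cpp_flood_watershed(gradientMagnitude(sm), seeds)
  mask <- basins > 1L
  # 1-px watershed line where two distinct foreground basins touch
  # (including diagonal contact, so basins stay 8-separated)
  line <- matrix(FALSE, nrow(img), ncol(img))
  b <- basins
  nr <- nrow(b); nc <- ncol(b)
  cut2 <- function(ai, aj, bi, bj) {
    da <- b[ai, aj]; db <- b[bi, bj]
    line[ai, aj] <<- line[ai, aj] | (da > 1 & db > 1 & da != db)
  }
  cut2(1:(nr - 1), 1:nc, 2:nr, 1:nc)
  cut2(1:nr, 1:(nc - 1), 1:nr, 2:nc)
  cut2(1:(nr - 1), 1:(nc - 1), 2:nr, 2:nc)
  cut2(2:nr, 1:(nc - 1), 1:(nr - 1), 2:nc)
  removeSmallComponents(mask & !line, minArea)
}

#' Gabor-textured k-means segmentation (KMS)
#'
#' Clusters pixels by k-means on a texture feature vector: the Gaussian
#' smoothed magnitude responses of a Gabor filter bank (all frequency by
#' orientation pairs) plus the pixel intensity. Channels are standardized;
#' the intensity channel is weighted to carry the same total energy as the
#' Gabor bank. Clusters whose mean image intensity exceeds the overall mean
#' are reported as plaque.
#'
#' @param img intensity matrix.
#' @param frequencies Gabor frequencies in cycles/pixel.
#' @param orientations Gabor orientations in degrees.
#' @param k number of clusters (default 2). With `k = 1` the single cluster
#'   mean equals the overall mean, so the mask is degenerate all-false.
#' @param smoothSigma Gaussian sigma for smoothing the Gabor magnitudes.
#' @param seed integer seed making the k-means initialization reproducible.
#' @return logical mask.
#' @export
kmsSegment <- function(img, frequencies = c(0.05, 0.1, 0.2),
                       orientations = c(0, 45, 90, 135), k = 2L,
                       smoothSigma = 3, seed = 1L) {
  stopifnot(is.matrix(img), k >= 1L,
            length(frequencies) > 0, length(orientations) > 0)
  chans <- vector("list", length(frequencies) * length(orientations))
  # kernels may not exceed the image extent
  maxR <- (min(dim(img)) - 1L) %/% 2L
  i <- 0L
  for (f in frequencies) {
    for (a in orientations) {
      kern <- gaborKernel(f, a, maxRadius = maxR)
      mag <- sqrt(as.matrix(EBImage::filter2(img, kern$re))^2 +
                  as.matrix(EBImage::filter2(img, kern$im))^2)
      i <- i + 1L
      chans[[i]] <- as.vector(as.matrix(EBImage::gblur(mag, smoothSigma)))
    }
  }
  X <- scale(do.call(cbind, chans))
  X[is.nan(X)] <- 0
  iv <- as.vector(scale(as.vector(img)))
  iv[is.nan(iv)] <- 0
  X <- cbind(X, iv * sqrt(ncol(X)))
  km <- withr::with_seed(as.integer(seed),
                         kmeans(X, centers = k, nstart = 1, iter.max = 50))
  clustMean <- tapply(as.vector(img), km$cluster, mean)
  plaque <- as.integer(names(clustMean))[clustMean > mean(img)]
  matrix(km$cluster %in% plaque, nrow(img), ncol(img))
}

#' Active-contour reference tracing
#'
#' Region-based (Chan-Vese energy) evolution of an initial mask: at each
#' iteration the mean intensities inside and outside the current contour
#' are computed and pixels in a one-pixel band around the boundary flip to
#' the region whose mean is closer. Used to derive reference masks when no
#' manual ground truth exists.
#'
#' @param img intensity matrix.
#' @param initMask non-empty logical matrix initializing the contour.
#' @param nIter number of evolution iterations; 0 returns `initMask`.
#' @return evolved logical mask.
#' @export
traceReference <- function(img, initMask, nIter = 50L) {
  stopifnot(is.matrix(img), is.logical(initMask),
            identical(dim(img), dim(initMask)))
  if (!any(initMask)) stop("initMask must be non-empty")
  mask <- initMask
  box <- matrix(1, 3, 3)
  for (it in seq_len(nIter)) {
    inside <- img[mask]
    outside <- img[!mask]
    if (length(outside) == 0) break
    c1 <- mean(inside); c2 <- mean(outside)
    dil <- as.matrix(EBImage::dilate(mask * 1, box)) > 0
    ero <- as.matrix(EBImage::erode(mask * 1, box)) > 0
    band <- xor(dil, ero)
    toIn <- (img - c1)^2 < (img - c2)^2
    newMask <- mask
    newMask[band] <- toIn[band]
    if (identical(newMask, mask)) break
    mask <- newMask
    if (!any(mask)) break
  }
  mask
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks of identical
#' dimensions. Two empty masks score 1 by convention (agreement on
#' absence).
#'
#' @param a,b logical matrices of equal dimensions.
#' @return Dice score in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' dice(m, m)
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical dimensions")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Connected-component labelling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, standard for blob-like
#'   microscopy objects).
#' @return list with `labels` (integer matrix, 0 = background, components
#'   numbered 1..n) and `n` (component count).
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  cpp_label_components(mask, connectivity)
}

#' Dispatch on a segmentation method name
#'
#' @param img intensity matrix (already preprocessed).
#' @param method one of "ots", "ifct", "mcw", "kms".
#' @param seed seed for the stochastic method (kms only).
#' @param ... further arguments passed to the method.
#' @return logical mask.
#' @export
segmentImage <- function(img, method = c("ots", "ifct", "mcw", "kms"),
                         seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
         ots = otsuSegment(img, ...)$mask,
         ifct = ifctSegment(img, ...),
         mcw = mcwSegment(img, ...),
         kms = kmsSegment(img, seed = seed, ...))
}

#' Otsu separability (effectiveness) of an image
#'
#' Ratio of the between-class variance at the Otsu threshold to the total
#' intensity variance, in `[0, 1]`. Near 1 for images with genuine
#' foreground/background structure; unimodal noise scores much lower. Used
#' to recognise plaque-free images.
#'
#' @param img intensity matrix.
#' @return separability score; 0 for a constant image.
#' @export
otsuSeparability <- function(img) {
  if (diff(range(img)) == 0) return(0)
  thr <- otsuSegment(img)$threshold
  v <- as.numeric(img)
  b <- v > thr
  if (!any(b) || all(b)) return(0)
  w1 <- mean(b)
  sb <- (1 - w1) * w1 * (mean(v[b]) - mean(v[!b]))^2
  tot <- mean((v - mean(v))^2)
  sb / tot
}

## internal helpers -----------------------------------------------------------

removeSmallComponents <- function(mask, minArea) {
  if (!any(mask) || minArea <= 1) return(mask)
  lab <- labelComponents(mask, 8L)
  sz <- tabulate(lab$labels[lab$labels > 0], lab$n)
  keep <- which(sz >= minArea)
  matrix(lab$labels %in% keep, nrow(mask), ncol(mask))
}

gradientMagnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(img, kx))
  gy <- as.matrix(EBImage::filter2(img, t(kx)))
  sqrt(gx^2 + gy^2)
}

# complex Gabor kernel (real and imaginary parts); sigma set for a one
# octave bandwidth, circular envelope
gaborKernel <- function(freq, thetaDeg, gamma = 1, maxRadius = Inf) {
  sg <- 0.56 / freq
  r <- min(ceiling(3 * sg), maxRadius)
  xs <- -r:r
  X <- outer(rep(1, length(xs)), xs)
  Y <- outer(xs, rep(1, length(xs)))
  th <- thetaDeg * pi / 180
  xp <- X * cos(th) + Y * sin(th)
  yp <- -X * sin(th) + Y * cos(th)
  env <- exp(-(xp^2 + (gamma * yp)^2) / (2 * sg^2))
  list(re = env * cos(2 * pi * freq * xp),
       im = env * sin(2 * pi * freq * xp))
}
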