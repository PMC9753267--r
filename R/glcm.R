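#' GLCM texture configuration
#'
#' Settings of the gray-level co-occurrence analysis: the sliding
#' computational window, the pixel-pair offsets (distance 1 at the four
#' standard orientations) and the gray-level quantization. 16-bit input is
#' rebinned to `nLevels` equal-width bins over the image's min-max range; 32
#' levels keeps 9x9 windows from being vanishingly sparse.
#'
#' @param windowSize odd window side length in pixels (default 9).
#' @param nLevels number of quantized gray levels (default 32).
#' @param distance pixel-pair offset distance (fixed default 1).
#' @param angles offset orientations in degrees (default 0/45/90/135).
#' @param averaging "features" (default) computes the 17 statistics per
#'   offset and averages them; "matrices" pools the co-occurrence counts
#'   over offsets before computing features once.
#' @return a validated list of class `GLCMConfig`.
#' @export
glcmConfig <- function(windowSize = 9L, nLevels = 32L, distance = 1L,
                       angles = c(0, 45, 90, 135),
                       averaging = c("features", "matrices")) {
  windowSize <- as.integer(windowSize)
  nLevels <- as.integer(nLevels)
  averaging <- match.arg(averaging)
  if (windowSize < 3L || windowSize %% 2L == 0L)
    stop("windowSize must be odd and >= 3")
  if (nLevels < 2L) stop("nLevels must be >= 2")
  if (length(angles) < 1L) stop("at least one offset angle is required")
  structure(list(windowSize = windowSize, nLevels = nLevels,
                 distance = as.integer(distance), angles = angles,
                 averaging = averaging),
            class = "GLCMConfig")
}

#' Quantize intensities to gray levels
#'
#' Equal-width binning of the value range `[lo, hi]` into `nLevels` levels
#' numbered 0..nLevels-1. By default the range is taken from the data
#' itself (whole-image quantization).
#'
#' @param img intensity matrix.
#' @param nLevels number of levels.
#' @param lo,hi range to bin over; defaults to `range(img)`.
#' @return integer matrix of levels in 0..nLevels-1.
#' @export
quantizeGrayLevels <- function(img, nLevels = 32L, lo = min(img),
                               hi = max(img)) {
  nLevels <- as.integer(nLevels)
  if (hi <= lo) return(matrix(0L, nrow(img), ncol(img)))
  q <- floor((img - lo) / (hi - lo) * nLevels)
  matrix(as.integer(pmin(pmax(q, 0), nLevels - 1L)), nrow(img), ncol(img))
}

#' Gray-level co-occurrence matrix of one window
#'
#' Counts all pixel pairs within the window separated by the offset,
#' accumulated symmetrically (each pair counted in both directions) and
#' normalized to sum 1. Rows grow downward, so at 45 degrees the offset
#' neighbour is up-and-right.
#'
#' @param window intensity matrix (one computational window).
#' @param distance offset distance in pixels.
#' @param angleDeg offset orientation in degrees (0, 45, 90 or 135).
#' @param nLevels gray levels to quantize to.
#' @param lo,hi quantization range (defaults to the window's own range).
#' @return `nLevels` x `nLevels` probability matrix (sums to 1, symmetric).
#' @export
#' @examples
#' chk <- outer(1:4, 1:4, "+") %% 2L # checkerboard
#' computeGLCM(chk, 1, 0, nLevels = 2)
computeGLCM <- function(window, distance = 1L, angleDeg = 0,
                        nLevels = 32L, lo = min(window), hi = max(window)) {
  stopifnot(is.matrix(window))
  d <- as.integer(distance)
  off <- switch(as.character(angleDeg),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d),
                stop("angleDeg must be one of 0, 45, 90, 135"))
  nr <- nrow(window); nc <- ncol(window)
  if (nr <= abs(off[1]) || nc <= abs(off[2]))
    stop("window smaller than the offset reach")
  q <- quantizeGrayLevels(window, nLevels, lo, hi)
  r0 <- max(1L, 1L - off[1]); r1 <- min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(nc, nc - off[2])
  a <- q[r0:r1, c0:c1, drop = FALSE]
  b <- q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]),
         drop = FALSE]
  counts <- matrix(0, nLevels, nLevels)
  tab <- table(factor(a, levels = 0:(nLevels - 1L)),
               factor(b, levels = 0:(nLevels - 1L)))
  counts <- counts + tab + t(tab) # symmetric accumulation
  counts / sum(counts)
}

#' The 17 Haralick texture statistics of a co-occurrence matrix
#'
#' Computes the classical second-order texture panel from a normalized
#' co-occurrence probability matrix: autocorrelation, cluster prominence,
#' cluster shade, contrast, correlation, difference entropy, dissimilarity,
#' energy, entropy, the two information measures of correlation, maximum
#' probability, sum average, sum entropy, sum of squares variance, sum
#' variance and homogeneity. Gray levels are valued 1..G; logarithms are
#' natural with the 0 log 0 = 0 convention. Degenerate matrices (a single
#' diagonal entry) give correlation, IMC1 and IMC2 of 0.
#'
#' @param P square probability matrix summing to 1.
#' @return named numeric vector of the 17 statistics in canonical order.
#' @export
#' @examples
#' P <- computeGLCM(outer(1:4, 1:4, "+") %% 2L, 1, 0, nLevels = 2)
#' haralickFeatures(P)[c("contrast", "energy")]
haralickFeatures <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1")
  G <- nrow(P)
  i <- matrix(rep(seq_len(G), G), G, G)        # row level value
  j <- t(i)                                    # col level value
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  nz <- P > 0
  plog <- function(v) ifelse(v > 0, log(v), 0)

  autoc <- sum(i * j * P)
  contrast <- sum((i - j)^2 * P)
  dissim <- sum(abs(i - j) * P)
  energy <- sum(P^2)
  entropy <- -sum(P[nz] * log(P[nz]))
  maxp <- max(P)
  homog <- sum(P / (1 + abs(i - j)))
  s <- i + j - mux - muy
  shade <- sum(s^3 * P)
  prom <- sum(s^4 * P)
  ssvar <- sum((i - mux)^2 * P)
  corr <- if (sx > 1e-12 && sy > 1e-12) (autoc - mux * muy) / (sx * sy) else 0

  ksum <- as.vector(tapply(as.vector(P), as.vector(i + j), sum))
  kval <- sort(unique(as.vector(i + j)))
  sa <- sum(kval * ksum)
  se <- -sum(ksum[ksum > 0] * log(ksum[ksum > 0]))
  sv <- sum((kval - sa)^2 * ksum)
  kdiff <- as.vector(tapply(as.vector(P), as.vector(abs(i - j)), sum))
  de <- -sum(kdiff[kdiff > 0] * log(kdiff[kdiff > 0]))

  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(P[nz] * plog(pxy)[nz])
  hxy2 <- -sum(pxy[pxy > 0] * log(pxy[pxy > 0]))
  imc1 <- if (max(hx, hy) > 1e-12) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(autocorrelation = autoc, cluster_prominence = prom,
    cluster_shade = shade, contrast = contrast, correlation = corr,
    difference_entropy = de, dissimilarity = dissim, energy = energy,
    entropy = entropy, imc1 = imc1, imc2 = imc2, max_probability = maxp,
    sum_average = sa, sum_entropy = se, sum_of_squares_variance = ssvar,
    sum_variance = sv, homogeneity = homog)
}
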