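# Independent brute-force oracles used to validate the package's
# implementations, plus small image builders.

# exhaustive Otsu: try every histogram split, compute the between-class
# variance directly from the two groups
oracleOtsu <- function(img, nBins = 256L) {
  rng <- range(img)
  b <- pmin(floor((img - rng[1]) / (rng[2] - rng[1]) * nBins), nBins - 1L)
  v <- as.vector(b)
  best <- -Inf; bestT <- NA_integer_
  for (t in seq_len(nBins - 1L) - 1L) { # split after bin t
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; bestT <- t }
  }
  rng[1] + (bestT + 1L) * (rng[2] - rng[1]) / nBins
}

# naive double-loop Haralick statistics (levels valued 1..G, natural logs)
oracleHaralick <- function(P) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mux)^2 * px)); sy <- sqrt(sum(((1:G) - muy)^2 * py))
  autoc <- contrast <- dissim <- energy <- entropy <- homog <- 0
  shade <- prom <- ssvar <- hxy1 <- 0
  maxp <- 0
  psum <- rep(0, 2 * G); pdiff <- rep(0, G)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    psumk <- i + j; pd <- abs(i - j)
    if (p > 0) {
      autoc <- autoc + i * j * p
      contrast <- contrast + (i - j)^2 * p
      dissim <- dissim + abs(i - j) * p
      energy <- energy + p^2
      entropy <- entropy - p * log(p)
      homog <- homog + p / (1 + abs(i - j))
      shade <- shade + (i + j - mux - muy)^3 * p
      prom <- prom + (i + j - mux - muy)^4 * p
      ssvar <- ssvar + (i - mux)^2 * p
      hxy1 <- hxy1 - p * log(px[i] * py[j])
      if (p > maxp) maxp <- p
      psum[psumk] <- psum[psumk] + p
      pdiff[pd + 1] <- pdiff[pd + 1] + p
    }
  }
  sa <- se <- 0
  for (k in 2:(2 * G)) if (psum[k] > 0) {
    sa <- sa + k * psum[k]; se <- se - psum[k] * log(psum[k])
  }
  sv <- 0
  for (k in 2:(2 * G)) if (psum[k] > 0) sv <- sv + (k - sa)^2 * psum[k]
  de <- 0
  for (k in 1:G) if (pdiff[k] > 0) de <- de - pdiff[k] * log(pdiff[k])
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy2 <- 0
  for (i in 1:G) for (j in 1:G) if (px[i] > 0 && py[j] > 0)
    hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
  corr <- if (sx > 1e-12 && sy > 1e-12) (autoc - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 1e-12) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(autocorrelation = autoc, cluster_prominence = prom,
    cluster_shade = shade, contrast = contrast, correlation = corr,
    difference_entropy = de, dissimilarity = dissim, energy = energy,
    entropy = entropy, imc1 = imc1, imc2 = imc2, max_probability = maxp,
    sum_average = sa, sum_entropy = se, sum_of_squares_variance = ssvar,
    sum_variance = sv, homogeneity = homog)
}

# random symmetric probability matrix
randomGLCM <- function(G) {
  m <- matrix(runif(G * G), G, G)
  m[sample(G * G, size = G)] <- 0 # some structural zeros
  m <- m + t(m)
  m / sum(m)
}

# chi-square statistic of a contingency table, direct formula
oracleChisq <- function(tab) {
  n <- sum(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - exp)^2 / exp)
}

# filled digital disk mask of radius r
discMask <- function(r, pad = 5L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  (xs - ctr)^2 + (ys - ctr)^2 <= r^2
}

# Gaussian-profile blob (support at one sigma) over a flat background
blobImage <- function(n = 96L, cx = n / 2, cy = n / 2, r = 16,
                      level = 30000, bg = 800, noiseSD = 60, seed = 1L) {
  withr::with_seed(seed, {
    xs <- matrix(rep(seq_len(n), each = n), n, n)
    ys <- matrix(rep(seq_len(n), n), n, n)
    d2 <- (xs - cx)^2 + (ys - cy)^2
    sup <- d2 <= r^2
    img <- bg + ifelse(sup, level * exp(-d2 / (2 * r^2)), 0) +
      rnorm(n * n, 0, noiseSD)
    list(img = matrix(pmin(pmax(round(img), 0), 65535), n, n), mask = sup)
  })
}

# feature table SummarizedExperiment built directly from a feature matrix
# (rows = features); labels recycled over EFS/EF/AA unless given
makeFeatureSE <- function(feat, labels) {
  colnames(feat) <- sprintf("s%03d", seq_len(ncol(feat)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = S4Vectors::DataFrame(id = colnames(feat), label = labels))
}

# SE whose per-class means of a single feature are exactly as requested;
# remaining panel rows are benign fillers
makeSEWithClassMeans <- function(means, nPerClass = 4L,
                                 feature = "mean_intensity") {
  labels <- rep(stageLevels(), each = nPerClass)
  feat <- matrix(1, nrow = 27, ncol = length(labels),
                 dimnames = list(featurePanelNames(), NULL))
  for (k in seq_along(stageLevels())) {
    idx <- which(labels == stageLevels()[k])
    # exactly zero-sum jitter so the class mean is exact in floating point
    delta <- rep(c(-0.5, 0.5), length.out = length(idx))
    if (length(idx) %% 2L == 1L) delta[length(idx)] <- 0
    feat[feature, idx] <- means[k] + delta
  }
  makeFeatureSE(feat, labels)
}

# three well-separated Gaussian point clouds as a feature table
separableCloudsSE <- function(nPerClass = 12L, nFeatures = 5L, gap = 30,
                              seed = 42L) {
  withr::with_seed(seed, {
    labels <- rep(stageLevels(), each = nPerClass)
    feat <- matrix(0, 27, length(labels),
                   dimnames = list(featurePanelNames(), NULL))
    for (k in seq_along(stageLevels())) {
      idx <- which(labels == stageLevels()[k])
      feat[seq_len(nFeatures), idx] <-
        rnorm(nFeatures * length(idx), mean = k * gap, sd = 1)
    }
    feat[(nFeatures + 1):27, ] <- rnorm((27 - nFeatures) * length(labels))
    makeFeatureSE(feat, labels)
  })
}
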