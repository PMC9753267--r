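#' Phantom generator configuration
#'
#' Builds a [PhantomConfig-class] describing the synthetic CARS foam-cell
#' phantom. The defaults emulate the qualitative structure of the three
#' lesion stages: early fatty streaks (EFS) are many small, dim, scattered
#' blobs; early fibroatheroma (EF) mixes dim immature and bright mature
#' blobs gathered around a few foci (producing the highest intensity
#' skewness and kurtosis of the three stages); advancing atheroma (AA) is a
#' compact coalesced cluster of large bright blobs. Mean foreground
#' intensity, total lesion area and foreground compactness all increase
#' with stage.
#'
#' @param imageWidth,imageHeight image size in pixels.
#' @param bitDepth pixel bit depth; intensities are clipped to
#'   `[0, 2^bitDepth - 1]`.
#' @param blobCount,blobCountSpread per-stage mean and SD of blob count
#'   (named over EFS/EF/AA).
#' @param blobRadius,blobRadiusSpread per-stage mean and SD of the blob
#'   support radius in pixels.
#' @param intensity,intensitySpread per-stage peak-intensity location and
#'   scale. The EF entry must equal the mixture mean implied by the EF
#'   mixture arguments; it is used for the stage-ordering invariant.
#' @param efDimIntensity,efBrightIntensity,efBrightFraction the EF
#'   dim/bright blob mixture: the dim (immature, EFS-like) and bright
#'   (mature, AA-like) peak levels and the mean per-image bright
#'   probability.
#' @param efMixtureConcentration Beta-concentration of the per-image
#'   bright fraction; lower values let single EF images shade into the
#'   neighbouring stages.
#' @param nFoci number of cluster foci per stage (0 = uniform scatter).
#' @param clusterSpread SD (px) of blob centres around their focus;
#'   decreasing with stage so compactness increases.
#' @param background,readNoise background level and Gaussian read-noise SD.
#' @return a validated [PhantomConfig-class].
#' @export
#' @examples
#' cfg <- phantomConfig()
#' cfg
phantomConfig <- function(imageWidth = 128L, imageHeight = 128L,
                          bitDepth = 16L,
                          blobCount = c(EFS = 28, EF = 18, AA = 12),
                          blobCountSpread = c(EFS = 5, EF = 4, AA = 2),
                          blobRadius = c(EFS = 5, EF = 8, AA = 13),
                          blobRadiusSpread = c(EFS = 1, EF = 1.5, AA = 2.5),
                          intensity = c(EFS = 12500, EF = 20800, AA = 30000),
                          intensitySpread = c(EFS = 1100, EF = 1600,
                                              AA = 2400),
                          efDimIntensity = 16000,
                          efBrightIntensity = 32000,
                          efBrightFraction = 0.3,
                          efMixtureConcentration = 4,
                          nFoci = c(EFS = 0L, EF = 3L, AA = 1L),
                          clusterSpread = c(EFS = Inf, EF = 15, AA = 11),
                          background = 800, readNoise = 100) {
  new("PhantomConfig",
      imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight),
      bitDepth = as.integer(bitDepth),
      blobCount = blobCount, blobCountSpread = blobCountSpread,
      blobRadius = blobRadius, blobRadiusSpread = blobRadiusSpread,
      intensity = intensity, intensitySpread = intensitySpread,
      efDimIntensity = efDimIntensity,
      efBrightIntensity = efBrightIntensity,
      efBrightFraction = efBrightFraction,
      efMixtureConcentration = efMixtureConcentration,
      nFoci = setNames(as.integer(nFoci), names(nFoci)),
      clusterSpread = clusterSpread,
      background = background, readNoise = readNoise)
}

#' Strong-separation phantom preset
#'
#' A [PhantomConfig-class] whose stage archetypes are pulled far apart in
#' mean intensity, integrated density and lesion area, so that the
#' interclass coefficient of variation of those features clearly exceeds
#' the 8 percent selection threshold. Used for end-to-end recovery
#' benchmarks of the segmentation/feature/classification chain.
#'
#' @param ... overrides passed on to [phantomConfig()].
#' @return a validated [PhantomConfig-class].
#' @export
strongSeparationConfig <- function(...) {
  args <- list(
    blobCount = c(EFS = 24, EF = 18, AA = 13),
    blobCountSpread = c(EFS = 3, EF = 3, AA = 2),
    blobRadius = c(EFS = 4.5, EF = 9, AA = 16),
    blobRadiusSpread = c(EFS = 0.8, EF = 1.5, AA = 2.5),
    intensity = c(EFS = 10000, EF = 24000, AA = 40000),
    intensitySpread = c(EFS = 900, EF = 1500, AA = 3000),
    efDimIntensity = 18000, efBrightIntensity = 38000,
    efBrightFraction = 0.3,
    clusterSpread = c(EFS = Inf, EF = 16, AA = 12))
  override <- list(...)
  args[names(override)] <- override
  do.call(phantomConfig, args)
}

#' Generate one synthetic foam-cell phantom
#'
#' Renders foam-cell blobs as isotropic Gaussian-profile discs
#' (`L * exp(-d^2 / (2 * r^2))`, hard support at `d <= r`) over a noisy
#' background. Overlapping blobs combine by pixelwise maximum so that
#' overlap does not manufacture super-bright artifacts. Poisson shot noise
#' is applied to the pre-clip signal and Gaussian read noise added before
#' rounding and clipping to the representable range. The ground-truth mask
#' is the union of blob supports.
#'
#' @param config a [PhantomConfig-class].
#' @param stage one of "EFS", "EF", "AA".
#' @param seed integer seed; the same (config, stage, seed) always yields a
#'   bit-identical record. The caller's RNG state is untouched.
#' @param id record identifier (default derived from stage and seed).
#' @return a [PlaqueRecord-class] with image, truth mask and label.
#' @export
#' @examples
#' rec <- generatePhantom(phantomConfig(), "AA", seed = 7)
#' rec
generatePhantom <- function(config, stage, seed,
                            id = sprintf("%s_seed%d", stage, seed)) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  if (length(stage) != 1L || !stage %in% stageLevels())
    stop("stage must be one of ", paste(stageLevels(), collapse = "/"))
  seed <- as.integer(seed)
  w <- config@imageWidth; h <- config@imageHeight
  maxv <- 2^config@bitDepth - 1

  withr::with_seed(seed, {
    n <- max(0L, as.integer(round(rnorm(1, config@blobCount[stage],
                                        config@blobCountSpread[stage]))))
    img <- matrix(0, h, w)
    mask <- matrix(FALSE, h, w)
    if (n > 0L) {
      nf <- config@nFoci[stage]
      if (nf == 0L) {
        cx <- runif(n, 1, w); cy <- runif(n, 1, h)
      } else {
        fx <- runif(nf, w * 0.25, w * 0.75)
        fy <- runif(nf, h * 0.25, h * 0.75)
        fi <- sample.int(nf, n, replace = TRUE)
        cs <- config@clusterSpread[stage]
        cx <- pmin(pmax(rnorm(n, fx[fi], cs), 1), w)
        cy <- pmin(pmax(rnorm(n, fy[fi], cs), 1), h)
      }
      rad <- pmax(1.5, rnorm(n, config@blobRadius[stage],
                             config@blobRadiusSpread[stage]))
      if (stage == "EF") {
        # per-image mixing fraction: some EF images are dim-dominated
        # (EFS-like), some bright-dominated (AA-like)
        k <- config@efMixtureConcentration
        fracBright <- rbeta(1, config@efBrightFraction * k,
                            (1 - config@efBrightFraction) * k)
        bright <- runif(n) < fracBright
        lev <- ifelse(bright,
                      rnorm(n, config@efBrightIntensity,
                            config@intensitySpread[stage]),
                      rnorm(n, config@efDimIntensity,
                            config@intensitySpread[stage]))
      } else {
        lev <- rnorm(n, config@intensity[stage],
                     config@intensitySpread[stage])
      }
      lev <- pmax(0, lev)
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      ys <- matrix(rep(seq_len(h), w), h, w)
      for (i in seq_len(n)) {
        d2 <- (xs - cx[i])^2 + (ys - cy[i])^2
        sup <- d2 <= rad[i]^2
        img <- pmax(img, ifelse(sup, lev[i] * exp(-d2 / (2 * rad[i]^2)), 0))
        mask <- mask | sup
      }
    }
    signal <- img + config@background
    noisy <- rpois(length(signal), lambda = as.vector(signal)) +
      rnorm(length(signal), 0, config@readNoise)
    pix <- matrix(pmin(pmax(round(noisy), 0), maxv), h, w)
    PlaqueRecord(id = id, image = pix, truthMask = mask, label = stage,
                 bitDepth = config@bitDepth)
  })
}

#' Generate a labelled phantom dataset
#'
#' Generates the requested number of phantoms per stage, each from a
#' distinct derived seed, and returns them in an order shuffled
#' reproducibly from the master seed.
#'
#' @param config a [PhantomConfig-class].
#' @param nPerStage named integer vector over EFS/EF/AA; e.g.
#'   `c(EFS = 214, EF = 134, AA = 218)` reproduces the class sizes of the
#'   rabbit study the phantom emulates.
#' @param seed master seed controlling both per-record seeds and the
#'   shuffle.
#' @return list of [PlaqueRecord-class].
#' @export
#' @examples
#' recs <- generateDataset(phantomConfig(), c(EFS = 2, EF = 2, AA = 2), 1)
#' length(recs)
generateDataset <- function(config,
                            nPerStage = c(EFS = 214L, EF = 134L, AA = 218L),
                            seed = 1L) {
  stopifnot(is(config, "PhantomConfig"))
  if (is.null(names(nPerStage)) ||
      !all(stageLevels() %in% names(nPerStage)))
    stop("nPerStage must be named over EFS/EF/AA")
  nPerStage <- nPerStage[stageLevels()]
  if (any(nPerStage < 0)) stop("counts must be nonnegative")
  total <- sum(nPerStage)
  if (total == 0L) return(list())
  plan <- rep(stageLevels(), times = nPerStage)
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    ord <- sample.int(total)
  })
  idx <- unlist(lapply(stageLevels(), function(s) seq_len(nPerStage[[s]])))
  recs <- vector("list", total)
  for (i in seq_len(total)) {
    recs[[i]] <- generatePhantom(
      config, plan[i], seeds[i],
      id = sprintf("%s_%03d", plan[i], idx[i]))
  }
  recs[ord]
}
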