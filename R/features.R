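## The 27-feature morphology panel: 6 first-order statistics, 4 shape
## descriptors and 17 GLCM texture statistics per segmented plaque.

#' Canonical names of the 27-feature panel
#'
#' Fixed ordering used by every feature table, CSV and selection result:
#' first-order statistics, then shape, then the 17 texture statistics.
#'
#' @return character vector of length 27.
#' @export
featurePanelNames <- function() {
  c("mean_intensity", "n_objects", "skewness", "kurtosis", "std_dev",
    "integrated_density",
    "area", "circularity", "perimeter", "extent",
    "autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
    "correlation", "difference_entropy", "dissimilarity", "energy",
    "entropy", "imc1", "imc2", "max_probability", "sum_average",
    "sum_entropy", "sum_of_squares_variance", "sum_variance", "homogeneity")
}

#' First-order statistics of the segmented plaque
#'
#' Six statistics of the masked pixel intensities: mean, number of objects
#' (8-connected components of the mask, a surrogate for the number of lipid
#' cells), skewness (standardized third central moment), kurtosis
#' (standardized fourth central moment, Pearson convention: normal = 3),
#' sample standard deviation, and integrated density (sum of masked
#' intensities). Zero-variance regions take the sentinel value 0 for
#' skewness and kurtosis.
#'
#' @param img intensity matrix.
#' @param mask non-empty logical matrix of the same dimensions.
#' @return named numeric vector of the 6 statistics.
#' @export
extractFOS <- function(img, mask) {
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) stop("mask is empty")
  v <- img[mask]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 > 0) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  c(mean_intensity = mu,
    n_objects = as.numeric(labelComponents(mask, 8L)$n),
    skewness = skew, kurtosis = kurt,
    std_dev = if (n > 1) sd(v) else 0,
    integrated_density = sum(v))
}

#' Shape descriptors of the segmented plaque
#'
#' Area (pixel count), perimeter (corrected chain-code length of the
#' component boundaries, summed over components), circularity
#' (`4 pi area / perimeter^2`, about 1 for large digital disks) and extent
#' (area over the bounding-box area of the mask union).
#'
#' @param mask non-empty logical matrix.
#' @return named numeric vector of the 4 descriptors.
#' @export
extractShape <- function(mask) {
  if (!any(mask)) stop("mask is empty")
  area <- sum(mask)
  per <- maskPerimeter(mask)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  bbox <- (diff(rows) + 1) * (diff(cols) + 1)
  circ <- if (per > 0) 4 * pi * area / per^2 else 0
  c(area = area, circularity = circ, perimeter = per,
    extent = area / bbox)
}

# perimeter by corrected chain-code length over 8-connected boundaries
# (Vossepoel-Smeulders weights: 0.980 per axial step, 1.406 per diagonal
# step, -0.091 per corner)
maskPerimeter <- function(mask) {
  lab <- labelComponents(mask, 8L)
  if (lab$n == 0) return(0)
  cont <- EBImage::ocontour(lab$labels)
  total <- 0
  for (cc in cont) {
    if (is.null(cc) || nrow(cc) < 2L) next
    pts <- rbind(cc, cc[1L, , drop = FALSE]) # close the contour
    st <- diff(pts)
    diagstep <- st[, 1] != 0 & st[, 2] != 0
    ne <- sum(!diagstep); no <- sum(diagstep)
    dir <- atan2(st[, 2], st[, 1])
    nc <- sum(dir != c(dir[-1], dir[1]))
    total <- total + 0.980 * ne + 1.406 * no - 0.091 * nc
  }
  total
}

#' Sliding-window GLCM texture panel
#'
#' For every pixel whose centre lies in the mask, a `windowSize` window
#' (mirror-padded at image borders) is analysed: co-occurrence matrices are
#' accumulated symmetrically at unit distance for the four standard
#' orientations, the 17 Haralick statistics are computed per orientation
#' and averaged (or computed from the pooled matrix when
#' `cfg$averaging == "matrices"`), and the per-centre panels are averaged
#' over the mask. Gray levels are quantized once over the whole image's
#' min-max range.
#'
#' @param img intensity matrix.
#' @param mask non-empty logical matrix.
#' @param cfg a [glcmConfig()].
#' @return named numeric vector of the 17 texture statistics.
#' @export
extractTexture <- function(img, mask, cfg = glcmConfig()) {
  stopifnot(identical(dim(img), dim(mask)), inherits(cfg, "GLCMConfig"))
  if (!any(mask)) stop("mask is empty")
  q <- quantizeGrayLevels(img, cfg$nLevels)
  v <- cpp_texture_panel(q, mask, cfg$windowSize, cfg$nLevels,
                         cfg$averaging == "matrices")
  names(v) <- featurePanelNames()[11:27]
  v
}

#' Extract the full 27-feature panel
#'
#' Concatenates [extractFOS()], [extractShape()] and [extractTexture()] in
#' canonical order.
#'
#' @param img intensity matrix (or a [PlaqueRecord-class]).
#' @param mask non-empty logical matrix.
#' @param cfg a [glcmConfig()].
#' @return named numeric vector of length 27.
#' @export
#' @examples
#' rec <- generatePhantom(phantomConfig(), "EFS", seed = 1)
#' f <- extractAll(rec, truthMask(rec))
#' length(f)
extractAll <- function(img, mask, cfg = glcmConfig()) {
  if (is(img, "PlaqueRecord")) img <- plaqueImage(img)
  out <- c(extractFOS(img, mask), extractShape(mask),
           extractTexture(img, mask, cfg))
  stopifnot(identical(names(out), featurePanelNames()))
  out
}

## ---------------------------------------------------------------------------
## Feature tables
## ---------------------------------------------------------------------------

#' Build a feature table from records and masks
#'
#' Extracts the 27-feature panel per record and assembles a
#' `SummarizedExperiment` with features as rows, samples as columns and
#' `id`/`label` in `colData`.
#'
#' @param records list of [PlaqueRecord-class].
#' @param masks parallel list of segmentation masks (default: the records'
#'   truth masks).
#' @param cfg a [glcmConfig()].
#' @return a `SummarizedExperiment` (27 x n).
#' @export
buildFeatureTable <- function(records, masks = lapply(records, truthMask),
                              cfg = glcmConfig()) {
  stopifnot(length(records) == length(masks))
  keep <- vapply(masks, function(m) !is.null(m) && any(m), logical(1))
  if (!any(keep)) stop("no record has a non-empty mask")
  records <- records[keep]; masks <- masks[keep]
  feat <- vapply(seq_along(records),
                 function(i) extractAll(records[[i]], masks[[i]], cfg),
                 numeric(27L))
  colnames(feat) <- vapply(records, recordId, character(1))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = S4Vectors::DataFrame(
      id = vapply(records, recordId, character(1)),
      label = vapply(records, stageLabel, character(1))))
}

#' Feature table as a plain data.frame
#'
#' @param se feature-table `SummarizedExperiment`.
#' @return data.frame with columns `id`, `label` and the 27 features.
#' @export
featureFrame <- function(se) {
  m <- t(SummarizedExperiment::assay(se, "features"))
  data.frame(id = se$id, label = se$label, m,
             row.names = NULL, check.names = FALSE)
}

#' Write / read a feature table CSV
#'
#' Columns: id, label, then the 27 canonical feature names, one row per
#' record. Numeric values are written with 17 significant digits so the
#' table round-trips losslessly.
#'
#' @param se feature-table `SummarizedExperiment`.
#' @param path CSV file path.
#' @return `writeFeatureCSV` returns `path` invisibly; `readFeatureCSV`
#'   returns a `SummarizedExperiment`.
#' @export
writeFeatureCSV <- function(se, path) {
  df <- featureFrame(se)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("id", "label", featurePanelNames())
  if (!all(need %in% colnames(df)))
    stop("feature CSV is missing required columns")
  feat <- t(as.matrix(df[, featurePanelNames(), drop = FALSE]))
  colnames(feat) <- df$id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = S4Vectors::DataFrame(id = as.character(df$id),
                                   label = as.character(df$label)))
}
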