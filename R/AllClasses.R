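#' Atherosclerotic plaque stage labels
#'
#' The three stages classified by the pipeline, in order of disease
#' progression: early fatty streak development (EFS), early fibroatheroma
#' (EF) and advancing atheroma (AA). Complex lesions (AHA types V/VI) are
#' outside the scope of the classifier.
#'
#' @return Character vector `c("EFS", "EF", "AA")`.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() c("EFS", "EF", "AA")

#' @title Stage factor helper
#' @description Coerce a character vector to the ordered stage factor.
#' @param x character vector of stage names.
#' @return an ordered factor with levels EFS < EF < AA.
#' @export
stageFactor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(stageLevels(), NA))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  factor(as.character(x), levels = stageLevels(), ordered = TRUE)
}

## ---------------------------------------------------------------------------
## PhantomConfig
## ---------------------------------------------------------------------------

#' PhantomConfig: parameters of the synthetic foam-cell image generator
#'
#' Per-stage distributions of the phantom generator. All per-stage slots are
#' named numeric vectors over `c("EFS","EF","AA")`. Foam-cell clusters are
#' rendered as isotropic Gaussian-profile discs; the early fibroatheroma
#' stage mixes a dim (immature) and a bright (mature) blob population,
#' which produces the elevated intensity skewness and kurtosis that
#' distinguishes that stage.
#'
#' @slot imageWidth,imageHeight image size in pixels.
#' @slot bitDepth bits per pixel (intensities live in `[0, 2^bitDepth - 1]`).
#' @slot blobCount,blobCountSpread per-stage mean and spread of the number
#'   of foam-cell blobs per image.
#' @slot blobRadius,blobRadiusSpread per-stage mean and spread of the blob
#'   support radius, in pixels.
#' @slot intensity,intensitySpread per-stage location and scale of the blob
#'   peak intensity. For EF the location is the mixture mean implied by the
#'   `efDim*`/`efBright*` slots and is stored for the ordering invariant.
#' @slot efDimIntensity,efBrightIntensity,efBrightFraction the EF intensity
#'   mixture: peak levels of the dim (immature, EFS-like) and bright
#'   (mature, AA-like) populations and the mean per-image probability that
#'   a blob is bright.
#' @slot efMixtureConcentration concentration of the Beta distribution the
#'   per-image bright fraction is drawn from (mean `efBrightFraction`);
#'   smaller values make individual EF images shade further into their
#'   neighbouring stages.
#' @slot nFoci per-stage number of cluster foci blob centres are scattered
#'   around; 0 means uniform scatter over the field.
#' @slot clusterSpread per-stage standard deviation (pixels) of blob centres
#'   around their focus; must decrease EFS > EF > AA so that the fraction of
#'   foreground in the largest connected component increases with stage.
#' @slot background,readNoise background level and Gaussian read-noise
#'   standard deviation, in intensity units. Poisson shot noise is applied
#'   to the pre-clip signal in addition.
#' @export
setClass("PhantomConfig", representation(
  imageWidth = "integer", imageHeight = "integer", bitDepth = "integer",
  blobCount = "numeric", blobCountSpread = "numeric",
  blobRadius = "numeric", blobRadiusSpread = "numeric",
  intensity = "numeric", intensitySpread = "numeric",
  efDimIntensity = "numeric", efBrightIntensity = "numeric",
  efBrightFraction = "numeric", efMixtureConcentration = "numeric",
  nFoci = "integer", clusterSpread = "numeric",
  background = "numeric", readNoise = "numeric"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  st <- stageLevels()
  perStage <- c("blobCount", "blobCountSpread", "blobRadius",
                "blobRadiusSpread", "intensity", "intensitySpread",
                "nFoci", "clusterSpread")
  for (s in perStage) {
    v <- slot(object, s)
    if (length(v) != 3L || !identical(names(v), st))
      msg <- c(msg, sprintf("slot '%s' must be named over %s",
                            s, paste(st, collapse = "/")))
  }
  if (length(msg)) return(msg)
  if (object@imageWidth < 1L || object@imageHeight < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@bitDepth < 1L || object@bitDepth > 16L)
    msg <- c(msg, "bitDepth must be in 1..16")
  nonneg <- c("blobCount", "blobCountSpread", "blobRadius",
              "blobRadiusSpread", "intensity", "intensitySpread")
  for (s in nonneg)
    if (any(slot(object, s) < 0))
      msg <- c(msg, sprintf("slot '%s' must be nonnegative", s))
  iv <- object@intensity
  if (!(iv["EFS"] < iv["EF"] && iv["EF"] < iv["AA"]))
    msg <- c(msg, "foreground intensity must be ordered EFS < EF < AA")
  cs <- object@clusterSpread
  if (!(cs["EFS"] > cs["EF"] && cs["EF"] > cs["AA"]))
    msg <- c(msg, paste("clusterSpread must decrease EFS > EF > AA",
                        "(compactness increases with stage)"))
  if (object@efBrightIntensity <= object@efDimIntensity)
    msg <- c(msg, "EF bright population must exceed the dim population")
  if (object@efBrightFraction <= 0 || object@efBrightFraction >= 1)
    msg <- c(msg, "efBrightFraction must be in (0, 1)")
  if (object@efMixtureConcentration <= 0)
    msg <- c(msg, "efMixtureConcentration must be positive")
  if (object@background < 0 || object@readNoise < 0)
    msg <- c(msg, "background and readNoise must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d px, %d-bit\n",
              object@imageWidth, object@imageHeight, object@bitDepth))
  m <- rbind(blobCount = object@blobCount,
             blobRadius = object@blobRadius,
             intensity = object@intensity,
             clusterSpread = object@clusterSpread)
  print(round(m, 1))
  cat(sprintf("EF mixture: dim %.0f / bright %.0f (bright fraction %.2f)\n",
              object@efDimIntensity, object@efBrightIntensity,
              object@efBrightFraction))
  cat(sprintf("background %.0f, read noise %.0f\n",
              object@background, object@readNoise))
})

## ---------------------------------------------------------------------------
## PlaqueRecord
## ---------------------------------------------------------------------------

#' PlaqueRecord: one CARS image with optional truth mask and stage label
#'
#' @slot id sample identifier.
#' @slot image integer intensity matrix (rows x cols).
#' @slot truthMask logical matrix of the same dimensions, or NULL.
#' @slot label one of "EFS", "EF", "AA", or NA when unlabelled.
#' @slot bitDepth bits per pixel of `image`.
#' @export
setClass("PlaqueRecord", representation(
  id = "character", image = "matrix", truthMask = "ANY",
  label = "character", bitDepth = "integer"))

setValidity("PlaqueRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (!is.numeric(object@image) || any(dim(object@image) < 1L))
    msg <- c(msg, "image must be a numeric matrix of at least 1 x 1")
  maxv <- 2^object@bitDepth - 1
  if (is.numeric(object@image) &&
      (min(object@image) < 0 || max(object@image) > maxv))
    msg <- c(msg, sprintf("pixel values must lie in [0, %d]", maxv))
  if (!is.null(object@truthMask)) {
    if (!is.logical(object@truthMask) ||
        !identical(dim(object@truthMask), dim(object@image)))
      msg <- c(msg, "truthMask must be a logical matrix matching image dims")
  }
  if (!is.na(object@label) && !object@label %in% stageLevels())
    msg <- c(msg, "label must be one of EFS/EF/AA or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlaqueRecord", function(object) {
  cat(sprintf("PlaqueRecord '%s': %d x %d px (%d-bit), label %s, %s\n",
              object@id, nrow(object@image), ncol(object@image),
              object@bitDepth,
              ifelse(is.na(object@label), "<none>", object@label),
              if (is.null(object@truthMask)) "no truth mask"
              else sprintf("truth mask (%d px foreground)",
                           sum(object@truthMask))))
})

#' Accessors for PlaqueRecord
#'
#' @param object a [PlaqueRecord-class].
#' @return `plaqueImage` the intensity matrix; `truthMask` the logical mask
#'   or NULL; `stageLabel` the stage string or NA; `recordId` the id;
#'   `bitDepth` the pixel bit depth.
#' @name PlaqueRecord-accessors
#' @aliases plaqueImage truthMask stageLabel recordId bitDepth
NULL

#' @rdname PlaqueRecord-accessors
#' @export
setGeneric("plaqueImage", function(object) standardGeneric("plaqueImage"))
#' @rdname PlaqueRecord-accessors
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @rdname PlaqueRecord-accessors
#' @export
setGeneric("stageLabel", function(object) standardGeneric("stageLabel"))
#' @rdname PlaqueRecord-accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @rdname PlaqueRecord-accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname PlaqueRecord-accessors
setMethod("plaqueImage", "PlaqueRecord", function(object) object@image)
#' @rdname PlaqueRecord-accessors
setMethod("truthMask", "PlaqueRecord", function(object) object@truthMask)
#' @rdname PlaqueRecord-accessors
setMethod("stageLabel", "PlaqueRecord", function(object) object@label)
#' @rdname PlaqueRecord-accessors
setMethod("recordId", "PlaqueRecord", function(object) object@id)
#' @rdname PlaqueRecord-accessors
setMethod("bitDepth", "PlaqueRecord", function(object) object@bitDepth)

#' Construct a PlaqueRecord
#'
#' @param id sample identifier.
#' @param image integer intensity matrix.
#' @param truthMask optional logical matrix with the ground-truth plaque
#'   foreground.
#' @param label optional stage label ("EFS", "EF" or "AA").
#' @param bitDepth pixel bit depth (default 16).
#' @return a [PlaqueRecord-class].
#' @export
PlaqueRecord <- function(id, image, truthMask = NULL, label = NA_character_,
                         bitDepth = 16L) {
  new("PlaqueRecord", id = as.character(id),
      image = image, truthMask = truthMask,
      label = as.character(label), bitDepth = as.integer(bitDepth))
}

## ---------------------------------------------------------------------------
## SelectionResult
## ---------------------------------------------------------------------------

#' SelectionResult: outcome of a feature-refinement method
#'
#' @slot method "CV" (interclass coefficient of variation) or "FTF"
#'   (chi-square filter-type selection).
#' @slot retained ordered character vector of retained feature names.
#' @slot scores named numeric score for every candidate feature (CV
#'   percentage, or the chi-square statistic for FTF).
#' @slot pValues named numeric vector of chi-square p-values (FTF only,
#'   NA otherwise).
#' @slot thresholdOrK the CV threshold in percent, or the FTF top-k count.
#' @export
setClass("SelectionResult", representation(
  method = "character", retained = "character", scores = "numeric",
  pValues = "numeric", thresholdOrK = "numeric"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!object@method %in% c("CV", "FTF"))
    msg <- c(msg, "method must be 'CV' or 'FTF'")
  if (is.null(names(object@scores)))
    msg <- c(msg, "scores must be named")
  if (!all(object@retained %in% names(object@scores)))
    msg <- c(msg, "retained features must be scored")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d of %d features retained (%s = %g)\n",
              object@method, length(object@retained), length(object@scores),
              ifelse(object@method == "CV", "threshold %", "top k"),
              object@thresholdOrK))
  cat(strwrap(paste(object@retained, collapse = ", "), indent = 2,
              exdent = 2), sep = "\n")
})

#' @rdname SelectionResult-class
#' @param object a `SelectionResult`.
#' @export
setGeneric("retainedFeatures", function(object)
  standardGeneric("retainedFeatures"))
#' @rdname SelectionResult-class
setMethod("retainedFeatures", "SelectionResult",
          function(object) object@retained)
#' @rdname SelectionResult-class
#' @export
setGeneric("featureScores", function(object)
  standardGeneric("featureScores"))
#' @rdname SelectionResult-class
setMethod("featureScores", "SelectionResult", function(object) object@scores)

## ---------------------------------------------------------------------------
## EvaluationReport
## ---------------------------------------------------------------------------

#' EvaluationReport: classifier performance on a held-out feature table
#'
#' Confusion matrix and one-vs-rest metrics for the three stages. Per-class
#' accuracy follows the class-conditional convention (correct within class /
#' class size, i.e. recall); precision, recall and F1 are one-vs-rest.
#' `generalizationError` is training accuracy minus mean cross-validation
#' accuracy of the fitted model, a proxy for overfitting.
#'
#' @slot confusion 3x3 integer matrix, rows = true stage, cols = predicted.
#' @slot perClass numeric matrix, rows = stages, cols = accuracy, precision,
#'   recall, f1.
#' @slot macro named numeric: macro accuracy/precision/recall/f1.
#' @slot generalizationError numeric proportion.
#' @export
setClass("EvaluationReport", representation(
  confusion = "matrix", perClass = "matrix", macro = "numeric",
  generalizationError = "numeric"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!identical(dim(object@confusion), c(3L, 3L)))
    msg <- c(msg, "confusion must be 3x3")
  if (any(object@confusion < 0))
    msg <- c(msg, "confusion counts must be nonnegative")
  pc <- object@perClass
  if (any(pc[is.finite(pc)] < 0) || any(pc[is.finite(pc)] > 1))
    msg <- c(msg, "per-class rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n  confusion (rows = truth):\n")
  print(object@confusion)
  cat("  per-class metrics:\n")
  print(round(object@perClass, 3))
  cat(sprintf("  macro accuracy %.3f, generalization error %.3f\n",
              object@macro["accuracy"], object@generalizationError))
})

#' @rdname EvaluationReport-class
#' @param object an `EvaluationReport`.
#' @export
setGeneric("confusionMatrix", function(object)
  standardGeneric("confusionMatrix"))
#' @rdname EvaluationReport-class
setMethod("confusionMatrix", "EvaluationReport",
          function(object) object@confusion)
#' @rdname EvaluationReport-class
#' @export
setGeneric("classMetrics", function(object) standardGeneric("classMetrics"))
#' @rdname EvaluationReport-class
setMethod("classMetrics", "EvaluationReport", function(object) object@perClass)
#' @rdname EvaluationReport-class
#' @export
setGeneric("macroMetrics", function(object) standardGeneric("macroMetrics"))
#' @rdname EvaluationReport-class
setMethod("macroMetrics", "EvaluationReport", function(object) object@macro)
#' @rdname EvaluationReport-class
#' @export
setGeneric("generalizationError", function(object)
  standardGeneric("generalizationError"))
#' @rdname EvaluationReport-class
setMethod("generalizationError", "EvaluationReport",
          function(object) object@generalizationError)
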