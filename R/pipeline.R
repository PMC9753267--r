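## End-to-end orchestration: preprocess -> four segmentations -> features
## -> two refinements -> three classifiers, with a cross-product summary.

#' Pipeline configuration
#'
#' Collects every stage's parameters. Defaults mirror the method's standard
#' settings: 1 percent saturation contrast stretch, unsharp radius 1.5 /
#' amount 0.8, GLCM window 9 at four orientations, CV threshold 8 percent,
#' FTF top 15, 60/20/20 stratified split and tenfold cross-validation, and
#' a Dice evaluation subset of up to 50 images per stage group.
#'
#' @param segmenters segmentation methods to run.
#' @param selectors feature-refinement methods to run.
#' @param classifiers classification algorithms to run.
#' @param lowFraction,highFraction,sharpenRadius,sharpenAmount
#'   preprocessing parameters.
#' @param glcm a [glcmConfig()].
#' @param cvThresholdPct CV retention threshold (percent).
#' @param ftfK FTF top-k count.
#' @param fractions train/test/val proportions.
#' @param cvFolds cross-validation folds for tuning.
#' @param tuningBudget random-search draws per classifier.
#' @param diceSubset Dice-scored images per stage group.
#' @param segParams named list of per-method argument lists, e.g.
#'   `list(mcw = list(markerMinDistance = 13))`.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(segmenters = c("ots", "ifct", "mcw", "kms"),
                           selectors = c("CV", "FTF"),
                           classifiers = c("KNN", "DT", "MCSVM"),
                           lowFraction = 0.01, highFraction = 0.01,
                           sharpenRadius = 1.5, sharpenAmount = 0.8,
                           glcm = glcmConfig(),
                           cvThresholdPct = 8, ftfK = 15L,
                           fractions = c(train = 0.6, test = 0.2,
                                         val = 0.2),
                           cvFolds = 10L, tuningBudget = 30L,
                           diceSubset = 50L,
                           segParams = list()) {
  structure(list(segmenters = match.arg(segmenters,
                                        c("ots", "ifct", "mcw", "kms"),
                                        several.ok = TRUE),
                 selectors = match.arg(selectors, c("CV", "FTF"),
                                       several.ok = TRUE),
                 classifiers = match.arg(classifiers,
                                         c("KNN", "DT", "MCSVM"),
                                         several.ok = TRUE),
                 lowFraction = lowFraction, highFraction = highFraction,
                 sharpenRadius = sharpenRadius,
                 sharpenAmount = sharpenAmount,
                 glcm = glcm, cvThresholdPct = cvThresholdPct,
                 ftfK = as.integer(ftfK), fractions = fractions,
                 cvFolds = as.integer(cvFolds),
                 tuningBudget = as.integer(tuningBudget),
                 diceSubset = as.integer(diceSubset),
                 segParams = segParams),
            class = "PipelineConfig")
}

preprocessRecord <- function(rec, config) {
  preprocessImage(plaqueImage(rec),
                  lowFraction = config$lowFraction,
                  highFraction = config$highFraction,
                  radius = config$sharpenRadius,
                  amount = config$sharpenAmount,
                  bitDepth = bitDepth(rec))
}

segmentOne <- function(img, method, config, seed) {
  args <- c(list(img = img, method = method),
            config$segParams[[method]])
  if (method == "kms") args$seed <- seed
  do.call(segmentImage, args)
}

#' Run the full classification pipeline
#'
#' Preprocesses every record, then for each segmentation method: computes
#' plaque masks, scores Dice agreement against reference masks on a seeded
#' random subset per stage group (the record's truth mask when present,
#' otherwise an active-contour reference traced from a dilated Otsu mask),
#' extracts the 27-feature panel, refines it with each selector, and
#' trains/evaluates each classifier on the refined panel with a stratified
#' 60/20/20 split. Records whose segmentation is empty or whose feature
#' extraction fails are quarantined per image and the run continues.
#'
#' @param records list of labelled [PlaqueRecord-class] (or a manifest CSV
#'   path).
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory; when given, masks, Dice CSVs,
#'   feature CSVs, selection JSONs, report JSONs and the summary CSV are
#'   written beneath it.
#' @param seed global seed; propagates to segmentation, splitting and
#'   tuning, so a rerun with the same inputs is bit-identical.
#' @return (invisibly) a list with `summary` (one row per segmenter x
#'   selector x classifier), `dice` (per-image Dice scores), `selections`,
#'   `reports`, `features` and `issues`.
#' @export
runPipeline <- function(records, config = pipelineConfig(), outDir = NULL,
                        seed = 1L) {
  if (is.character(records) && length(records) == 1L)
    records <- readDataset(records)
  if (length(records) == 0) stop("no usable records")
  seed <- as.integer(seed)
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  pre <- lapply(records, preprocessRecord, config = config)
  labs <- vapply(records, stageLabel, character(1))
  ids <- vapply(records, recordId, character(1))
  withr::with_seed(seed, {
    kmsSeeds <- sample.int(.Machine$integer.max - 1L, length(records))
  })

  issues <- data.frame(id = character(), stage = character(),
                       problem = character())
  quarantine <- function(id, stage, problem) {
    issues <<- rbind(issues, data.frame(id = id, stage = stage,
                                        problem = problem))
  }

  # seeded Dice subset: up to diceSubset records per stage group
  withr::with_seed(seed + 1L, {
    diceIdx <- unlist(lapply(stageLevels(), function(s) {
      cand <- which(labs == s)
      if (length(cand) > config$diceSubset)
        sort(sample(cand, config$diceSubset)) else cand
    }))
  })

  summaryRows <- list()
  diceTables <- list()
  selections <- list()
  reports <- list()
  featureTables <- list()

  for (m in config$segmenters) {
    masks <- vector("list", length(records))
    for (i in seq_along(records)) {
      masks[[i]] <- tryCatch(
        segmentOne(pre[[i]], m, config, kmsSeeds[i]),
        error = function(e) {
          quarantine(ids[i], paste0("segment/", m), conditionMessage(e))
          NULL
        })
    }
    ok <- !vapply(masks, is.null, logical(1)) &
      vapply(masks, function(x) !is.null(x) && any(x), logical(1))
    for (i in which(!ok))
      quarantine(ids[i], paste0("segment/", m), "empty mask")

    # Dice against reference masks on the seeded subset
    dsub <- intersect(diceIdx, which(ok))
    dscore <- vapply(dsub, function(i) {
      ref <- truthMask(records[[i]])
      if (is.null(ref)) {
        init <- as.matrix(EBImage::dilate(
          otsuSegment(pre[[i]])$mask * 1,
          EBImage::makeBrush(7, "disc"))) > 0
        if (!any(init)) return(NA_real_)
        ref <- traceReference(pre[[i]], init, nIter = 30L)
      }
      dice(masks[[i]], ref)
    }, numeric(1))
    diceTab <- data.frame(id = ids[dsub], method = m,
                          label = labs[dsub], dice = dscore)
    diceTables[[m]] <- diceTab

    ft <- tryCatch(
      buildFeatureTable(records[ok], masks[ok], config$glcm),
      error = function(e) NULL)
    if (is.null(ft)) {
      quarantine("*", paste0("features/", m), "feature extraction failed")
      next
    }
    featureTables[[m]] <- ft

    sels <- list()
    for (selName in config$selectors) {
      sel <- if (selName == "CV")
        cvSelect(ft, config$cvThresholdPct)
      else ftfSelect(ft, config$ftfK)
      sels[[selName]] <- sel
      split <- splitDataset(ft, config$fractions, seed = seed)
      for (alg in config$classifiers) {
        spec <- classifierSpec(alg, tuningBudget = config$tuningBudget,
                               cvFolds = config$cvFolds, seed = seed)
        model <- tuneAndTrain(spec, split$train,
                              features = retainedFeatures(sel))
        rep <- evaluateModel(model, split$test)
        key <- paste(m, selName, alg, sep = "_")
        reports[[key]] <- rep
        pc <- classMetrics(rep)
        summaryRows[[key]] <- data.frame(
          segmenter = m, selector = selName, classifier = alg,
          nFeatures = length(retainedFeatures(sel)),
          meanDice = mean(dscore, na.rm = TRUE),
          macroAccuracy = unname(macroMetrics(rep)["accuracy"]),
          accEFS = pc["EFS", "accuracy"],
          accEF = pc["EF", "accuracy"],
          accAA = pc["AA", "accuracy"],
          macroF1 = unname(macroMetrics(rep)["f1"]),
          generalizationError = generalizationError(rep))
      }
    }
    selections[[m]] <- sels

    if (!is.null(outDir)) {
      mdir <- file.path(outDir, m)
      dir.create(file.path(mdir, "masks"), showWarnings = FALSE,
                 recursive = TRUE)
      for (i in which(ok))
        writeMask(masks[[i]], file.path(mdir, "masks",
                                        paste0(ids[i], ".png")))
      write.csv(diceTab, file.path(mdir, "dice.csv"), row.names = FALSE)
      writeFeatureCSV(ft, file.path(mdir, "features.csv"))
      for (selName in names(sels))
        writeSelectionJSON(sels[[selName]],
                           file.path(mdir, paste0("selection_",
                                                  tolower(selName),
                                                  ".json")))
    }
  }

  summary <- do.call(rbind, c(summaryRows, make.row.names = FALSE))
  if (!is.null(outDir)) {
    write.csv(summary, file.path(outDir, "summary.csv"),
              row.names = FALSE)
    for (key in names(reports))
      writeReportJSON(reports[[key]],
                      file.path(outDir, paste0("report_", key, ".json")))
    if (nrow(issues))
      write.csv(issues, file.path(outDir, "issues.csv"),
                row.names = FALSE)
  }
  invisible(list(summary = summary, dice = diceTables,
                 selections = selections, reports = reports,
                 features = featureTables, issues = issues))
}

#' Fit an inference bundle
#'
#' Trains one (segmenter, selector, classifier) combination on a labelled
#' record set and packages everything needed to classify a new image.
#'
#' @param records labelled [PlaqueRecord-class] list.
#' @param segmenter segmentation method name.
#' @param selector "CV" or "FTF".
#' @param algorithm "KNN", "DT" or "MCSVM".
#' @param config a [pipelineConfig()].
#' @param seed integer seed.
#' @return a list of class `plaqueBundle`.
#' @export
fitBundle <- function(records, segmenter = "ots", selector = "CV",
                      algorithm = "DT", config = pipelineConfig(),
                      seed = 1L) {
  pre <- lapply(records, preprocessRecord, config = config)
  withr::with_seed(as.integer(seed), {
    kmsSeeds <- sample.int(.Machine$integer.max - 1L, length(records))
  })
  masks <- lapply(seq_along(records), function(i)
    segmentOne(pre[[i]], segmenter, config, kmsSeeds[i]))
  ok <- vapply(masks, any, logical(1))
  ft <- buildFeatureTable(records[ok], masks[ok], config$glcm)
  sel <- if (selector == "CV") cvSelect(ft, config$cvThresholdPct)
         else ftfSelect(ft, config$ftfK)
  spec <- classifierSpec(algorithm, tuningBudget = config$tuningBudget,
                         cvFolds = config$cvFolds, seed = seed)
  model <- tuneAndTrain(spec, ft, features = retainedFeatures(sel))
  structure(list(config = config, segmenter = segmenter,
                 selection = sel, model = model, seed = seed),
            class = "plaqueBundle")
}

#' Classify a single image
#'
#' Runs preprocess, segmentation, feature extraction and prediction on one
#' image with a fitted bundle. An empty segmentation yields the explicit
#' outcome "no plaque detected" rather than a stage label.
#'
#' An image whose histogram shows no real foreground/background structure
#' (Otsu separability, the ratio of between-class to total variance, below
#' `minSeparability`) is also reported as plaque-free: threshold methods
#' would otherwise split pure background noise mid-histogram.
#'
#' @param img intensity matrix, [PlaqueRecord-class], or image file path.
#' @param bundle a `plaqueBundle` from [fitBundle()].
#' @param minSeparability Otsu effectiveness floor below which the image is
#'   declared plaque-free (default 0.8; blank noise scores about 0.72,
#'   genuine plaque 0.86 and above).
#' @return list with `status` ("ok" or "no plaque detected"), `label`
#'   (stage string or NA) and `features` (the 27-feature vector or NULL).
#' @export
classifySingle <- function(img, bundle, minSeparability = 0.8) {
  stopifnot(inherits(bundle, "plaqueBundle"))
  if (is.character(img)) img <- readPlaqueImage(img)
  if (is(img, "PlaqueRecord")) img <- plaqueImage(img)
  cfg <- bundle$config
  pre <- preprocessImage(img, cfg$lowFraction, cfg$highFraction,
                         cfg$sharpenRadius, cfg$sharpenAmount)
  mask <- tryCatch(
    segmentOne(pre, bundle$segmenter, cfg, bundle$seed),
    error = function(e) matrix(FALSE, nrow(pre), ncol(pre)))
  if (!any(mask) || otsuSeparability(pre) < minSeparability)
    return(list(status = "no plaque detected", label = NA_character_,
                features = NULL))
  feats <- extractAll(img, mask, cfg$glcm)
  lab <- as.character(predictStage(bundle$model, feats))
  list(status = "ok", label = lab, features = feats)
}
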