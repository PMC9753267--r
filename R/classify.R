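## Supervised staging: stratified splitting, seeded random-search tuning of
## kNN / decision tree / one-vs-one multiclass SVM, prediction and
## evaluation.

#' Stratified train/test/validation split
#'
#' Partitions a feature table into disjoint, exhaustive train/test/
#' validation subsets. With stratification each class is shuffled and
#' allocated by the largest-remainder rule (floor counts first, remaining
#' rows to the subsets with the largest fractional remainders, ties in the
#' order train, test, validation), so per-class proportions are preserved
#' within rounding.
#'
#' @param se feature-table `SummarizedExperiment`.
#' @param fractions named proportions over train/test/val, summing to 1
#'   (default 60/20/20).
#' @param seed integer seed; the same seed reproduces the partition.
#' @param stratified stratify by stage label (default TRUE).
#' @return named list of three `SummarizedExperiment`s: `train`, `test`,
#'   `val`.
#' @export
splitDataset <- function(se, fractions = c(train = 0.6, test = 0.2,
                                           val = 0.2),
                         seed = 1L, stratified = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0))
    stop("fractions must be positive and sum to 1")
  fractions <- fractions[c("train", "test", "val")]
  n <- ncol(se)
  assign1 <- function(idx) {
    m <- length(idx)
    raw <- fractions * m
    cnt <- floor(raw)
    rem <- m - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    split(idx, rep(names(fractions), times = cnt))
  }
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      parts <- list(train = integer(), test = integer(), val = integer())
      for (s in unique(se$label)) {
        idx <- sample(which(se$label == s))
        p <- assign1(idx)
        for (nm in names(p)) parts[[nm]] <- c(parts[[nm]], p[[nm]])
      }
    } else {
      parts <- assign1(sample(seq_len(n)))
    }
  })
  lapply(parts[c("train", "test", "val")], function(i) se[, sort(i)])
}

#' Classifier specification
#'
#' Algorithm choice and tuning policy. Hyperparameters are drawn by seeded
#' random search over the standard spaces: kNN tunes the number of
#' neighbours (1..25) and the distance metric (Euclidean/Manhattan); the
#' decision tree tunes maximum depth (1..15), minimum leaf size (1..15),
#' minimum parent size to split (2..40) and the complexity parameter
#' (log-uniform 1e-4..0.1); the one-vs-one multiclass SVM (radial kernel)
#' tunes the box constraint (log-uniform 0.1..100) and the kernel width
#' gamma (log-uniform 1e-3..1).
#'
#' @param algorithm "KNN", "DT" or "MCSVM".
#' @param tuningBudget number of sampled configurations (default 30);
#'   0 trains at the space defaults.
#' @param cvFolds cross-validation folds used for tuning (default 10).
#' @param seed integer seed controlling sampling and fold assignment.
#' @return a list of class `ClassifierSpec`.
#' @export
classifierSpec <- function(algorithm = c("KNN", "DT", "MCSVM"),
                           tuningBudget = 30L, cvFolds = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (cvFolds < 2L) stop("cvFolds must be >= 2")
  structure(list(algorithm = algorithm,
                 tuningBudget = as.integer(tuningBudget),
                 cvFolds = as.integer(cvFolds), seed = as.integer(seed)),
            class = "ClassifierSpec")
}

defaultConfig <- function(algorithm, p) {
  switch(algorithm,
         KNN = list(k = 5L, metric = "Euclidean"),
         DT = list(maxdepth = 10L, minbucket = 7L, minsplit = 20L,
                   cp = 0.01),
         MCSVM = list(cost = 1, gamma = 1 / p))
}

sampleConfig <- function(algorithm) {
  switch(algorithm,
         KNN = list(k = sample(1:25, 1),
                    metric = sample(c("Euclidean", "Manhattan"), 1)),
         DT = list(maxdepth = sample(1:15, 1), minbucket = sample(1:15, 1),
                   minsplit = sample(2:40, 1), cp = 10^runif(1, -4, -1)),
         MCSVM = list(cost = 10^runif(1, -1, 2),
                      gamma = 10^runif(1, -3, 0)))
}

fitOne <- function(algorithm, config, x, y) {
  switch(algorithm,
         KNN = {
           sc <- scaleParams(x)
           list(kind = "KNN",
                fit = e1071::gknn(applyScale(x, sc), y, k = config$k,
                                  method = config$metric, scale = FALSE),
                scale = sc)
         },
         DT = {
           df <- data.frame(.label = y, x, check.names = FALSE)
           list(kind = "DT",
                fit = rpart::rpart(
                  .label ~ ., data = df, method = "class",
                  control = rpart::rpart.control(
                    maxdepth = config$maxdepth,
                    minbucket = config$minbucket,
                    minsplit = config$minsplit,
                    cp = config$cp, xval = 0)))
         },
         MCSVM = {
           sc <- scaleParams(x)
           xs <- applyScale(x, sc)
           lev <- levels(y)
           pairs <- utils::combn(lev, 2, simplify = FALSE)
           fits <- lapply(pairs, function(pr) {
             sel <- y %in% pr
             e1071::svm(xs[sel, , drop = FALSE],
                        factor(y[sel], levels = pr),
                        kernel = "radial", cost = config$cost,
                        gamma = config$gamma, scale = FALSE)
           })
           list(kind = "MCSVM", fit = fits, pairs = pairs, levels = lev,
                scale = sc)
         })
}

predictOne <- function(model, x) {
  lev <- stageLevels()
  switch(model$kind,
         KNN = {
           p <- predict(model$fit, applyScale(x, model$scale))
           factor(as.character(p), levels = lev)
         },
         DT = {
           df <- data.frame(x, check.names = FALSE)
           p <- predict(model$fit, df, type = "class")
           factor(as.character(p), levels = lev)
         },
         MCSVM = {
           xs <- applyScale(x, model$scale)
           n <- nrow(xs)
           votes <- margin <- matrix(
             0, n, length(model$levels),
             dimnames = list(NULL, model$levels))
           for (b in seq_along(model$fit)) {
             p <- predict(model$fit[[b]], xs, decision.values = TRUE)
             dv <- attr(p, "decision.values")
             # the column name "X/Y" says the sign orientation: d > 0 -> X
             pr <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
             d <- as.numeric(dv)
             votes[, pr[1]] <- votes[, pr[1]] + (d > 0)
             votes[, pr[2]] <- votes[, pr[2]] + (d <= 0)
             margin[, pr[1]] <- margin[, pr[1]] + d
             margin[, pr[2]] <- margin[, pr[2]] - d
           }
           # majority vote; ties broken by the largest aggregate margin
           pick <- vapply(seq_len(n), function(r) {
             v <- votes[r, ]
             top <- which(v == max(v))
             if (length(top) > 1L) top <- top[which.max(margin[r, top])]
             model$levels[top]
           }, character(1))
           factor(pick, levels = lev)
         })
}

scaleParams <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

applyScale <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

featureMatrixOf <- function(se, features = NULL) {
  m <- t(SummarizedExperiment::assay(se, "features"))
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  m
}

#' Tune and train a classifier
#'
#' Seeded random search over the algorithm's hyperparameter space:
#' each sampled configuration is scored by mean stratified k-fold
#' cross-validation misclassification loss on the training table; the best
#' configuration (ties to the earlier draw) is refit on the full training
#' table. With `tuningBudget = 0` the space defaults are used directly.
#'
#' @param spec a [classifierSpec()].
#' @param train training feature table (`SummarizedExperiment`) containing
#'   every stage.
#' @param features optional character vector restricting the feature panel
#'   (e.g. a selection result's retained set).
#' @return a list of class `plaqueModel` with the fitted model, the chosen
#'   configuration, the full tuning trace (configuration and CV loss),
#'   training accuracy and cross-validated accuracy.
#' @export
tuneAndTrain <- function(spec, train, features = NULL) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  x <- featureMatrixOf(train, features)
  y <- factor(train$label, levels = stageLevels())
  if (any(table(y) == 0)) stop("training table must contain every stage")
  keepcol <- apply(x, 2, function(v) sd(v) > 0)
  x <- x[, keepcol, drop = FALSE]
  if (ncol(x) == 0) stop("no informative features in the training table")

  withr::with_seed(spec$seed, {
    folds <- integer(length(y))
    for (s in levels(y)) {
      idx <- sample(which(y == s))
      folds[idx] <- rep_len(seq_len(spec$cvFolds), length(idx))
    }
    configs <- if (spec$tuningBudget == 0L) {
      list(defaultConfig(spec$algorithm, ncol(x)))
    } else {
      replicate(spec$tuningBudget, sampleConfig(spec$algorithm),
                simplify = FALSE)
    }
    losses <- vapply(configs, function(cf) {
      errs <- vapply(seq_len(spec$cvFolds), function(f) {
        ho <- folds == f
        if (!any(ho) || length(unique(y[!ho])) < 3L) return(NA_real_)
        m <- fitOne(spec$algorithm, cf, x[!ho, , drop = FALSE], y[!ho])
        mean(predictOne(m, x[ho, , drop = FALSE]) != y[ho])
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
  })
  best <- which.min(losses)
  fit <- fitOne(spec$algorithm, configs[[best]], x, y)
  trainAcc <- mean(predictOne(fit, x) == y)
  trace <- data.frame(
    config = vapply(configs, function(cf)
      paste(sprintf("%s=%s", names(cf),
                    vapply(cf, function(v) format(v, digits = 4),
                           character(1))),
            collapse = ", "), character(1)),
    cvLoss = losses)
  structure(list(algorithm = spec$algorithm, model = fit,
                 config = configs[[best]], trace = trace,
                 features = colnames(x),
                 trainAccuracy = trainAcc,
                 cvAccuracy = 1 - losses[best], spec = spec),
            class = "plaqueModel")
}

#' Predict stage labels
#'
#' @param model a `plaqueModel` from [tuneAndTrain()].
#' @param newdata feature table (`SummarizedExperiment`), numeric matrix
#'   with named columns, or a single named feature vector.
#' @return factor of predicted stages.
#' @export
predictStage <- function(model, newdata) {
  stopifnot(inherits(model, "plaqueModel"))
  if (is(newdata, "SummarizedExperiment"))
    newdata <- featureMatrixOf(newdata)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  if (!all(model$features %in% colnames(newdata)))
    stop("newdata is missing model features: ",
         paste(setdiff(model$features, colnames(newdata)), collapse = ", "))
  predictOne(model$model, newdata[, model$features, drop = FALSE])
}

#' Metrics from a 3x3 confusion matrix
#'
#' Per-class accuracy (correct within class / class size), one-vs-rest
#' precision, recall and F1 (harmonic mean, 0 when undefined), and their
#' macro averages. Rows are truth, columns predictions.
#'
#' @param conf 3x3 count matrix with stage dimnames.
#' @return list with `perClass` (matrix) and `macro` (named numeric).
#' @export
metricsFromConfusion <- function(conf) {
  stopifnot(identical(dim(conf), c(3L, 3L)))
  lev <- stageLevels()
  perClass <- matrix(NA_real_, 3, 4,
                     dimnames = list(lev, c("accuracy", "precision",
                                            "recall", "f1")))
  for (s in lev) {
    tp <- conf[s, s]
    fn <- sum(conf[s, ]) - tp
    fp <- sum(conf[, s]) - tp
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    perClass[s, ] <- c(rec, prec, rec, f1)
  }
  macro <- c(accuracy = sum(diag(conf)) / sum(conf),
             precision = mean(perClass[, "precision"]),
             recall = mean(perClass[, "recall"]),
             f1 = mean(perClass[, "f1"]))
  list(perClass = perClass, macro = macro)
}

#' Evaluate a fitted model on a held-out table
#'
#' @param model a `plaqueModel`.
#' @param test non-empty feature table.
#' @return an [EvaluationReport-class]. The generalization error is the
#'   model's training accuracy minus its mean cross-validation accuracy.
#' @export
evaluateModel <- function(model, test) {
  if (ncol(test) == 0) stop("test table is empty")
  truth <- factor(test$label, levels = stageLevels())
  pred <- predictStage(model, test)
  conf <- table(truth = truth, pred = pred)
  conf <- unclass(conf)[stageLevels(), stageLevels()]
  met <- metricsFromConfusion(conf)
  new("EvaluationReport", confusion = conf, perClass = met$perClass,
      macro = met$macro,
      generalizationError = model$trainAccuracy - model$cvAccuracy)
}

#' Serialize an EvaluationReport to JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(
    list(confusion = as.data.frame.matrix(report@confusion),
         per_class = as.data.frame(report@perClass),
         macro = as.list(report@macro),
         generalization_error = report@generalizationError),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
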