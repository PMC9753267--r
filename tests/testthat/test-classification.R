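# Splitting, tuning, prediction and evaluation

test_that("stratified 60/20/20 split gives exact sizes on balanced data", {
  se <- separableCloudsSE(nPerClass = 20)
  sp <- splitDataset(se, seed = 4)
  expect_equal(ncol(sp$train), 36L)
  expect_equal(ncol(sp$test), 12L)
  expect_equal(ncol(sp$val), 12L)
  for (part in sp)
    expect_equal(unname(table(part$label)[stageLevels()]),
                 rep(ncol(part) / 3, 3), ignore_attr = TRUE)
  expect_error(splitDataset(se, c(train = 0.5, test = 0.2, val = 0.2)),
               "sum to 1")
})

test_that("splits are deterministic, disjoint and exhaustive", {
  se <- separableCloudsSE(nPerClass = 17) # awkward class size
  for (seed in c(1, 2, 99)) {
    sp1 <- splitDataset(se, seed = seed)
    sp2 <- splitDataset(se, seed = seed)
    expect_identical(lapply(sp1, colnames), lapply(sp2, colnames))
    all_ids <- unlist(lapply(sp1, colnames))
    expect_length(all_ids, ncol(se))
    expect_length(unique(all_ids), ncol(se))
  }
})

test_that("566 rows split by the largest-remainder rule", {
  labels <- rep(stageLevels(), times = c(214, 134, 218))
  feat <- matrix(rnorm(27 * 566), 27, 566,
                 dimnames = list(featurePanelNames(), NULL))
  se <- makeFeatureSE(feat, labels)
  sp <- splitDataset(se, seed = 7)
  sizes <- vapply(sp, ncol, integer(1))
  expect_equal(sum(sizes), 566L)
  # per class: floor + largest remainder, ties in train/test/val order
  lr <- function(n, f = c(0.6, 0.2, 0.2)) {
    cnt <- floor(f * n); rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(f * n - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    cnt
  }
  want <- lr(214) + lr(134) + lr(218)
  expect_equal(unname(sizes), want)
})

test_that("kNN achieves zero CV loss on separable clouds; k=1 memorizes", {
  se <- separableCloudsSE(nPerClass = 12)
  spec <- classifierSpec("KNN", tuningBudget = 8, cvFolds = 4, seed = 2)
  model <- tuneAndTrain(spec, se)
  expect_equal(min(model$trace$cvLoss), 0)
  expect_equal(model$cvAccuracy, 1)
  # a 1-NN queried at an exact training point returns that point's label
  spec1 <- classifierSpec("KNN", tuningBudget = 0, cvFolds = 4, seed = 2)
  m1 <- tuneAndTrain(spec1, se)
  m1$model$fit$k <- 1L # query the fitted gknn at k = 1 semantics
  x <- t(SummarizedExperiment::assay(se))[, m1$features]
  p <- predictStage(m1, x[3, , drop = FALSE])
  expect_equal(as.character(p), se$label[3])
})

test_that("tuning is deterministic given the tuning seed", {
  se <- separableCloudsSE(nPerClass = 10)
  spec <- classifierSpec("DT", tuningBudget = 6, cvFolds = 3, seed = 11)
  m1 <- tuneAndTrain(spec, se)
  m2 <- tuneAndTrain(spec, se)
  expect_identical(m1$config, m2$config)
  expect_identical(m1$trace, m2$trace)
  expect_error(tuneAndTrain(spec, se[, se$label != "EF"]), "every stage")
})

test_that("budget 0 trains at the space defaults", {
  se <- separableCloudsSE(nPerClass = 8)
  m <- tuneAndTrain(classifierSpec("DT", tuningBudget = 0, cvFolds = 3,
                                   seed = 1), se)
  expect_equal(nrow(m$trace), 1L)
  expect_equal(m$config$maxdepth, 10L)
})

test_that("a decision tree flips its label exactly at the threshold", {
  labels <- rep(c("EFS", "AA"), each = 20)
  feat <- matrix(0, 27, 40, dimnames = list(featurePanelNames(), NULL))
  feat["area", ] <- c(seq(1, 20), seq(31, 50))
  se <- makeFeatureSE(feat, c(labels))
  # complete the 3-class schema with a couple of EF rows far away
  feat2 <- cbind(feat, matrix(0, 27, 2))
  feat2["area", 41:42] <- c(1000, 1001)
  se <- makeFeatureSE(feat2, c(labels, "EF", "EF"))
  m <- tuneAndTrain(classifierSpec("DT", tuningBudget = 0, cvFolds = 3,
                                   seed = 3), se, features = "area")
  thr <- m$model$fit$splits[1, "index"]
  lo <- matrix(thr - 0.5, 1, 1, dimnames = list(NULL, "area"))
  hi <- matrix(thr + 0.5, 1, 1, dimnames = list(NULL, "area"))
  expect_false(as.character(predictStage(m, lo)) ==
                 as.character(predictStage(m, hi)))
})

test_that("one-vs-one SVM decodes by vote with margin tie-breaks", {
  # tight clusters at the vertices of an equilateral triangle
  withr::with_seed(5, {
    ang <- c(90, 210, 330) * pi / 180
    ctr <- cbind(cos(ang), sin(ang)) * 10
    labels <- rep(stageLevels(), each = 10)
    feat <- matrix(0, 27, 30, dimnames = list(featurePanelNames(), NULL))
    for (k in 1:3) {
      idx <- which(labels == stageLevels()[k])
      feat["area", idx] <- ctr[k, 1] + rnorm(10, 0, 0.3)
      feat["perimeter", idx] <- ctr[k, 2] + rnorm(10, 0, 0.3)
    }
    se <- makeFeatureSE(feat, labels)
  })
  m <- tuneAndTrain(classifierSpec("MCSVM", tuningBudget = 5, cvFolds = 3,
                                   seed = 8), se,
                    features = c("area", "perimeter"))
  # each vertex is classified as its own class
  for (k in 1:3) {
    q <- matrix(ctr[k, ], 1, 2, dimnames = list(NULL, c("area",
                                                        "perimeter")))
    expect_equal(as.character(predictStage(m, q)), stageLevels()[k])
  }
  # at the centroid every pairwise vote can disagree (a voting cycle);
  # the margin tie-break must still yield one deterministic stage
  q0 <- matrix(0, 1, 2, dimnames = list(NULL, c("area", "perimeter")))
  p1 <- predictStage(m, q0); p2 <- predictStage(m, q0)
  expect_identical(p1, p2)
  expect_true(as.character(p1) %in% stageLevels())
  # nudging the query toward a vertex resolves the tie toward that class
  for (k in 1:3) {
    qk <- matrix(ctr[k, ] * 0.25, 1, 2,
                 dimnames = list(NULL, c("area", "perimeter")))
    expect_equal(as.character(predictStage(m, qk)), stageLevels()[k])
  }
})

test_that("evaluation metrics match hand-computed confusion matrices", {
  conf <- matrix(c(50, 3, 2,
                   4, 40, 6,
                   1, 5, 44), 3, 3, byrow = TRUE,
                 dimnames = list(stageLevels(), stageLevels()))
  met <- metricsFromConfusion(conf)
  expect_equal(unname(met$perClass["EFS", "recall"]), 50 / 55)
  expect_equal(unname(met$perClass["EFS", "precision"]), 50 / 55)
  expect_equal(unname(met$perClass["EF", "recall"]), 40 / 50)
  expect_equal(unname(met$perClass["EF", "precision"]), 40 / 48)
  f1 <- 2 * (40 / 48) * (40 / 50) / ((40 / 48) + (40 / 50))
  expect_equal(unname(met$perClass["EF", "f1"]), f1)
  expect_equal(unname(met$macro["accuracy"]), (50 + 40 + 44) / sum(conf))
  # constant AA predictor on a balanced test set
  confAA <- matrix(0, 3, 3, dimnames = list(stageLevels(), stageLevels()))
  confAA[, "AA"] <- 30
  mAA <- metricsFromConfusion(confAA)
  expect_equal(unname(mAA$perClass["AA", "recall"]), 1)
  expect_equal(unname(mAA$perClass["AA", "precision"]), 1 / 3)
  expect_equal(unname(mAA$perClass["EFS", "f1"]), 0)
  # random confusion matrices against naive formulas
  withr::with_seed(14, {
    for (rep in 1:20) {
      cf <- matrix(rpois(9, 20), 3, 3,
                   dimnames = list(stageLevels(), stageLevels()))
      met <- metricsFromConfusion(cf)
      for (s in 1:3) {
        tp <- cf[s, s]
        expect_equal(unname(met$perClass[s, "recall"]), tp / sum(cf[s, ]))
        expect_equal(unname(met$perClass[s, "precision"]),
                     if (sum(cf[, s]) > 0) tp / sum(cf[, s]) else 0)
      }
    }
  })
})

test_that("a perfect model evaluates to an all-diagonal report", {
  se <- separableCloudsSE(nPerClass = 14)
  sp <- splitDataset(se, seed = 6)
  m <- tuneAndTrain(classifierSpec("KNN", tuningBudget = 12, cvFolds = 3,
                                   seed = 6), sp$train)
  rep <- evaluateModel(m, sp$test)
  expect_equal(sum(confusionMatrix(rep)) - sum(diag(confusionMatrix(rep))),
               0)
  expect_equal(unname(classMetrics(rep)[, "accuracy"]), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(generalizationError(rep),
               m$trainAccuracy - m$cvAccuracy)
  expect_error(evaluateModel(m, se[, 0]), "empty")
})
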