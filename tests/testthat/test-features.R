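# The 27-feature morphology panel

test_that("FOS statistics on a constant region use the documented sentinels", {
  img <- matrix(0L, 20, 20); mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE; img[mask] <- 500L
  f <- extractFOS(img, mask)
  expect_equal(unname(f["mean_intensity"]), 500)
  expect_equal(unname(f["std_dev"]), 0)
  expect_equal(unname(f["integrated_density"]), 50000)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
  expect_error(extractFOS(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("object count follows 8-connected components of the mask", {
  img <- matrix(100L, 12, 12); mask <- matrix(FALSE, 12, 12)
  mask[1:2, 1:2] <- TRUE; mask[5:6, 5:6] <- TRUE; mask[9:10, 9:10] <- TRUE
  expect_equal(unname(extractFOS(img, mask)["n_objects"]), 3)
})

test_that("skewness and kurtosis match two-point closed forms", {
  withr::with_seed(13, {
    n <- 100
    img <- matrix(sample(c(100L, 300L), n * n, replace = TRUE), n, n)
  })
  f <- extractFOS(img, matrix(TRUE, 100, 100))
  # symmetric two-point distribution: skewness 0, kurtosis (m4/m2^2) = 1
  expect_lt(abs(f[["skewness"]]), 0.05)
  expect_lt(abs(f[["kurtosis"]] - 1), 0.1)
})

test_that("shape descriptors: rectangle, square, digital disk", {
  full <- matrix(TRUE, 8, 13)
  s <- extractShape(full)
  expect_equal(unname(s["extent"]), 1)
  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  expect_equal(unname(extractShape(sq)["area"]), 100)
  disc <- discMask(50L)
  sd_ <- extractShape(disc)
  expect_gt(unname(sd_["circularity"]), 0.9)
  expect_lt(unname(sd_["circularity"]), 1.1)
  # perimeter against the analytic circumference of the traced circle
  expect_lt(abs(sd_[["perimeter"]] - 2 * pi * 50) / (2 * pi * 50), 0.05)
})

test_that("co-occurrence matrices: checkerboard, constant, normalization", {
  chk <- outer(1:6, 1:6, "+") %% 2L
  P <- computeGLCM(chk, 1, 0, nLevels = 2)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1] + P[2, 2], 0)
  cst <- matrix(5L, 5, 5)
  Pc <- computeGLCM(cst, 1, 90, nLevels = 4)
  expect_equal(unname(Pc[1, 1]), 1)
  withr::with_seed(2, w <- matrix(sample.int(1000, 81), 9, 9))
  for (a in c(0, 45, 90, 135)) {
    Pr <- computeGLCM(w, 1, a, nLevels = 8)
    expect_equal(sum(Pr), 1, tolerance = 1e-12)
    expect_equal(Pr, t(Pr), tolerance = 1e-12)
  }
  expect_error(computeGLCM(matrix(1:2, 1, 2), 1, 90, 2), "offset reach")
})

test_that("Haralick features of degenerate and checkerboard matrices", {
  Pc <- computeGLCM(matrix(5L, 5, 5), 1, 0, nLevels = 4)
  h <- haralickFeatures(Pc)
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["homogeneity"]), 1)
  expect_equal(unname(h["max_probability"]), 1)
  expect_equal(unname(h["correlation"]), 0) # degenerate convention
  chk <- outer(1:6, 1:6, "+") %% 2L
  hc <- haralickFeatures(computeGLCM(chk, 1, 0, nLevels = 2))
  expect_equal(unname(hc["contrast"]), 1)
  expect_equal(unname(hc["dissimilarity"]), 1)
  expect_equal(unname(hc["energy"]), 0.5)
})

test_that("Haralick features equal a naive double-loop oracle", {
  withr::with_seed(77, {
    for (rep in 1:200) {
      G <- sample(c(4L, 8L), 1)
      P <- randomGLCM(G)
      expect_equal(haralickFeatures(P), oracleHaralick(P),
                   tolerance = 1e-10)
    }
  })
})

test_that("sliding-window texture panel matches the R composition", {
  withr::with_seed(31, img <- matrix(sample.int(4000, 81), 9, 9))
  mask <- matrix(FALSE, 9, 9); mask[5, 5] <- TRUE
  got <- extractTexture(img, mask, glcmConfig(windowSize = 9, nLevels = 8))
  byHand <- rowMeans(vapply(c(0, 45, 90, 135), function(a)
    haralickFeatures(computeGLCM(img, 1, a, nLevels = 8,
                                 lo = min(img), hi = max(img))),
    numeric(17)))
  expect_equal(unname(got), unname(byHand), tolerance = 1e-8)
})

test_that("texture panel of a homogeneous plaque is degenerate", {
  img <- matrix(30000L, 24, 24)
  mask <- matrix(FALSE, 24, 24); mask[9:15, 9:15] <- TRUE
  tx <- extractTexture(img, mask, glcmConfig())
  expect_equal(unname(tx["energy"]), 1)
  expect_equal(unname(tx["entropy"]), 0)
  expect_length(tx, 17L)
  expect_identical(names(tx), featurePanelNames()[11:27])
})

test_that("offset averaging is near-inert on an isotropic random field", {
  withr::with_seed(55, img <- matrix(sample.int(1000, 441, TRUE), 21, 21))
  perOffset <- vapply(c(0, 45, 90, 135), function(a)
    haralickFeatures(computeGLCM(img, 1, a, nLevels = 8,
                                 lo = min(img), hi = max(img))),
    numeric(17))
  ctr <- perOffset["contrast", ]
  expect_lt((max(ctr) - min(ctr)) / mean(ctr), 0.15)
})

test_that("the full panel has 27 entries, is deterministic and scales", {
  rec <- generatePhantom(phantomConfig(imageWidth = 64L, imageHeight = 64L),
                         "EF", seed = 19)
  msk <- truthMask(rec)
  f1 <- extractAll(rec, msk)
  f2 <- extractAll(rec, msk)
  expect_length(f1, 27L)
  expect_identical(names(f1), featurePanelNames())
  expect_identical(f1, f2)
  img <- plaqueImage(rec)
  doubled <- extractAll(img * 2L, msk) # stays within 16-bit range
  for (nm in c("area", "extent", "n_objects", "circularity", "perimeter"))
    expect_equal(doubled[[nm]], f1[[nm]])
  expect_equal(doubled[["mean_intensity"]], 2 * f1[["mean_intensity"]])
  expect_equal(doubled[["integrated_density"]],
               2 * f1[["integrated_density"]])
})

test_that("feature tables round-trip losslessly through CSV", {
  recs <- generateDataset(phantomConfig(imageWidth = 64L,
                                        imageHeight = 64L),
                          c(EFS = 2, EF = 2, AA = 2), seed = 23)
  se <- buildFeatureTable(recs)
  path <- tempfile(fileext = ".csv")
  writeFeatureCSV(se, path)
  back <- readFeatureCSV(path)
  expect_identical(SummarizedExperiment::assay(back, "features"),
                   SummarizedExperiment::assay(se, "features"))
  expect_identical(back$label, se$label)
})
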