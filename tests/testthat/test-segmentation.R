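# Otsu, IFCT, MCW, KMS, active-contour tracing, Dice, labelling

test_that("Otsu separates a two-valued image exactly", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  o <- otsuSegment(img)
  expect_identical(o$mask, img == 200)
  expect_true(o$threshold > 10 && o$threshold < 200)
  expect_error(otsuSegment(matrix(7, 4, 4)), "constant")
})

test_that("Otsu on a tiny multiset matches the exhaustive-search oracle", {
  img <- matrix(c(1, 1, 2, 8, 9, 9), 2, 3)
  o <- otsuSegment(img, nBins = 16L)
  expect_equal(o$threshold, oracleOtsu(img, 16L))
  expect_identical(o$mask, img > o$threshold)
})

test_that("Otsu equals exhaustive search on random 16x16 images", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      nb <- sample(c(32L, 64L, 256L), 1)
      img <- matrix(sample.int(60000, 256, replace = TRUE), 16, 16)
      expect_equal(otsuSegment(img, nb)$threshold, oracleOtsu(img, nb))
    }
  })
})

test_that("Otsu misclassifies < 1% of a well-separated Gaussian mixture", {
  withr::with_seed(8, {
    n <- 1e4
    lab <- rep(c(FALSE, TRUE), each = n)
    v <- round(c(rnorm(n, 1000, 500), rnorm(n, 40000, 500)))
    v <- pmin(pmax(v, 0), 65535)
    img <- matrix(v, 200, 100)
    o <- otsuSegment(img)
    expect_lt(mean(o$mask != matrix(lab, 200, 100)), 0.01)
  })
})

test_that("Dice scores identical, disjoint and half-overlapping masks", {
  m <- matrix(FALSE, 20, 20)
  a <- m; a[1:10, 1:10] <- TRUE
  b <- m; b[6:15, 1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  d <- m; d[15:20, 15:20] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(dice(a, b), 0.5) # |a|=|b|=100, overlap 50
  expect_equal(dice(m, m), 1)   # both empty, by convention
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("component labelling respects connectivity", {
  m <- matrix(FALSE, 10, 10)
  expect_equal(labelComponents(m)$n, 0L)
  m[1:2, 1:2] <- TRUE; m[5:6, 5:6] <- TRUE; m[9:10, 9:10] <- TRUE
  expect_equal(labelComponents(m)$n, 3L)
  diagm <- matrix(FALSE, 4, 4)
  diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_equal(labelComponents(diagm, 8)$n, 1L)
  expect_equal(labelComponents(diagm, 4)$n, 2L)
  lab <- labelComponents(m)$labels
  expect_setequal(unique(lab[lab > 0]), 1:3)
})

test_that("IFCT with a single candidate reduces to local Otsu of its box", {
  b <- blobImage(n = 64, r = 10, level = 20000, noiseSD = 0, seed = 2)
  m <- ifctSegment(b$img, candidateQuantile = 0.9, minArea = 5)
  seedThr <- quantile(b$img, 0.9, names = FALSE)
  cand <- labelComponents(b$img > seedThr)
  expect_equal(cand$n, 1L)
  px <- which(cand$labels == 1, arr.ind = TRUE)
  rr <- range(px[, 1]); cc <- range(px[, 2])
  sub <- b$img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  loc <- otsuSegment(sub)
  expect_identical(m[rr[1]:rr[2], cc[1]:cc[2]], loc$mask)
  outside <- m; outside[rr[1]:rr[2], cc[1]:cc[2]] <- FALSE
  expect_false(any(outside))
})

test_that("IFCT recovers a dim blob that global Otsu misses", {
  withr::with_seed(4, {
    n <- 64
    img <- matrix(round(rnorm(n * n, 500, 20)), n, n)
  })
  add_blob <- function(img, cx, cy, lvl, r = 6) {
    xs <- matrix(rep(seq_len(nrow(img)), each = nrow(img)), nrow(img))
    ys <- matrix(rep(seq_len(nrow(img)), nrow(img)), nrow(img))
    sup <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    img[sup] <- lvl
    img
  }
  img <- add_blob(img, 16, 16, 60000)
  img <- add_blob(img, 48, 48, 8000)
  glob <- otsuSegment(img)$mask
  expect_equal(labelComponents(glob)$n, 1L) # only the bright blob
  m <- ifctSegment(img, candidateQuantile = 0.9, minArea = 10)
  expect_equal(labelComponents(m)$n, 2L)
})

test_that("IFCT returns an empty mask on background-only images", {
  withr::with_seed(10, img <- matrix(round(rnorm(900, 500, 30)), 30, 30))
  m <- ifctSegment(img, minArea = 20)
  expect_false(any(m))
})

test_that("MCW recovers a single blob and splits twin peaks", {
  b <- blobImage(n = 96, r = 16, level = 30000, seed = 3)
  m <- mcwSegment(b$img)
  expect_gte(dice(m, b$mask), 0.8)
  expect_false(any(mcwSegment(matrix(100L, 40, 40))))
  # two overlapping blobs with distinct peaks split into >= 2 components
  two <- blobImage(n = 96, cx = 38, cy = 48, r = 14, level = 30000,
                   seed = 5)
  two2 <- blobImage(n = 96, cx = 62, cy = 48, r = 14, level = 28000,
                    seed = 6)
  img <- pmax(two$img, two2$img)
  m2 <- mcwSegment(img)
  expect_gte(labelComponents(m2)$n, 2L)
})

test_that("KMS is seed-deterministic and recovers a textured plaque", {
  rec <- generatePhantom(phantomConfig(imageWidth = 96L,
                                       imageHeight = 96L), "AA", seed = 21)
  img <- preprocessImage(plaqueImage(rec))
  m1 <- kmsSegment(img, seed = 4)
  m2 <- kmsSegment(img, seed = 4)
  expect_identical(m1, m2)
  expect_gte(dice(m1, truthMask(rec)), 0.8)
  # k = 1 is degenerate: the single cluster mean equals the overall mean
  expect_false(any(kmsSegment(img, k = 1, seed = 1)))
})

test_that("active-contour tracing refines and is stable at the truth", {
  b <- blobImage(n = 80, r = 14, level = 30000, noiseSD = 50, seed = 9)
  # hard-edged blob: flatten the interior profile
  img <- b$img; img[b$mask] <- pmax(img[b$mask], 25000)
  expect_error(traceReference(img, matrix(FALSE, 80, 80)), "non-empty")
  expect_identical(traceReference(img, b$mask, nIter = 0), b$mask)
  init <- as.matrix(EBImage::dilate(b$mask * 1,
                                    EBImage::makeBrush(9, "disc"))) > 0
  out <- traceReference(img, init, nIter = 50)
  expect_gte(dice(out, b$mask), 0.95)
  stable <- traceReference(img, b$mask, nIter = 25)
  expect_gte(dice(stable, b$mask), 0.99)
})

test_that("segmentImage dispatches on the method name", {
  b <- blobImage(n = 48, r = 8, level = 20000, seed = 12)
  expect_identical(segmentImage(b$img, "ots"), otsuSegment(b$img)$mask)
  expect_identical(segmentImage(b$img, "kms", seed = 2),
                   kmsSegment(b$img, seed = 2))
})

test_that("mean Dice over strong-separation phantoms is high for ots, mcw
          and kms, and Otsu ranks best", {
  cfg <- strongSeparationConfig(imageWidth = 96L, imageHeight = 96L)
  recs <- generateDataset(cfg, c(EFS = 17, EF = 17, AA = 17), seed = 77)
  score <- function(fun) {
    mean(vapply(seq_along(recs), function(i) {
      img <- preprocessImage(plaqueImage(recs[[i]]))
      dice(fun(img, i), truthMask(recs[[i]]))
    }, numeric(1)))
  }
  dOts <- score(function(img, i) otsuSegment(img)$mask)
  dMcw <- score(function(img, i) mcwSegment(img))
  dKms <- score(function(img, i) kmsSegment(img, seed = i))
  dIfct <- score(function(img, i) ifctSegment(img))
  expect_gte(dOts, 0.7)
  expect_gte(dMcw, 0.7)
  expect_gte(dKms, 0.7)
  # qualitative ranking: Otsu is not beaten by watershed or k-means
  # (thresholding methods saturate on these phantoms, so allow ties)
  expect_gte(dOts, max(dMcw, dKms) - 0.01)
  expect_gte(dIfct, 0.5)
})
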