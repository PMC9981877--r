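test_that("membrane segmentation recovers the truth mask", {
  cfg <- cfgSmall()
  rec <- reconstructStack(stackSmall(), apodizeTaper = 0.4)
  seg <- segmentMembrane(rec@kMap)
  tr <- lsecSmall()@truthLabels
  trMem <- tr == 1L | tr == 3L           # clusters live on the membrane
  jac <- sum(seg == 1L & trMem) / sum(seg == 1L | trMem)
  expect_gt(jac, 0.8)
  ## classes are exclusive and exhaustive
  expect_true(all(seg %in% c(0L, 1L, 2L)))
  ## flat map is all background
  expect_true(all(segmentMembrane(matrix(0, 64, 64)) == 0L))
})

test_that("the sliding paraboloid separates peaks from smooth backgrounds", {
  cst <- matrix(1.5, 48, 48)
  sp <- slidingParaboloidBackground(cst, 10)
  expect_equal(sp$background, cst)
  expect_true(all(sp$residual == 0))

  ## a single narrow peak on a flat base is fully assigned to the residual
  base <- matrix(0.5, 64, 64); base[32, 32] <- 2
  sp <- slidingParaboloidBackground(base, 10)
  expect_lt(max(abs(sp$background - 0.5)), 0.02)
  expect_gt(sp$residual[32, 32], 1.4)

  ## a gentle image-wide ramp is absorbed into the background (away from the
  ## finite-domain boundary, where the sliding element is one-sided)
  ramp <- matrix(rep(seq(0, 0.1, length.out = 64), each = 64), 64, 64)
  sp <- slidingParaboloidBackground(ramp, 10)
  expect_lt(max(sp$residual[, 1:40]), 1e-9)
  expect_lt(mean(sp$residual), 0.1 * 0.05)

  ## invariants: background below the image; opening idempotent
  withr::with_seed(6, {
    und <- outer(sin(seq(0, 3, length.out = 96)),
                 cos(seq(0, 2, length.out = 96))) * 0.3
    und[20, 20] <- und[20, 20] + 2
    und[70, 40] <- und[70, 40] + 1.5
    sp1 <- slidingParaboloidBackground(und, 10)
    expect_true(all(sp1$background <= und + 1e-12))
    expect_true(all(sp1$residual >= 0))
    sp2 <- slidingParaboloidBackground(sp1$background, 10)
    expect_lt(max(abs(sp2$background - sp1$background)), 1e-5 * diff(range(und)))
  })
})

test_that("prominence detection matches the printed two-bump arithmetic", {
  f <- twoBumpFixture()                   # peaks 3e-4, valley 1e-4
  d1 <- detectClusters(f, 1.5e-4)
  expect_identical(nrow(d1), 2L)
  d2 <- detectClusters(f, 2.5e-4)         # lower bump's prominence is ~2e-4
  expect_identical(nrow(d2), 1L)
  expect_identical(nrow(detectClusters(matrix(1, 32, 32), 1e-6)), 0L)
})

test_that("flood-based prominence agrees exactly with the brute-force oracle", {
  withr::with_seed(13, {
    for (rep in 1:3) {
      f <- EBImage::imageData(EBImage::gblur(EBImage::Image(matrix(runif(24 * 24), 24, 24)),
                                    sigma = 1.2))
      oracle <- bruteForceProminence(f)
      mine <- detectClusters(f, prominence = 1e-12)
      oracle <- oracle[order(oracle$row, oracle$col), ]
      mineS <- mine[order(mine$row, mine$col), ]
      expect_identical(nrow(mineS), nrow(oracle))
      expect_identical(mineS$row, oracle$row)
      expect_identical(mineS$col, oracle$col)
      expect_equal(mineS$prominence, oracle$prominence, tolerance = 1e-12)
    }
  })
})

test_that("detection is monotone in prominence and offset-invariant", {
  withr::with_seed(17, {
    f <- EBImage::imageData(EBImage::gblur(EBImage::Image(matrix(runif(48 * 48), 48, 48)),
                                  sigma = 1.5))
    counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(pr)
      nrow(detectClusters(f, pr)), integer(1))
    expect_true(all(diff(counts) <= 0))
    d0 <- detectClusters(f, 0.05)
    d7 <- detectClusters(f + 7, 0.05)
    expect_identical(d0$row, d7$row)
    expect_equal(d7$value, d0$value + 7, tolerance = 1e-12)
  })
})

test_that("planted fenestration clusters are counted and ranked correctly", {
  n <- 384L
  cfg <- acquisitionConfig(imageShape = c(n, n), pixelSizeNm = 100)
  ph <- makeLsecPhantom(shape = c(n, n), nClusters = 60, seed = 11,
                        clusterRadiusRangeNm = c(450, 700), clusterK = 6e-4)
  rec <- reconstructStack(acquireStack(ph, cfg), apodizeTaper = 0.4)
  sc <- ph@meta$membraneThicknessNm / (depthOfField(cfg) * 1000)
  rep <- analyzeFenestrations(rec, prominence = 0.4 * (6e-4 - 2.7e-4) * sc,
                              maskErodePx = 5, minDistancePx = 9)
  planted <- nrow(ph@truthClusters)
  expect_lt(abs(rep@nClusters - planted) / planted, 0.10)
  expect_gt(rep@clusterMean, rep@membraneMean)
  expect_identical(rep@nClusters, length(rep@clusterK))
})

test_that("a cluster-free phantom yields an empty fenestration report", {
  cfg <- cfgSmall()
  ph <- makeLsecPhantom(shape = c(128L, 128L), nClusters = 0, seed = 2)
  rec <- reconstructStack(acquireStack(ph, cfg), apodizeTaper = 0.4)
  rep <- analyzeFenestrations(rec, prominence = 0.00015)
  expect_identical(rep@nClusters, 0L)
})
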