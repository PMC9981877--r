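test_that("flat-field correction is exact, linear and guards its inputs", {
  cfg <- cfgSmall()
  st <- stackSmall()
  d <- flatfieldCorrect(st)
  expect_length(d, 4)

  stId <- st
  attr(stId, "images") <- st@backgrounds
  expect_true(all(vapply(flatfieldCorrect(stId),
                         function(m) max(abs(m)) == 0, logical(1))))
  st11 <- st
  attr(st11, "images") <- lapply(st@backgrounds, function(b) 1.1 * b)
  expect_true(all(vapply(flatfieldCorrect(st11),
                         function(m) max(abs(m - 0.1)) < 1e-12, logical(1))))
  ## linearity in I at fixed B
  stAB <- st
  attr(stAB, "images") <- lapply(seq_along(st@images), function(i)
    2 * st@images[[i]] + 3 * st@backgrounds[[i]])
  dAB <- flatfieldCorrect(stAB)
  for (i in 1:4) expect_equal(dAB[[i]], 2 * d[[i]] + 4, tolerance = 1e-9)

  stBad <- st
  bg <- st@backgrounds; bg[[2]][5, 7] <- 0
  attr(stBad, "backgrounds") <- bg
  expect_error(flatfieldCorrect(stBad), "\\(5, 7\\)")
})

test_that("the regularized inversion recovers a known weak object", {
  cfg <- cfgSmall()
  obj <- phantomToEffectiveObject(lsecSmall(), cfg)
  st <- stackSmall()
  rec <- reconstructStack(st, tauAbs = 1e-6, tauPh = 1e-6)
  cut <- 2 * cfg@na / cfg@wavelengthNm
  muT <- bandLimit(obj@mu, 100, cut)
  phT <- bandLimit(obj@phi - mean(obj@phi), 100, cut)
  expect_lt(relRMS(rec@mu, muT), 0.01)
  expect_lt(relRMS(rec@phi - mean(rec@phi), phT), 0.01)

  ## all-zero differences give all-zero maps
  tfs <- lapply(c(0, 90, 180, 270), function(a)
    computeWOTF(makeHalfringSource(pupilSmall(), a), pupilSmall()))
  z <- lapply(1:4, function(i) matrix(0, 128, 128))
  sol0 <- solveQDPC(z, tfs, 1, 1)
  expect_true(max(abs(sol0$mu)) == 0 && max(abs(sol0$phi)) == 0)

  ## tau -> infinity suppresses the solution entirely
  d <- flatfieldCorrect(st)
  solInf <- solveQDPC(d, tfs, 1e18, 1e18)
  expect_lt(max(abs(solInf$mu)), 1e-6 * max(abs(rec@mu)))

  ## unregularized normal equations are singular outside the passband
  expect_error(solveQDPC(d, tfs, 0, 0), "regularization required")
})

test_that("extinction conversion and its scaling behave as documented", {
  cfg <- acquisitionConfig()
  expect_equal(muToK(0.0210, cfg, pathLengthNm = 2 * 1355), 3.4e-4,
               tolerance = 1e-2)
  ## default path length is twice the depth of field
  expect_equal(muToK(1, cfg), 1 * 275 / (2 * pi * 2 * depthOfField(cfg) * 1000))
  expect_identical(muToK(0, cfg), 0)
  expect_equal(muToK(0.02, cfg, pathLengthNm = 1000),
               2 * muToK(0.02, cfg, pathLengthNm = 2000))
})

test_that("the full pipeline is quantitative on synthetic cells", {
  cfg <- cfgSmall()
  ph <- lsecSmall()
  rec <- reconstructStack(stackSmall())   # default tau = 300
  expect_gt(cor(as.vector(rec@kMap), as.vector(ph@kMap)), 0.9)

  ## ordering of median recovered extinction follows the sample structure
  lb <- ph@truthLabels
  meds <- c(median(rec@kMap[lb == 0]), median(rec@kMap[lb == 1]),
            median(rec@kMap[lb == 2]))
  expect_true(meds[1] < meds[2] && meds[2] < meds[3])

  ## background-only stack reconstructs to (numerically) zero extinction
  empty <- makeLsecPhantom(shape = c(128L, 128L), nClusters = 0, seed = 2)
  attr(empty, "kMap") <- matrix(0, 128, 128)
  attr(empty, "deltaN") <- matrix(0, 128, 128)
  attr(empty, "truthLabels") <- matrix(0L, 128, 128)
  recE <- reconstructStack(acquireStack(empty, cfg))
  expect_lt(max(abs(recE@kMap)), 1e-6)
})

test_that("reconstruction is linear and degrades gracefully with noise", {
  cfg <- cfgSmall()
  p1 <- lsecSmall()
  p2 <- makeBeadPhantom(shape = c(128L, 128L), nBeads = 40, seed = 9)
  r1 <- reconstructStack(acquireStack(p1, cfg))
  r2 <- reconstructStack(acquireStack(p2, cfg))
  ## sum of stacks (images summed minus one background) reconstructs to the
  ## sum of reconstructions at fixed tau
  stSum <- acquireStack(p1, cfg)
  st2 <- acquireStack(p2, cfg)
  attr(stSum, "images") <- lapply(1:4, function(i)
    stSum@images[[i]] + st2@images[[i]] - 1)
  rSum <- reconstructStack(stSum)
  expect_lt(max(abs(rSum@kMap - (r1@kMap + r2@kMap))) /
            max(abs(r1@kMap + r2@kMap)), 1e-6)

  ## recovery error is monotonically non-decreasing in the noise level
  obj <- phantomToEffectiveObject(p1, cfg)
  cut <- 2 * cfg@na / cfg@wavelengthNm
  muT <- bandLimit(obj@mu, 100, cut)
  errs <- vapply(c(Inf, 5e4, 5e3, 5e2), function(ps) {
    st <- acquireStack(p1, cfg, photonScale = if (is.finite(ps)) ps else NULL,
                       seed = 21)
    relRMS(reconstructStack(st)@mu, muT)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
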