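test_that("the linearized forward model honors its limit cases", {
  cfg <- cfgSmall(); p <- pupilSmall()
  s <- makeHalfringSource(p, 30)
  tf <- computeWOTF(s, p)
  zero <- new("EffectiveObject", phi = matrix(0, 128, 128),
              mu = matrix(0, 128, 128), pixelSizeNm = 100)
  I0 <- forwardWOTF(zero, s, p, cfg, transfer = tf)
  expect_equal(max(abs(I0 - tf@background)), 0, tolerance = 1e-9)

  ## pure weak absorber darkens the image (up to band-limit ringing)
  obj <- phantomToEffectiveObject(lsecSmall(), cfg)
  abs_ <- new("EffectiveObject", phi = matrix(0, 128, 128), mu = obj@mu,
              pixelSizeNm = 100)
  Ia <- forwardWOTF(abs_, s, p, cfg, transfer = tf)
  expect_lt(mean(Ia), tf@background)
  expect_lt(max(Ia), tf@background * (1 + 0.01))

  ## pure phase object is invisible under a symmetric (full-ring) source
  sF <- s; sF@values <- Mod(p@values)
  ph <- new("EffectiveObject", phi = obj@phi, mu = matrix(0, 128, 128),
            pixelSizeNm = 100)
  Ip <- forwardWOTF(ph, sF, p, cfg)
  BF <- sum(sF@values * Mod(p@values)^2)
  expect_lt(max(abs(Ip - BF)) / BF, 1e-9)
})

test_that("the Abbe oracle agrees with the linearized model for weak objects", {
  cfg <- cfgSmall(); p <- pupilSmall()
  s <- makeHalfringSource(p, 30)
  tf <- computeWOTF(s, p)

  ## empty object: flat field equal to B within 1e-6 relative
  zero <- new("EffectiveObject", phi = matrix(0, 128, 128),
              mu = matrix(0, 128, 128), pixelSizeNm = 100)
  Ie <- forwardAbbe(zero, s, p, cfg, nSourcePoints = 64)
  expect_lt(max(abs(Ie - tf@background)) / tf@background, 1e-6)

  ## weak phantom: < 2% relative RMS, discrepancy shrinking with strength
  base <- phantomToEffectiveObject(lsecSmall(), cfg)
  disc <- vapply(c(1, 0.5, 0.25), function(sc) {
    obj <- new("EffectiveObject", phi = base@phi * sc * 0.25,
               mu = base@mu * sc * 0.25, pixelSizeNm = 100)
    Iw <- forwardWOTF(obj, s, p, cfg, transfer = tf)
    Ib <- forwardAbbe(obj, s, p, cfg, nSourcePoints = NULL)
    sqrt(mean((Iw - Ib)^2)) / tf@background
  }, numeric(1))
  expect_lt(disc[1], 0.02)
  expect_true(all(diff(disc) < 0))              # shrinks with object strength
  ## quadratic shrinkage: halving strength cuts the residual ~4x (superlinear
  ## growth of the discrepancy when the object strengthens)
  expect_gt(disc[1] / disc[2], 2.5)
  expect_gt(disc[2] / disc[3], 2.5)
  expect_warning(forwardAbbe(zero, s, p, cfg, nSourcePoints = 4), "undersampled")
})

test_that("photon noise has the stated mean-variance behavior", {
  img <- matrix(0.8, 64, 64)
  n1 <- addNoise(img, 5000, seed = 3)
  expect_identical(n1, addNoise(img, 5000, seed = 3))
  expect_false(identical(n1, addNoise(img, 5000, seed = 4)))
  ## variance of a flat region ~ mean / photonScale (5% tolerance at n = 65k)
  big <- addNoise(matrix(0.8, 256, 256), 2000, seed = 1)
  expect_lt(abs(var(as.vector(big)) - 0.8 / 2000) / (0.8 / 2000), 0.05)
  expect_equal(mean(big), 0.8, tolerance = 0.005)
  ## high photon budget: image essentially unchanged
  hi <- addNoise(img, 1e9, seed = 2)
  expect_lt(max(abs(hi - img)), 1e-3)
})

test_that("acquired stacks are consistent with their phantom and metadata", {
  cfg <- cfgSmall()
  st <- stackSmall()
  expect_length(st@images, 4)
  expect_length(st@backgrounds, 4)
  expect_identical(st@orientationsDeg, c(0, 90, 180, 270))

  ## empty phantom: every image equals its background
  empty <- makeLsecPhantom(shape = c(128L, 128L), nClusters = 0, seed = 2)
  attr(empty, "kMap") <- matrix(0, 128, 128)
  attr(empty, "deltaN") <- matrix(0, 128, 128)
  attr(empty, "truthLabels") <- matrix(0L, 128, 128)
  stE <- acquireStack(empty, cfg)
  for (i in 1:4)
    expect_lt(max(abs(stE@images[[i]] - stE@backgrounds[[i]])), 1e-9)

  ## permutation invariance after metadata reorder
  st2 <- acquireStack(lsecSmall(), cfg, orientationsDeg = c(180, 0, 270, 90), seed = 5)
  for (i in seq_along(st@orientationsDeg)) {
    j <- match(st@orientationsDeg[i], st2@orientationsDeg)
    expect_equal(st@images[[i]], st2@images[[j]], tolerance = 1e-12)
  }
  expect_error(acquireStack(lsecSmall(), cfg, orientationsDeg = c(0, 360)),
               "distinct")

  ## energy ordering: adding absorption never raises the mean image
  obj <- phantomToEffectiveObject(lsecSmall(), cfg)
  p <- pupilSmall(); s <- makeHalfringSource(p, 0); tf <- computeWOTF(s, p)
  withr::with_seed(8, {
    for (i in 1:3) {
      mu <- matrix(runif(128 * 128, 0, 0.05), 128, 128)
      o1 <- new("EffectiveObject", phi = obj@phi * 0.3, mu = mu, pixelSizeNm = 100)
      o2 <- new("EffectiveObject", phi = obj@phi * 0.3, mu = mu * 1.5, pixelSizeNm = 100)
      expect_lt(mean(forwardWOTF(o2, s, p, cfg, transfer = tf)),
                mean(forwardWOTF(o1, s, p, cfg, transfer = tf)))
    }
  })
})

test_that("opposite orientations cancel the odd phase response", {
  cfg <- cfgSmall(); p <- pupilSmall()
  obj0 <- phantomToEffectiveObject(lsecSmall(), cfg)
  ph <- new("EffectiveObject", phi = obj0@phi * 0.3,
            mu = matrix(0, 128, 128), pixelSizeNm = 100)
  s0 <- makeHalfringSource(p, 0); s180 <- makeHalfringSource(p, 180)
  I0 <- forwardWOTF(ph, s0, p, cfg)
  I180 <- forwardWOTF(ph, s180, p, cfg)
  sSym <- s0; sSym@values <- s0@values + s180@values
  Isym <- forwardWOTF(ph, sSym, p, cfg)
  expect_lt(max(abs((I0 + I180) - Isym)) / mean(Isym), 1e-3)
})
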