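test_that("periodic-smooth decomposition is exact, periodic and linear", {
  withr::with_seed(4, {
    ## an intensity-like image: dominant flat level plus smooth non-periodic
    ## structure, which is what creates the spectral cross artifact
    img <- 100 + outer(seq(0, 2, length.out = 96), seq(1, 3, length.out = 80)) +
      outer(sin(seq(0, 2.5, length.out = 96)), cos(seq(0, 1.7, length.out = 80)))
    ps <- periodicSmoothDecompose(img)
    expect_equal(ps$periodic + ps$smooth, img, tolerance = 1e-12)

    ## the periodic part has matching opposite edges: tiling discontinuity
    ## energy far below both the raw discontinuity and the image energy
    per <- ps$periodic
    edgeE <- sum((per[1, ] - per[96, ])^2) + sum((per[, 1] - per[, 80])^2)
    rawE <- sum((img[1, ] - img[96, ])^2) + sum((img[, 1] - img[, 80])^2)
    expect_lt(edgeE / rawE, 1e-2)
    expect_lt(edgeE / sum(img^2), 1e-8)

    ## constant image: smooth carries it all (up to the mean convention)
    cst <- matrix(3.3, 32, 32)
    psC <- periodicSmoothDecompose(cst)
    expect_lt(max(abs(psC$periodic - mean(psC$periodic))), 1e-12)

    ## a smoothly tiling (DFT-mode) image passes through nearly unchanged;
    ## the decomposition reads the one-step wrap difference as a small jump,
    ## so the agreement is close but not exact
    x <- outer(sin(2 * pi * (0:63) / 64), cos(2 * pi * 2 * (0:63) / 64))
    psP <- periodicSmoothDecompose(x)
    expect_lt(sqrt(mean((psP$periodic - x)^2)) / sqrt(mean(x^2)), 0.05)

    ## linearity
    a <- matrix(rnorm(32 * 32), 32, 32); b <- matrix(rnorm(32 * 32), 32, 32)
    lhs <- periodicSmoothDecompose(2 * a + 5 * b)$periodic
    rhs <- 2 * periodicSmoothDecompose(a)$periodic +
      5 * periodicSmoothDecompose(b)$periodic
    expect_equal(lhs, rhs, tolerance = 1e-10)
  })
})

test_that("illumination direction is recovered within 5 degrees", {
  n <- 256L
  cfg <- acquisitionConfig(imageShape = c(n, n), pixelSizeNm = 100)
  pupil <- makeAnnularPupil(cfg)
  beads <- makeBeadPhantom(shape = c(n, n), nBeads = round(n^2 / 300),
                           beadRadiusNm = 200, deltaN = 0.02, k = 1e-5, seed = 7)
  obj <- phantomToEffectiveObject(beads, cfg)
  for (ang in c(0, 75, 210)) {
    I <- forwardAbbe(obj, makeHalfringSource(pupil, ang), pupil, cfg,
                     nSourcePoints = 64)
    est <- estimateIlluminationDirection(I, cfg)
    expect_lt(angularError(est@angleDeg, ang), 5)
    expect_gte(est@confidence, 1)
  }
})

test_that("a rotationally symmetric spectrum triggers a low-confidence warning", {
  n <- 256L
  cfg <- acquisitionConfig(imageShape = c(n, n), pixelSizeNm = 100)
  pupil <- makeAnnularPupil(cfg)
  beads <- makeBeadPhantom(shape = c(n, n), nBeads = 150, seed = 3)
  obj <- phantomToEffectiveObject(beads, cfg)
  sFull <- makeHalfringSource(pupil, 0)
  sFull@values <- Mod(pupil@values)
  I <- forwardAbbe(obj, sFull, pupil, cfg, nSourcePoints = 128)
  expect_warning(estimateIlluminationDirection(I, cfg), "low-confidence")
})

test_that("the full direction pipeline beats the naive spectrum projection", {
  ## edge-heavy fixture: bead field plus a strong illumination ramp that
  ## creates opposite-edge discontinuities
  n <- 256L
  cfg <- acquisitionConfig(imageShape = c(n, n), pixelSizeNm = 100)
  pupil <- makeAnnularPupil(cfg)
  beads <- makeBeadPhantom(shape = c(n, n), nBeads = round(n^2 / 300),
                           beadRadiusNm = 200, deltaN = 0.02, k = 1e-5, seed = 23)
  obj <- phantomToEffectiveObject(beads, cfg)
  ramp <- 1 + outer(seq(-0.25, 0.25, length.out = n),
                    seq(-0.15, 0.15, length.out = n), "+")
  errsFull <- c(); errsNaive <- c()
  for (ang in c(30, 120)) {
    I <- forwardAbbe(obj, makeHalfringSource(pupil, ang), pupil, cfg,
                     nSourcePoints = 64) * ramp
    eF <- suppressWarnings(estimateIlluminationDirection(I, cfg))
    eN <- suppressWarnings(estimateIlluminationDirection(I, cfg, naive = TRUE))
    errsFull <- c(errsFull, angularError(eF@angleDeg %% 180, ang %% 180, 180))
    errsNaive <- c(errsNaive, angularError(eN@angleDeg %% 180, ang %% 180, 180))
  }
  expect_lt(max(errsFull), 5)
  expect_gt(max(errsNaive), max(errsFull))
})

test_that("the pupil is recovered from off-center pinhole images", {
  n <- 256L
  cfg <- acquisitionConfig(imageShape = c(n, n), pixelSizeNm = 100)
  pupil <- makeAnnularPupil(cfg)
  dfx <- pupil@fxStep; dfy <- pupil@fyStep
  mkPinhole <- function(angDeg, radFrac = 0.8) {
    v <- matrix(0, n, n)
    r <- (cfg@naObs + radFrac * (cfg@na - cfg@naObs)) / cfg@wavelengthNm
    v[round(n / 2 + 1 - r * sin(angDeg * pi / 180) / dfy),
      round(n / 2 + 1 + r * cos(angDeg * pi / 180) / dfx)] <- 1
    new("SourceDistribution", values = v, orientation = c(1, 0),
        fxStep = dfx, fyStep = dfy, radialWeight = numeric(0))
  }
  imgs <- lapply(seq_along(aa <- c(20, 110, 200, 290)), function(i) {
    ph <- makeBeadPhantom(shape = c(n, n), nBeads = 250, beadRadiusNm = 150,
                          deltaN = 0.015, k = 3e-4, seed = i + 10)
    forwardAbbe(phantomToEffectiveObject(ph, cfg), mkPinhole(aa[i]), pupil, cfg,
                nSourcePoints = NULL)
  })
  est <- estimatePupil(imgs, cfg)
  tr <- Re(pupil@values) > 0
  ev <- est@values > 0
  expect_gt(sum(tr & ev) / sum(tr | ev), 0.95)

  ## averaging more images reduces the pre-binarization residual
  e1 <- estimatePupil(imgs[1], cfg, binarize = FALSE)@values
  e4 <- estimatePupil(imgs, cfg, binarize = FALSE)@values
  resid <- function(e) sd(e[tr] / mean(e[tr]))
  expect_lt(resid(e4), resid(e1))

  ## pinhole at the pupil center is a degenerate geometry (simulated through
  ## an unobscured pupil, since an annulus blocks the axial point entirely)
  cfgU <- acquisitionConfig(imageShape = c(n, n), pixelSizeNm = 100, naObs = 1e-9)
  pupilU <- makeAnnularPupil(cfgU)
  ctr <- mkPinhole(0)
  ctr@values[] <- 0
  ctr@values[n / 2 + 1, n / 2 + 2] <- 1   # one pixel off DC: copies coincide
  phC <- makeBeadPhantom(shape = c(n, n), nBeads = 250, seed = 2)
  Ic <- forwardAbbe(phantomToEffectiveObject(phC, cfgU), ctr, pupilU, cfgU,
                    nSourcePoints = NULL)
  expect_error(estimatePupil(list(Ic), cfg), "degenerate")
})
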