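test_that("annular pupil matches the analytic area ratio and edge conventions", {
  cfg <- cfgSmall()
  p <- makeAnnularPupil(cfg)
  full <- makeAnnularPupil(acquisitionConfig(imageShape = c(128L, 128L),
                                             pixelSizeNm = 100, naObs = 1e-9))
  frac <- sum(p@values) / sum(full@values)
  expect_lt(abs(frac - (1 - (0.27 / 0.65)^2)), 0.01)

  ## closed outer edge: a grid frequency exactly at na/lambda is inside
  g <- uvqdpc:::frequencyGridNm(c(128L, 128L), 100)
  expect_true(all(p@values[abs(g$ur - cfg@na / cfg@wavelengthNm) < 1e-12] == 1))
  expect_true(all(p@values[g$ur > cfg@na / cfg@wavelengthNm] == 0))
  expect_true(all(p@values[g$ur < cfg@naObs / cfg@wavelengthNm] == 0))

  ## naObs -> 0 gives the full disc
  expect_gt(sum(full@values), sum(p@values))
  expect_error(makeAnnularPupil(acquisitionConfig(na = 0.3, naObs = 0.4)),
               "naObs")
})

test_that("half-ring sources tile the annulus and respect radial weights", {
  p <- pupilSmall()
  s0 <- makeHalfringSource(p, 0)
  s180 <- makeHalfringSource(p, 180)
  both <- s0@values + s180@values
  ann <- Mod(p@values)
  ## complementarity: union covers the annulus; overlap only on the split line
  expect_true(all(both >= ann))
  expect_lte(sum(both > ann), sum(ann[65, ] > 0) + 2)  # dividing row only

  four <- makeHalfringSource(p, 90)@values + makeHalfringSource(p, 270)@values + both
  expect_true(all(abs(four[ann > 0 & four %in% c(2)] - 2) == 0))
  expect_gte(min(four[ann > 0]), 2)   # every annulus point covered twice or more

  expect_equal(makeHalfringSource(p, 45, radialWeight = rep(1, 16))@values,
               makeHalfringSource(p, 45)@values)
  sw <- makeHalfringSource(p, 0, radialWeight = cosineRadialProfile(32))
  expect_lt(sum(sw@values), sum(s0@values))
  ## source energy never exceeds pupil energy
  for (a in c(0, 30, 200)) {
    expect_lte(sum(makeHalfringSource(p, a)@values), sum(Mod(p@values)^2) + 1e-9)
  }
})

test_that("weak-object transfer functions have the required structure", {
  p <- pupilSmall()
  ctr <- 65L  # grid center for a 128-point axis
  for (ang in c(0, 37, 90)) {
    tf <- computeWOTF(makeHalfringSource(p, ang), p)
    expect_equal(Re(tf@hAbs[ctr, ctr]), -2 * tf@background, tolerance = 1e-12)
    expect_lt(Mod(tf@hPh[ctr, ctr]), 1e-9)
    ## h_abs real and even, h_ph imaginary and odd; both Hermitian-symmetric
    sub <- function(m) m[2:128, 2:128]
    flip <- function(m) m[128:2, 128:2]
    expect_lt(max(abs(Im(tf@hAbs))), 1e-9 * tf@background)
    expect_lt(max(Mod(sub(tf@hAbs) - flip(tf@hAbs))), 1e-9 * tf@background)
    expect_lt(max(abs(Re(tf@hPh))), 1e-9 * tf@background)
    expect_lt(max(Mod(sub(tf@hPh) + flip(tf@hPh))), 1e-9 * tf@background)
  }
  ## full-ring (symmetric) source kills the phase transfer entirely
  sFull <- makeHalfringSource(p, 0)
  sFull@values <- Mod(p@values)
  tfF <- computeWOTF(sFull, p)
  expect_lt(max(Mod(tfF@hPh)), 1e-9 * tfF@background)

  ## half-ring at 0: h_ph odd along u_x, even along u_y
  tf0 <- computeWOTF(makeHalfringSource(p, 0), p)
  hp <- Im(tf0@hPh)
  expect_lt(max(abs(hp[2:128, 2:128] + hp[2:128, 128:2])), 1e-9 * tf0@background)
  expect_lt(max(abs(hp[2:128, 2:128] - hp[128:2, 2:128])), 1e-9 * tf0@background)

  ## degenerate source
  sZero <- sFull; sZero@values <- matrix(0, 128, 128)
  expect_error(computeWOTF(sZero, p), "degenerate")
})

test_that("transfer functions rotate with the source orientation", {
  p <- pupilSmall()
  tf0 <- computeWOTF(makeHalfringSource(p, 0), p)
  tf90 <- computeWOTF(makeHalfringSource(p, 90), p)
  ## rotating the 0-degree kernels by 90 degrees equals the 90-degree kernels
  rot90 <- function(m) t(m)[, rev(seq_len(ncol(m)))]  # 90 deg CCW for centered odd part
  a0 <- Mod(tf0@hPh[2:128, 2:128])
  a90 <- Mod(tf90@hPh[2:128, 2:128])
  expect_lt(max(abs(rot90(a0) - a90)), 1e-6 * tf0@background)
})
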