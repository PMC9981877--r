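#' Periodic-plus-smooth image decomposition
#'
#' Splits an image into a periodic component, whose DFT is free of the
#' cross-shaped artifact caused by opposite-edge discontinuities, and a
#' smooth component that carries those discontinuities. The two components
#' sum to the input exactly. The smooth part solves a discrete Poisson
#' equation driven by the edge mismatches (Moisan-style decomposition).
#'
#' @param image 2-D real matrix.
#' @return list(periodic = matrix, smooth = matrix).
#' @export
periodicSmoothDecompose <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  nr <- nrow(image); nc <- ncol(image)
  b <- matrix(0, nr, nc)
  dr <- image[nr, ] - image[1, ]
  b[1, ] <- b[1, ] + dr; b[nr, ] <- b[nr, ] - dr
  dc <- image[, nc] - image[, 1]
  b[, 1] <- b[, 1] + dc; b[, nc] <- b[, nc] - dc
  qr <- 2 * cos(2 * pi * (seq_len(nr) - 1) / nr)
  qc <- 2 * cos(2 * pi * (seq_len(nc) - 1) / nc)
  denom <- outer(qr, qc, function(a, b) a + b - 4)
  denom[1, 1] <- 1                      # DC of the smooth part is set to 0
  sHat <- stats::fft(b) / denom
  sHat[1, 1] <- 0
  smooth <- Re(stats::fft(sHat, inverse = TRUE)) / (nr * nc)
  list(periodic = image - smooth, smooth = smooth)
}

## Center projections of the Radon transform: for each probed angle, the
## line integral through the image center along a line at that angle
## (degrees CCW from +x in the image convention, y up). Realized as image
## rotation (bilinear) followed by a central-column sum.
radonCenterProjection <- function(image, angleStepDeg = 1) {
  angles <- seq(0, 180 - angleStepDeg, by = angleStepDeg)
  nr <- nrow(image); nc <- ncol(image)
  c0 <- gridCenter(nc)
  vals <- vapply(angles, function(a) {
    rot <- EBImage::rotate(EBImage::Image(image), a, filter = "bilinear",
                           output.dim = c(nr, nc), bg.col = 0)
    sum(EBImage::imageData(rot)[, c0])
  }, numeric(1))
  list(angles = angles, values = vals)
}

circularMedian3 <- function(x) {
  n <- length(x)
  ext <- c(x[n], x, x[1])
  vapply(seq_len(n), function(i) stats::median(ext[i:(i + 2)]), numeric(1))
}

## Parabolic sub-bin refinement of an extremum on a circular profile;
## returns a fractional index (0-based).
parabolicRefine <- function(prof, i) {
  n <- length(prof)
  ym <- prof[((i - 2) %% n) + 1]; y0 <- prof[i]; yp <- prof[(i %% n) + 1]
  den <- ym - 2 * y0 + yp
  if (abs(den) < 1e-12) return(i - 1)
  (i - 1) + 0.5 * (ym - yp) / den
}

## Third-order asymmetry statistic along direction d: sum f^2 (D_d * f)
## with a derivative-of-Gaussian filter. Quadratic statistics are blind to
## the 180-degree sign of the odd (phase-contrast) image component, so a
## third-order moment is the minimal sign-sensitive choice.
dpcAsymmetryStat <- function(f, d, sigma = 2) {
  nr <- nrow(f); nc <- ncol(f)
  x <- matrix(rep(seq_len(nc) - gridCenter(nc), each = nr), nr, nc)
  y <- -(matrix(seq_len(nr) - gridCenter(nr), nr, nc))
  u <- d[1] * x + d[2] * y
  D <- -u * exp(-(x^2 + y^2) / (2 * sigma^2))
  conv <- Re(stats::fft(stats::fft(f) * stats::fft(ifftShift2(D)), inverse = TRUE)) / length(f)
  sum(f^2 * conv)
}

## Sign convention of the asymmetry statistic, calibrated at run time by
## imaging a single positive (thicker and more absorbing) blob through the
## same optics at the candidate direction.
dpcModelSign <- function(axisDeg, config) {
  n <- 64L
  cfg <- acquisitionConfig(wavelengthNm = config@wavelengthNm,
                           bandwidthNm = config@bandwidthNm,
                           na = config@na, naObs = config@naObs,
                           nMedium = config@nMedium,
                           pixelSizeNm = config@pixelSizeNm, imageShape = c(n, n))
  p <- makeAnnularPupil(cfg)
  src <- makeHalfringSource(p, axisDeg)
  blob <- discCoverage(c(n, n), gridCenter(n), gridCenter(n), 2)
  obj <- new("EffectiveObject", phi = blob * 0.2, mu = blob * 0.05, pixelSizeNm = cfg@pixelSizeNm)
  I <- forwardWOTF(obj, src, p, cfg)
  f <- I / mean(I) - 1
  th <- axisDeg * pi / 180
  sign(dpcAsymmetryStat(f, c(cos(th), sin(th))))
}

#' Estimate the mean illumination direction from one oblique image
#'
#' A half-ring source makes the optical transfer function anisotropic, so
#' the spectrum of an image of small scatterers is dominated by that shape:
#' its radial center-projections peak in the direction orthogonal to the
#' mean illumination direction. A naive spectrum projection is corrupted by
#' edge artifacts; the pipeline therefore applies, in order: a smooth
#' circular crop (Gaussian-blurred mask, sigma = `cropSigmaPx`), periodic-
#' smooth decomposition, Fourier transform, log magnitude, a smooth mask
#' excluding frequencies outside the nominal incoherent support, the Radon
#' center projections per angle, a 3-sample circular median filter, and an
#' argmax. The 180 degree ambiguity of the spectral method is resolved from
#' the sign of the DPC asymmetry of the image itself (correlation between
#' the image and its directional derivative along the candidate axis).
#'
#' @param image intensity image of bead-like scatterers (flat-field corrected
#'   or raw; the mean is removed internally).
#' @param config an [AcquisitionConfig-class].
#' @param angleStepDeg Radon angular step (degrees).
#' @param cropSigmaPx Gaussian sigma of the circular crop edge (pixels).
#' @param specSmoothPx Gaussian sigma (pixels) applied to the masked
#'   log-spectrum before the Radon step; suppresses speckle that otherwise
#'   biases the discrete (rotation-based) projections toward grid-aligned
#'   angles.
#' @param naive skip the smooth crop, periodic decomposition, spectral mask
#'   and spectrum smoothing (the degraded baseline; for diagnostics only).
#' @param confidenceThreshold peak-to-median profile ratio below which a
#'   low-confidence warning is raised.
#' @return a [DirectionEstimate-class]; angle in [0, 360). The stored
#'   profile is indexed by projection direction, so its broad maximum lies
#'   orthogonal to the estimated axis while the sharp minimum -- the nodal
#'   line of the antisymmetric phase transfer, which this implementation
#'   locates because it is much better conditioned than the flat-topped
#'   maximum -- sits at the axis itself.
#' @export
estimateIlluminationDirection <- function(image, config, angleStepDeg = 1,
                                          cropSigmaPx = 20, specSmoothPx = 2,
                                          naive = FALSE,
                                          confidenceThreshold = 1.05) {
  stopifnot(is.matrix(image), is(config, "AcquisitionConfig"))
  nr <- nrow(image); nc <- ncol(image)
  f <- image - mean(image)
  if (!naive) {
    rad <- min(nr, nc) / 2 - 2.5 * cropSigmaPx
    rr <- matrix(seq_len(nr) - gridCenter(nr), nr, nc)
    cc <- matrix(rep(seq_len(nc) - gridCenter(nc), each = nr), nr, nc)
    mask <- (sqrt(rr^2 + cc^2) <= rad) * 1
    mask <- EBImage::imageData(EBImage::gblur(EBImage::Image(mask), sigma = cropSigmaPx))
    f <- f * mask
    f <- periodicSmoothDecompose(f)$periodic
  }
  spec <- log1p(Mod(fftShift2(stats::fft(f))))
  if (!naive) {
    fmask <- smoothRadialMask(c(nr, nc), config@pixelSizeNm,
                              2 * config@na / config@wavelengthNm, edgePx = 10)
    spec <- spec * fmask
    if (specSmoothPx > 0)
      spec <- EBImage::imageData(EBImage::gblur(EBImage::Image(spec), sigma = specSmoothPx))
  }
  rp <- radonCenterProjection(spec, angleStepDeg)
  prof <- circularMedian3(rp$values)
  confidence <- max(prof) / stats::median(prof)
  if (confidence < confidenceThreshold)
    warning(sprintf("low-confidence direction estimate (peak/median = %.3f): the spectrum may be rotationally symmetric", confidence))
  ## re-index from rotation angle m to projection direction theta = -m so
  ## the broad profile maximum is orthogonal to the illumination axis and
  ## the sharp minimum lies on it
  theta <- (-rp$angles) %% 180
  ord <- order(theta)
  profTheta <- prof[ord]; thetaSorted <- theta[ord]
  iMin <- which.min(profTheta)
  axis <- (parabolicRefine(-profTheta, iMin) * angleStepDeg) %% 180
  ## resolve the 180-degree ambiguity: compare the third-order DPC asymmetry
  ## of the image with a model blob imaged at the candidate direction
  ## (assumes optically thicker regions absorb more, as for cells in medium)
  th <- axis * pi / 180
  g <- image / mean(image) - 1
  sMeas <- sign(dpcAsymmetryStat(g, c(cos(th), sin(th))))
  sModel <- dpcModelSign(axis, config)
  angle <- if (sMeas == sModel || sMeas == 0) axis else (axis + 180) %% 360
  new("DirectionEstimate", angleDeg = angle, radonProfile = profTheta,
      profileAngles = thetaSorted, confidence = confidence)
}

#' Estimate the pupil function from off-center-pinhole images
#'
#' With a pinhole source at pupil position u_p, the spectrum of the recorded
#' intensity contains the sample spectrum multiplied by two decentered
#' copies of the pupil function, centered at +/- u_p. This estimator locates
#' the copies in each log-magnitude spectrum by cross-correlation with a
#' zero-mean annulus template built from the nominal NA geometry (a
#' classical matched filter), re-centers and averages the extracted copies
#' across images, and binarizes the average at half its 99th percentile.
#'
#' @param pinholeImages list of intensity images (matrices), each acquired
#'   with an off-center pinhole source; several images with different
#'   pinhole positions average out object structure.
#' @param config an [AcquisitionConfig-class] giving the nominal geometry.
#' @param binarize return a binary pupil (default) or the averaged
#'   pre-binarization estimate.
#' @param thresholdFactor binarization threshold as a fraction of the 99th
#'   percentile of the averaged estimate.
#' @return a [PupilFunction-class]. If the two copies coincide (pinhole at
#'   the pupil center) the geometry is degenerate and an error is raised
#'   carrying the correlation map as attribute `diagnostic`.
#' @export
estimatePupil <- function(pinholeImages, config, binarize = TRUE,
                          thresholdFactor = 0.4) {
  stopifnot(is.list(pinholeImages), length(pinholeImages) >= 1,
            is(config, "AcquisitionConfig"))
  nr <- nrow(pinholeImages[[1]]); nc <- ncol(pinholeImages[[1]])
  tmplCfg <- acquisitionConfig(wavelengthNm = config@wavelengthNm,
                               bandwidthNm = config@bandwidthNm,
                               na = config@na, naObs = config@naObs,
                               nMedium = config@nMedium,
                               pixelSizeNm = config@pixelSizeNm,
                               imageShape = c(nr, nc))
  tmpl <- Re(makeAnnularPupil(tmplCfg)@values)
  t0 <- tmpl - mean(tmpl)
  rOutPx <- config@na / config@wavelengthNm /
    (1 / (nr * config@pixelSizeNm))          # pupil radius in pixels (rows)
  acc <- matrix(0, nr, nc); nAcc <- 0
  lastCorr <- NULL
  for (img in pinholeImages) {
    spec <- log1p(Mod(fftShift2(stats::fft(img - mean(img)))))
    corr <- Re(crossCorrelate2(t0 + 0i, spec + 0i))
    lastCorr <- corr
    r0 <- gridCenter(nr); c0 <- gridCenter(nc)
    pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
    off <- c(pk[1] - r0, pk[2] - c0)
    if (sqrt(sum(off^2)) < 2) {
      e <- simpleError("degenerate pinhole geometry: the two pupil copies coincide at the spectrum center")
      attr(e, "diagnostic") <- corr
      stop(e)
    }
    for (sgn in c(1, -1)) {
      sh <- circShift2(ifftShift2(spec), -sgn * off[1], -sgn * off[2])
      acc <- acc + fftShift2(sh)
      nAcc <- nAcc + 1
    }
  }
  est <- acc / nAcc
  est <- est - stats::median(est[tmpl == 0])   # remove the spectral floor
  est[est < 0] <- 0
  est <- est / max(est)
  vals <- if (binarize) {
    ## the outer annulus edge is dimmed by the object's spectral envelope;
    ## a threshold of 0.4 x 99th percentile plus a small closing recovers it
    bin <- (est >= thresholdFactor * stats::quantile(est, 0.99)) * 1
    (EBImage::imageData(EBImage::closing(EBImage::Image(bin),
                                EBImage::makeBrush(3L, "box"))) > 0.5) * 1
  } else est
  new("PupilFunction", values = vals,
      fxStep = 1 / (nc * config@pixelSizeNm), fyStep = 1 / (nr * config@pixelSizeNm),
      na = config@na, naObs = config@naObs, wavelengthNm = config@wavelengthNm)
}
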