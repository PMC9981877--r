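#' Linearized (weak-object) forward image formation
#'
#' Computes the intensity predicted by the weak-object transfer-function
#' model,
#' \deqn{\hat I(u) = B\,\delta(u) + h_{abs}(u)\,\hat\mu(u) + h_{ph}(u)\,\hat\phi(u),}
#' returned in real space. The result is real up to numerical rounding; a
#' residual imaginary part above `imagTol` (relative to the background B)
#' raises an internal-consistency error.
#'
#' @param obj an [EffectiveObject-class].
#' @param source a [SourceDistribution-class].
#' @param pupil a [PupilFunction-class].
#' @param config an [AcquisitionConfig-class] (shape consistency check).
#' @param transfer optional precomputed [TransferFunctions-class] for this
#'   source/pupil pair (skips recomputation).
#' @param imagTol tolerance on the relative imaginary residual.
#' @return intensity image (matrix) in source-sum units (background level B).
#' @export
forwardWOTF <- function(obj, source, pupil, config, transfer = NULL, imagTol = 1e-8) {
  stopifnot(is(obj, "EffectiveObject"))
  if (!identical(dim(obj@mu), dim(pupil@values)))
    stop("object and pupil grids do not match")
  tf <- if (is.null(transfer)) computeWOTF(source, pupil) else transfer
  ha <- ifftShift2(tf@hAbs)
  hp <- ifftShift2(tf@hPh)
  ihat <- ha * stats::fft(obj@mu) + hp * stats::fft(obj@phi)
  d <- stats::fft(ihat, inverse = TRUE) / length(ihat)
  if (max(abs(Im(d))) > imagTol * max(tf@background, 1))
    stop("internal consistency error: imaginary residual above tolerance")
  tf@background + Re(d)
}

#' Brute-force partially coherent (Abbe) forward model
#'
#' Reference oracle for [forwardWOTF()]: sums coherent images over discrete
#' source points,
#' \deqn{I(r) = \sum_s w_s \left| \mathcal{F}^{-1}[P(u)\,\hat T(u - u_s)](r) \right|^2,}
#' with the exact complex transmission \eqn{T = \exp(i\phi - \mu)} (no weak-
#' object linearization). Weights are normalized so an empty object returns
#' the same background B as [forwardWOTF()] for the same source. Source
#' points are taken from the nonzero pixels of the (half-ring) source;
#' `nSourcePoints = NULL` uses all of them, otherwise an approximately
#' uniform subsample is used.
#'
#' @param obj an [EffectiveObject-class].
#' @param source a [SourceDistribution-class].
#' @param pupil a [PupilFunction-class].
#' @param config an [AcquisitionConfig-class].
#' @param nSourcePoints number of source points (default 64), or `NULL` for
#'   all; fewer than 8 raises an undersampling warning.
#' @return intensity image (matrix), background level B.
#' @export
forwardAbbe <- function(obj, source, pupil, config, nSourcePoints = 64) {
  stopifnot(is(obj, "EffectiveObject"))
  S <- source@values; P <- pupil@values
  idx <- which(S > 0 & Mod(P) > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("degenerate source: zero total weight inside the pupil")
  B <- sum(S * Mod(P)^2)
  if (!is.null(nSourcePoints) && nSourcePoints < nrow(idx)) {
    if (nSourcePoints < 8)
      warning("fewer than 8 source points: the partially coherent sum is undersampled")
    ## stratify the subsample uniformly in ring angle (column-major picking
    ## would bias the effective source shape and tilt the transfer functions)
    r0 <- gridCenter(nrow(P)); c0 <- gridCenter(ncol(P))
    ringAng <- atan2(-(idx[, 1] - r0), idx[, 2] - c0)
    ord <- order(ringAng, (idx[, 1] - r0)^2 + (idx[, 2] - c0)^2)
    pick <- unique(round(seq(1, nrow(idx), length.out = nSourcePoints)))
    idx <- idx[ord[pick], , drop = FALSE]
  }
  w <- S[idx] * Mod(P[idx])^2
  w <- w * (B / sum(w))                       # empty object returns exactly B
  nr <- nrow(P); nc <- ncol(P)
  r0 <- gridCenter(nr); c0 <- gridCenter(nc)
  Pstd <- ifftShift2(P)
  That <- stats::fft(exp(1i * obj@phi - obj@mu))
  I <- matrix(0, nr, nc)
  for (j in seq_len(nrow(idx))) {
    dr <- idx[j, 1] - r0; dc <- idx[j, 2] - c0
    E <- stats::fft(Pstd * circShift2(That, dr, dc), inverse = TRUE) / (nr * nc)
    I <- I + w[j] * Mod(E)^2
  }
  I
}

#' Photon (shot) noise
#'
#' Applies Poisson counting noise at a mean budget of `photonScale` photons
#' per unit intensity: the returned image is `rpois(photonScale * I) /
#' photonScale`, so the expectation is unchanged and the variance of a flat
#' region is `mean / photonScale`. Deterministic under `seed`; the caller's
#' RNG state is untouched.
#'
#' @param image nonnegative intensity matrix.
#' @param photonScale photons per unit intensity (> 0).
#' @param seed integer seed.
#' @return noisy image (matrix).
#' @export
addNoise <- function(image, photonScale, seed = 1) {
  stopifnot(photonScale > 0, all(image >= 0))
  withSeed(seed, {
    matrix(stats::rpois(length(image), image * photonScale) / photonScale,
           nrow(image), ncol(image))
  })
}

#' Acquire a simulated oblique-illumination stack
#'
#' Generates, per half-ring orientation, an intensity image of the phantom
#' and a matching sample-free background image with identical optics --
#' mirroring an acquisition in which background frames are taken on a
#' cell-free area for flat-field correction. Images are anchored to a
#' background level of 1. Optional photon noise is applied independently to
#' every frame with per-frame sub-seeds derived from `seed`.
#'
#' @param phantom a [ComplexPhantom-class].
#' @param config an [AcquisitionConfig-class]; its `imageShape` and
#'   `pixelSizeNm` must match the phantom.
#' @param orientationsDeg orientations; default from `config` (must be distinct).
#' @param method `"wotf"` (linearized, fast) or `"abbe"` (brute force).
#' @param photonScale photons per unit intensity for shot noise, or `NULL`
#'   (default) for a noise-free stack.
#' @param seed integer seed for the noise.
#' @param radialWeight optional radial source profile (see
#'   [makeHalfringSource()]).
#' @param nSourcePoints passed to [forwardAbbe()] when `method = "abbe"`.
#' @return a [DPCStack-class].
#' @export
acquireStack <- function(phantom, config, orientationsDeg = config@orientationsDeg,
                         method = c("wotf", "abbe"), photonScale = NULL, seed = 1,
                         radialWeight = NULL, nSourcePoints = 64) {
  method <- match.arg(method)
  stopifnot(is(phantom, "ComplexPhantom"), is(config, "AcquisitionConfig"))
  if (anyDuplicated(orientationsDeg %% 360))
    stop("orientations must be distinct")
  if (!identical(dim(phantom@kMap), as.integer(config@imageShape)) ||
      phantom@pixelSizeNm != config@pixelSizeNm)
    stop("phantom grid does not match the configuration")
  obj <- phantomToEffectiveObject(phantom, config)
  pupil <- makeAnnularPupil(config)
  imgs <- list(); bgs <- list()
  for (i in seq_along(orientationsDeg)) {
    src <- makeHalfringSource(pupil, orientationsDeg[i], radialWeight)
    tf <- computeWOTF(src, pupil)
    I <- if (method == "wotf") {
      forwardWOTF(obj, src, pupil, config, transfer = tf)
    } else {
      forwardAbbe(obj, src, pupil, config, nSourcePoints = nSourcePoints)
    }
    B <- tf@background
    img <- pmax(I / B, 0)
    bg <- matrix(1, nrow(I), ncol(I))
    if (!is.null(photonScale)) {
      img <- addNoise(img, photonScale, seed = seed + 2L * i)
      bg <- addNoise(bg, photonScale, seed = seed + 2L * i + 1L)
      bg[bg <= 0] <- 1 / photonScale
    }
    imgs[[i]] <- img; bgs[[i]] <- bg
  }
  new("DPCStack", images = imgs, backgrounds = bgs,
      orientationsDeg = as.numeric(orientationsDeg), config = config)
}
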