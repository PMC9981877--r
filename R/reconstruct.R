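#' Flat-field correction
#'
#' Per orientation j, forms the normalized difference image
#' d_j = (I_j - B_j) / B_j, which removes illumination inhomogeneity and
#' anchors the sample-free level at zero.
#'
#' @param stack a [DPCStack-class] with strictly positive backgrounds.
#' @return list of difference images (matrices).
#' @export
flatfieldCorrect <- function(stack) {
  stopifnot(is(stack, "DPCStack"))
  lapply(seq_along(stack@images), function(j) {
    B <- stack@backgrounds[[j]]
    bad <- which(B <= 0)
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(B))
      stop(sprintf("nonpositive background pixel at (%d, %d) in orientation %g",
                   rc[1], rc[2], stack@orientationsDeg[j]))
    }
    (stack@images[[j]] - B) / B
  })
}

#' Joint Tikhonov-regularized qDPC inversion
#'
#' Solves, independently at every spatial frequency, the 2x2 regularized
#' least-squares problem
#' \deqn{\min_{\hat\mu, \hat\phi} \sum_j \| h_{abs,j}\hat\mu + h_{ph,j}\hat\phi
#'  - B_j \hat d_j \|^2 + \tau_{abs}\|\hat\mu\|^2 + \tau_{ph}\|\hat\phi\|^2}
#' by closed-form normal equations, then inverse-transforms to real-valued
#' absorption and phase maps. The transfer functions are used in their
#' source-sum units (B = sum S|P|^2 with per-pixel source weights), so tau
#' acts against |h|^2 of that scale: it is negligible where the object is
#' well transferred and dominates near transfer-function nulls and the band
#' edge, where it suppresses noise amplification at the cost of nominal
#' resolution.
#'
#' @param diffs list of flat-field-corrected difference images (from
#'   [flatfieldCorrect()]).
#' @param transfer list of matching [TransferFunctions-class], one per
#'   orientation (at least 2).
#' @param tauAbs,tauPh nonnegative regularization weights; with both zero a
#'   singular normal matrix at any frequency raises a
#'   regularization-required error.
#' @param supportMask optional 0/1 matrix (centered layout): frequencies
#'   where the mask is 0 are zeroed before the inverse transform.
#' @return list(phi = matrix, mu = matrix).
#' @export
solveQDPC <- function(diffs, transfer, tauAbs, tauPh, supportMask = NULL) {
  stopifnot(length(diffs) == length(transfer), length(diffs) >= 2,
            tauAbs >= 0, tauPh >= 0)
  d <- dim(diffs[[1]])
  n <- prod(d)
  A11 <- matrix(tauAbs, d[1], d[2]); A22 <- matrix(tauPh, d[1], d[2])
  A12 <- matrix(0 + 0i, d[1], d[2])
  b1 <- matrix(0 + 0i, d[1], d[2]); b2 <- b1
  for (j in seq_along(diffs)) {
    if (!identical(dim(diffs[[j]]), d) || !identical(dim(transfer[[j]]@hAbs), d))
      stop("transfer grids must match image grids")
    ha <- ifftShift2(transfer[[j]]@hAbs)
    hp <- ifftShift2(transfer[[j]]@hPh)
    y <- transfer[[j]]@background * stats::fft(diffs[[j]])
    A11 <- A11 + Mod(ha)^2
    A22 <- A22 + Mod(hp)^2
    A12 <- A12 + Conj(ha) * hp
    b1 <- b1 + Conj(ha) * y
    b2 <- b2 + Conj(hp) * y
  }
  det <- A11 * A22 - Mod(A12)^2
  ## with tau = 0 the system is singular wherever both kernels vanish (all
  ## frequencies outside the passband); floating-point dust keeps det just
  ## above zero there, hence the relative threshold
  if (any(det <= 0) ||
      ((tauAbs == 0 || tauPh == 0) && min(det) < 1e-12 * max(det)))
    stop("singular normal matrix at some frequency: regularization required (increase tauAbs/tauPh)")
  muHat <- (A22 * b1 - A12 * b2) / det
  phiHat <- (A11 * b2 - Conj(A12) * b1) / det
  if (!is.null(supportMask)) {
    m <- ifftShift2(supportMask)
    muHat <- muHat * m
    phiHat <- phiHat * m
  }
  list(phi = Re(stats::fft(phiHat, inverse = TRUE)) / n,
       mu = Re(stats::fft(muHat, inverse = TRUE)) / n)
}

#' Attenuation exponent to extinction coefficient
#'
#' Amplitude attenuation over a single pass of length l is exp(-2 pi k l /
#' lambda); the reflection geometry doubles the path, so the measured
#' double-pass exponent is mu = 2 pi k L / lambda with L the *total* optical
#' path. Inverting,
#' \deqn{k = \frac{\mu \lambda}{2 \pi L}.}
#' The default L is twice the depth of field -- the double pass through the
#' axial slice the objective integrates over -- which makes the returned
#' extinction coefficients a lower bound for structures thinner than the
#' depth of field.
#'
#' @param mu attenuation-exponent map (matrix) or scalar.
#' @param config an [AcquisitionConfig-class].
#' @param pathLengthNm assumed total (double-pass) path length in nm;
#'   default `2 * depthOfField(config) * 1000`.
#' @return extinction-coefficient map of the same shape.
#' @examples
#' cfg <- acquisitionConfig()
#' muToK(0.0210, cfg)  # ~3.4e-4 for the reference instrument
#' @export
muToK <- function(mu, config, pathLengthNm = NULL) {
  stopifnot(is(config, "AcquisitionConfig"))
  if (is.null(pathLengthNm)) pathLengthNm <- 2 * depthOfField(config) * 1000
  stopifnot(pathLengthNm > 0)
  mu * config@wavelengthNm / (2 * pi * pathLengthNm)
}

#' Full qDPC reconstruction pipeline
#'
#' Runs flat-field correction, recomputes the weak-object transfer functions
#' for each recorded orientation from the configuration stored in the stack,
#' solves the joint Tikhonov inversion, zeroes frequencies beyond the
#' incoherent support 2 NA / lambda, and converts the retrieved attenuation
#' to a quantitative extinction-coefficient map. All parameters used are
#' recorded in the returned result.
#'
#' @param stack a [DPCStack-class].
#' @param tauAbs,tauPh regularization weights (defaults from the stack's
#'   configuration).
#' @param pathLengthNm total path length for the mu -> k conversion (default
#'   twice the depth of field).
#' @param radialWeight optional radial source profile assumed at
#'   reconstruction time (must match the acquisition for quantitative
#'   results).
#' @param apodizeTaper fraction of the passband over which the support mask
#'   is cosine-tapered instead of cut hard (0 = hard cutoff). A taper trades
#'   a little resolution for strong suppression of the band-limit ringing
#'   around sharp, strong structures such as the nucleus edge; useful before
#'   peak-based analyses.
#' @return a [ReconstructionResult-class].
#' @export
reconstructStack <- function(stack, tauAbs = stack@config@tauAbs,
                             tauPh = stack@config@tauPh,
                             pathLengthNm = NULL, radialWeight = NULL,
                             apodizeTaper = 0) {
  stopifnot(is(stack, "DPCStack"))
  config <- stack@config
  diffs <- flatfieldCorrect(stack)
  pupil <- makeAnnularPupil(config)
  transfer <- lapply(stack@orientationsDeg, function(a)
    computeWOTF(makeHalfringSource(pupil, a, radialWeight), pupil))
  mask <- cosineTaperMask(dim(diffs[[1]]), config@pixelSizeNm,
                          2 * config@na / config@wavelengthNm, apodizeTaper)
  sol <- solveQDPC(diffs, transfer, tauAbs, tauPh, supportMask = mask)
  if (is.null(pathLengthNm)) pathLengthNm <- 2 * depthOfField(config) * 1000
  new("ReconstructionResult", phi = sol$phi, mu = sol$mu,
      kMap = muToK(sol$mu, config, pathLengthNm),
      tauAbs = tauAbs, tauPh = tauPh, pathLengthNm = pathLengthNm,
      config = config)
}
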