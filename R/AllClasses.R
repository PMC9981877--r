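#' @import methods
NULL

#' Acquisition configuration
#'
#' Optical and numerical parameters of a reflection-geometry qDPC
#' acquisition: illumination wavelength and bandwidth, the annular pupil of
#' the Cassegrain-type objective (outer NA and central-obscuration NA),
#' medium index, sampling at the object plane, and the Tikhonov
#' regularization weights used at reconstruction time.
#'
#' @slot wavelengthNm illumination center wavelength (nm).
#' @slot bandwidthNm FWHM source bandwidth (nm), used for the coherence length.
#' @slot na numerical aperture of the objective.
#' @slot naObs equivalent NA of the central obscuration (secondary mirror);
#'   0 gives an unobscured disc pupil.
#' @slot nMedium refractive index of the imaging medium.
#' @slot pixelSizeNm pixel pitch at the sample plane (nm).
#' @slot imageShape integer (rows, cols) of simulated/acquired images.
#' @slot tauAbs,tauPh Tikhonov weights for the absorption and phase channels.
#' @slot orientationsDeg half-ring mask orientations (degrees, CCW from +x).
#' @export
setClass("AcquisitionConfig", representation(
  wavelengthNm = "numeric", bandwidthNm = "numeric",
  na = "numeric", naObs = "numeric", nMedium = "numeric",
  pixelSizeNm = "numeric", imageShape = "integer",
  tauAbs = "numeric", tauPh = "numeric", orientationsDeg = "numeric"
))

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (object@wavelengthNm <= 0) msg <- c(msg, "wavelengthNm must be > 0")
  if (object@bandwidthNm <= 0) msg <- c(msg, "bandwidthNm must be > 0")
  if (object@na <= 0) msg <- c(msg, "na must be > 0")
  if (object@naObs < 0) msg <- c(msg, "naObs must be >= 0")
  if (object@naObs >= object@na) msg <- c(msg, "naObs must be < na")
  if (object@nMedium <= 0) msg <- c(msg, "nMedium must be > 0")
  if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  if (object@tauAbs < 0 || object@tauPh < 0) msg <- c(msg, "tau weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Pupil function on the centered frequency grid
#'
#' @slot values complex (or 0/1 numeric) pupil amplitudes; DC at the grid
#'   center, support zero outside |u| > na/lambda.
#' @slot fxStep,fyStep frequency increment per pixel (cycles/nm).
#' @slot na,naObs,wavelengthNm optical parameters the pupil was built from.
#' @export
setClass("PupilFunction", representation(
  values = "matrix", fxStep = "numeric", fyStep = "numeric",
  na = "numeric", naObs = "numeric", wavelengthNm = "numeric"
))

setValidity("PupilFunction", function(object) {
  if (max(Mod(object@values)) > 1 + 1e-9) return("pupil modulus must be <= 1")
  TRUE
})

#' Half-ring (or arbitrary) source distribution in the pupil plane
#'
#' @slot values nonnegative source weights on the same centered grid as the
#'   pupil it was derived from.
#' @slot orientation unit 2-vector (x, y) of the mean illumination direction.
#' @slot fxStep,fyStep frequency increment per pixel (cycles/nm).
#' @slot radialWeight radial profile applied over |u| (numeric(0) if none).
#' @export
setClass("SourceDistribution", representation(
  values = "matrix", orientation = "numeric",
  fxStep = "numeric", fyStep = "numeric", radialWeight = "numeric"
))

setValidity("SourceDistribution", function(object) {
  if (any(object@values < 0)) return("source weights must be nonnegative")
  if (length(object@orientation) != 2L) return("orientation must be a 2-vector")
  TRUE
})

#' Weak-object transfer functions for one illumination orientation
#'
#' Absorption (Hermitian-symmetric) and phase (Hermitian-antisymmetric)
#' transfer functions plus the DC background term B, all on the centered
#' frequency grid in source-sum units (B = sum S |P|^2).
#'
#' @slot hAbs,hPh complex matrices (centered layout).
#' @slot background scalar B.
#' @slot orientation unit 2-vector of the source orientation.
#' @slot fxStep,fyStep frequency increment per pixel (cycles/nm).
#' @export
setClass("TransferFunctions", representation(
  hAbs = "matrix", hPh = "matrix", background = "numeric",
  orientation = "numeric", fxStep = "numeric", fyStep = "numeric"
))

#' Complex-refractive-index phantom
#'
#' Ground-truth object for simulations: per-pixel real refractive-index
#' increment over the medium, extinction coefficient (imaginary part of the
#' refractive index), and local physical thickness.
#'
#' @slot deltaN real refractive-index increment (dimensionless).
#' @slot kMap extinction coefficient (dimensionless, >= 0).
#' @slot thickness local thickness (nm).
#' @slot pixelSizeNm pixel pitch (nm).
#' @slot truthLabels integer labels: 0 background, 1 membrane, 2 nucleus,
#'   3 fenestration cluster.
#' @slot truthClusters data.frame(row, col, radiusNm) of planted clusters.
#' @slot meta list of generator parameters (seed, lpPerMm for bar targets, ...).
#' @export
setClass("ComplexPhantom", representation(
  deltaN = "matrix", kMap = "matrix", thickness = "matrix",
  pixelSizeNm = "numeric", truthLabels = "matrix",
  truthClusters = "data.frame", meta = "list"
))

setValidity("ComplexPhantom", function(object) {
  msg <- character()
  d <- dim(object@kMap)
  if (!identical(dim(object@deltaN), d) || !identical(dim(object@thickness), d) ||
      !identical(dim(object@truthLabels), d))
    msg <- c(msg, "all phantom maps must share one shape")
  if (any(object@kMap < 0)) msg <- c(msg, "kMap must be >= 0")
  if (any(object@thickness < 0)) msg <- c(msg, "thickness must be >= 0")
  bg <- object@truthLabels == 0L
  if (any(object@kMap[bg] != 0) || any(object@deltaN[bg] != 0))
    msg <- c(msg, "background pixels must have k = 0 and deltaN = 0")
  if (length(msg)) msg else TRUE
})

#' Effective weak object seen by the microscope
#'
#' Double-pass phase (radians) and amplitude-attenuation exponent derived
#' from a phantom: phi = 2 (2 pi / lambda) deltaN t, mu = 2 (2 pi / lambda) k t.
#'
#' @slot phi double-pass phase map (radians).
#' @slot mu double-pass attenuation exponent (dimensionless, >= 0).
#' @slot pixelSizeNm pixel pitch (nm).
#' @export
setClass("EffectiveObject", representation(
  phi = "matrix", mu = "matrix", pixelSizeNm = "numeric"
))

setValidity("EffectiveObject", function(object) {
  if (!identical(dim(object@phi), dim(object@mu)))
    return("phi and mu must share one shape")
  if (any(object@mu < -1e-12)) return("mu must be >= 0")
  TRUE
})

#' Stack of oblique-illumination intensity images
#'
#' The acquisition unit: one intensity image and one matching background
#' (flat-field, sample-free) image per half-ring orientation.
#'
#' @slot images list of nonnegative matrices.
#' @slot backgrounds list of strictly positive matrices (same shapes).
#' @slot orientationsDeg orientation of each image (degrees).
#' @slot config the [AcquisitionConfig-class] used.
#' @export
setClass("DPCStack", representation(
  images = "list", backgrounds = "list",
  orientationsDeg = "numeric", config = "AcquisitionConfig"
))

setValidity("DPCStack", function(object) {
  msg <- character()
  n <- length(object@images)
  if (length(object@backgrounds) != n || length(object@orientationsDeg) != n)
    msg <- c(msg, "images, backgrounds and orientationsDeg must have equal length")
  if (n > 0) {
    d <- dim(object@images[[1]])
    same <- all(vapply(c(object@images, object@backgrounds),
                       function(m) identical(dim(m), d), logical(1)))
    if (!same) msg <- c(msg, "all images and backgrounds must share one shape")
    if (any(vapply(object@backgrounds, function(m) any(m <= 0), logical(1))))
      msg <- c(msg, "backgrounds must be strictly positive")
  }
  if (length(unique(object@orientationsDeg %% 360)) < 2L)
    msg <- c(msg, "at least 2 distinct orientations are required")
  if (length(msg)) msg else TRUE
})

#' Result of a qDPC reconstruction
#'
#' @slot phi retrieved double-pass phase (radians).
#' @slot mu retrieved double-pass attenuation exponent.
#' @slot kMap extinction-coefficient map, kMap = mu lambda / (2 pi L) with L
#'   the assumed total (double-pass) optical path.
#' @slot tauAbs,tauPh regularization weights actually used.
#' @slot pathLengthNm total path length L (nm) used for the mu -> k conversion.
#' @slot config the [AcquisitionConfig-class] used (provenance).
#' @export
setClass("ReconstructionResult", representation(
  phi = "matrix", mu = "matrix", kMap = "matrix",
  tauAbs = "numeric", tauPh = "numeric", pathLengthNm = "numeric",
  config = "AcquisitionConfig"
))

setValidity("ReconstructionResult", function(object) {
  if (!all(is.finite(object@phi)) || !all(is.finite(object@mu)) ||
      !all(is.finite(object@kMap))) return("all result maps must be finite")
  TRUE
})

#' Illumination-direction estimate
#'
#' @slot angleDeg estimated mean illumination direction in [0, 360).
#' @slot radonProfile center-projection value per probed angle.
#' @slot profileAngles probed angles (degrees) matching radonProfile.
#' @slot confidence ratio of the peak to the median profile value.
#' @export
setClass("DirectionEstimate", representation(
  angleDeg = "numeric", radonProfile = "numeric",
  profileAngles = "numeric", confidence = "numeric"
))

#' Contrast report for one region of interest
#'
#' @slot sigma population standard deviation over the ROI.
#' @slot median median ROI value.
#' @slot sigmaOverMedian sigma / median.
#' @slot michelson Michelson contrast (Imax - Imin)/(Imax + Imin).
#' @slot roi short descriptor of the ROI used.
#' @export
setClass("ContrastReport", representation(
  sigma = "numeric", median = "numeric", sigmaOverMedian = "numeric",
  michelson = "numeric", roi = "character"
))

#' Fenestration-cluster analysis report
#'
#' @slot nClusters number of detected clusters.
#' @slot clusterK extinction coefficient per detected cluster.
#' @slot membraneK per-pixel extinction values of the segmented membrane.
#' @slot clusterMean,clusterStd,membraneMean,membraneStd summary statistics.
#' @slot clusters data.frame(row, col, k) of detections.
#' @slot detectionParams list(paraboloidRadiusPx, prominence, onResidual).
#' @export
setClass("FenestrationReport", representation(
  nClusters = "integer", clusterK = "numeric", membraneK = "numeric",
  clusterMean = "numeric", clusterStd = "numeric",
  membraneMean = "numeric", membraneStd = "numeric",
  clusters = "data.frame", detectionParams = "list"
))

setValidity("FenestrationReport", function(object) {
  if (object@nClusters != length(object@clusterK))
    return("nClusters must equal length(clusterK)")
  TRUE
})
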