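#' @include AllClasses.R
NULL

#' Accessors for uvqdpc data classes
#'
#' Small accessor family in place of direct slot access: `kMap()` returns the
#' extinction-coefficient map of a phantom or reconstruction, `muMap()` and
#' `phiMap()` the attenuation-exponent and phase maps, `images()`,
#' `backgrounds()` and `orientations()` the content of a [DPCStack-class],
#' `pupilValues()` the frequency-domain array of a pupil or source, and
#' `truthLabels()` / `truthClusters()` the ground truth of a phantom.
#'
#' @param x an object of the matching class.
#' @return the slot content (matrix, list, numeric vector, or data.frame).
#' @name accessors
#' @aliases kMap muMap phiMap images backgrounds orientations pupilValues
#'   truthLabels truthClusters
NULL

#' @rdname accessors
#' @export
setGeneric("kMap", function(x) standardGeneric("kMap"))
#' @rdname accessors
#' @export
setMethod("kMap", "ComplexPhantom", function(x) x@kMap)
#' @rdname accessors
#' @export
setMethod("kMap", "ReconstructionResult", function(x) x@kMap)

#' @rdname accessors
#' @export
setGeneric("muMap", function(x) standardGeneric("muMap"))
#' @rdname accessors
#' @export
setMethod("muMap", "EffectiveObject", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("muMap", "ReconstructionResult", function(x) x@mu)

#' @rdname accessors
#' @export
setGeneric("phiMap", function(x) standardGeneric("phiMap"))
#' @rdname accessors
#' @export
setMethod("phiMap", "EffectiveObject", function(x) x@phi)
#' @rdname accessors
#' @export
setMethod("phiMap", "ReconstructionResult", function(x) x@phi)

#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname accessors
#' @export
setMethod("images", "DPCStack", function(x) x@images)

#' @rdname accessors
#' @export
setGeneric("backgrounds", function(x) standardGeneric("backgrounds"))
#' @rdname accessors
#' @export
setMethod("backgrounds", "DPCStack", function(x) x@backgrounds)

#' @rdname accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname accessors
#' @export
setMethod("orientations", "DPCStack", function(x) x@orientationsDeg)

#' @rdname accessors
#' @export
setGeneric("pupilValues", function(x) standardGeneric("pupilValues"))
#' @rdname accessors
#' @export
setMethod("pupilValues", "PupilFunction", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("pupilValues", "SourceDistribution", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setMethod("truthLabels", "ComplexPhantom", function(x) x@truthLabels)

#' @rdname accessors
#' @export
setGeneric("truthClusters", function(x) standardGeneric("truthClusters"))
#' @rdname accessors
#' @export
setMethod("truthClusters", "ComplexPhantom", function(x) x@truthClusters)

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig:",
      sprintf("lambda %g nm (FWHM %g nm), NA %g / obscuration %g, n %g",
              object@wavelengthNm, object@bandwidthNm, object@na,
              object@naObs, object@nMedium), "\n")
  cat(sprintf("  %d x %d px @ %g nm, tau = (%g, %g), orientations: %s deg\n",
              object@imageShape[1], object@imageShape[2], object@pixelSizeNm,
              object@tauAbs, object@tauPh,
              paste(object@orientationsDeg, collapse = ", ")))
})

setMethod("show", "PupilFunction", function(object) {
  cat(sprintf("PupilFunction: %d x %d grid, NA %g / %g at %g nm, %d nonzero px\n",
              nrow(object@values), ncol(object@values), object@na, object@naObs,
              object@wavelengthNm, sum(Mod(object@values) > 0)))
})

setMethod("show", "SourceDistribution", function(object) {
  ang <- atan2(object@orientation[2], object@orientation[1]) * 180 / pi
  cat(sprintf("SourceDistribution: %d x %d grid, orientation %.1f deg, total weight %g\n",
              nrow(object@values), ncol(object@values), ang %% 360, sum(object@values)))
})

setMethod("show", "TransferFunctions", function(object) {
  cat(sprintf("TransferFunctions: %d x %d grid, B = %g, hAbs(0) = %g\n",
              nrow(object@hAbs), ncol(object@hAbs), object@background,
              Re(object@hAbs[gridCenter(nrow(object@hAbs)), gridCenter(ncol(object@hAbs))])))
})

setMethod("show", "ComplexPhantom", function(object) {
  cat(sprintf("ComplexPhantom: %d x %d px @ %g nm, %d clusters, k in [%g, %g]\n",
              nrow(object@kMap), ncol(object@kMap), object@pixelSizeNm,
              nrow(object@truthClusters), min(object@kMap), max(object@kMap)))
})

setMethod("show", "EffectiveObject", function(object) {
  cat(sprintf("EffectiveObject: %d x %d px, max |phi| = %.4g rad, max mu = %.4g\n",
              nrow(object@phi), ncol(object@phi), max(abs(object@phi)), max(object@mu)))
})

setMethod("show", "DPCStack", function(object) {
  cat(sprintf("DPCStack: %d orientations (%s deg), %d x %d px\n",
              length(object@images), paste(object@orientationsDeg, collapse = ", "),
              nrow(object@images[[1]]), ncol(object@images[[1]])))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult: %d x %d px, tau = (%g, %g), L = %g nm\n",
              nrow(object@kMap), ncol(object@kMap), object@tauAbs, object@tauPh,
              object@pathLengthNm))
  cat(sprintf("  k in [%.3g, %.3g], phi in [%.3g, %.3g] rad\n",
              min(object@kMap), max(object@kMap), min(object@phi), max(object@phi)))
})

setMethod("show", "DirectionEstimate", function(object) {
  cat(sprintf("DirectionEstimate: %.2f deg (confidence %.3f)\n",
              object@angleDeg, object@confidence))
})

setMethod("show", "ContrastReport", function(object) {
  cat(sprintf("ContrastReport [%s]: sigma/median = %.4g, Michelson = %.4g\n",
              object@roi, object@sigmaOverMedian, object@michelson))
})

setMethod("show", "FenestrationReport", function(object) {
  cat(sprintf("FenestrationReport: %d clusters, cluster k = %.3g +/- %.3g, membrane k = %.3g +/- %.3g\n",
              object@nClusters, object@clusterMean, object@clusterStd,
              object@membraneMean, object@membraneStd))
})
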