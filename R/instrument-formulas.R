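#' Depth of field of an obscured objective (truncated Ewald sphere)
#'
#' The central obscuration of a Cassegrain-type objective removes the low-NA
#' part of the generalized pupil, which lengthens the depth of field relative
#' to an unobscured objective of equal NA. Modeling the generalized pupil as
#' a *truncated* Ewald-sphere cap gives
#' \deqn{\Delta z = \frac{\lambda_0}{n}\left(\sqrt{1 - NA_{obs}^2/n^2}
#'   - \sqrt{1 - NA^2/n^2}\right)^{-1}.}
#' With naObs = 0 and small NA this reduces to the classical 2 n lambda / NA^2.
#'
#' @param config an [AcquisitionConfig-class].
#' @return depth of field in micrometres.
#' @examples
#' depthOfField(acquisitionConfig())  # 1.355 um for the reference instrument
#' @export
depthOfField <- function(config) {
  stopifnot(is(config, "AcquisitionConfig"))
  na <- config@na; naObs <- config@naObs; n <- config@nMedium
  if (naObs < 0 || naObs > na) stop("require 0 <= naObs <= na")
  if (na > n) stop("domain error: na must not exceed nMedium")
  denom <- sqrt(1 - naObs^2 / n^2) - sqrt(1 - na^2 / n^2)
  if (denom <= .Machine$double.eps)
    stop("degenerate pupil: na equals naObs, depth of field diverges")
  (config@wavelengthNm / n) / denom / 1000
}

#' Theoretical lateral resolution
#'
#' Diffraction-limited two-point resolution lambda / (2 NA).
#'
#' @param config an [AcquisitionConfig-class].
#' @return resolution in nm.
#' @examples
#' theoreticalResolution(acquisitionConfig())  # 211.5 nm, ~212 nm
#' @export
theoreticalResolution <- function(config) {
  stopifnot(is(config, "AcquisitionConfig"), config@na > 0)
  config@wavelengthNm / (2 * config@na)
}

#' Bar-target line-pair frequency to spatial period
#'
#' Converts a resolution-target frequency in line pairs per millimetre to the
#' corresponding bar period, rounded to integer nanometres. Resolving a
#' 3300 lp/mm element demonstrates a resolving power of at least 303 nm.
#'
#' @param lpPerMm line pairs per millimetre (> 0).
#' @return period in nm (integer-rounded).
#' @examples
#' linepairResolution(3300)  # 303
#' @export
linepairResolution <- function(lpPerMm) {
  stopifnot(lpPerMm > 0)
  round(1e6 / lpPerMm)
}

#' Temporal coherence length of the source
#'
#' Uses the convention L_c = lambda^2 / dlambda. Note that for the reference
#' instrument the printed 6.8 um figure corresponds to a bandwidth of about
#' 11.1 nm under this convention; the nominal 10 nm bandwidth gives 7.56 um.
#'
#' @param config an [AcquisitionConfig-class].
#' @return coherence length in micrometres.
#' @export
coherenceLength <- function(config) {
  stopifnot(is(config, "AcquisitionConfig"), config@bandwidthNm > 0)
  config@wavelengthNm^2 / config@bandwidthNm / 1000
}

#' Illumination power budget at the sample
#'
#' Multiplies the nominal LED output by the loss chain of the illumination
#' path: beam-splitter transmission, half-ring mask (half the annulus),
#' the annular fraction of the pupil passed relative to the full NA
#' (naObs^2/na^2 models the obscuration-matched ring used for illumination),
#' and the fiber-coupling loss given by the ratio of the fiber core area to
#' the LED emitting surface.
#'
#' @param ledMw LED output power (mW).
#' @param splitter beam-splitter transmission factor.
#' @param halfmask half-ring mask factor.
#' @param naObs,na obscuration and full numerical apertures.
#' @param fiberCoreMm fiber core diameter (mm).
#' @param ledSideMm LED emitter side length (mm, square emitter).
#' @return power at the sample in mW.
#' @examples
#' powerBudget(80, 0.5, 0.5, 0.27, 0.65, 0.55, 2)  # ~0.2 mW
#' @export
powerBudget <- function(ledMw, splitter, halfmask, naObs, na, fiberCoreMm, ledSideMm) {
  stopifnot(ledMw >= 0, splitter >= 0, halfmask >= 0, naObs >= 0,
            na > 0, fiberCoreMm >= 0, ledSideMm > 0)
  ledMw * splitter * halfmask * (naObs^2 / na^2) *
    (pi * (fiberCoreMm / 2)^2) / (ledSideMm^2)
}
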