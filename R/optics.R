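#' Create an acquisition configuration
#'
#' Bundles the optical and numerical parameters of a reflection qDPC
#' acquisition. Defaults reproduce the reference instrument: a 275 nm LED of
#' 10 nm bandwidth behind a 0.65 NA Cassegrain-type objective whose secondary
#' mirror obscures frequencies below an equivalent 0.27 NA.
#'
#' A warning (not an error) is raised when `pixelSizeNm` violates the Nyquist
#' bound lambda/(4 NA) for the incoherent passband; simulations then alias.
#'
#' @param wavelengthNm center wavelength (nm).
#' @param bandwidthNm source bandwidth (nm).
#' @param na objective numerical aperture.
#' @param naObs obscuration numerical aperture (0 for an unobscured pupil).
#' @param nMedium refractive index of the imaging medium.
#' @param pixelSizeNm pixel pitch at the sample plane (nm).
#' @param imageShape integer (rows, cols).
#' @param tauAbs,tauPh Tikhonov regularization weights (see [solveQDPC()]).
#' @param orientationsDeg half-ring orientations in degrees, CCW from +x.
#' @return an [AcquisitionConfig-class] object.
#' @examples
#' cfg <- acquisitionConfig()
#' theoreticalResolution(cfg)
#' @export
acquisitionConfig <- function(wavelengthNm = 275, bandwidthNm = 10,
                              na = 0.65, naObs = 0.27, nMedium = 1,
                              pixelSizeNm = 100, imageShape = c(256L, 256L),
                              tauAbs = 300, tauPh = tauAbs,
                              orientationsDeg = c(0, 90, 180, 270)) {
  cfg <- new("AcquisitionConfig",
             wavelengthNm = as.numeric(wavelengthNm),
             bandwidthNm = as.numeric(bandwidthNm),
             na = as.numeric(na), naObs = as.numeric(naObs),
             nMedium = as.numeric(nMedium),
             pixelSizeNm = as.numeric(pixelSizeNm),
             imageShape = as.integer(imageShape),
             tauAbs = as.numeric(tauAbs), tauPh = as.numeric(tauPh),
             orientationsDeg = as.numeric(orientationsDeg))
  nyq <- cfg@wavelengthNm / (4 * cfg@na)
  if (cfg@pixelSizeNm > nyq + 1e-9)
    warning(sprintf("pixelSizeNm = %g exceeds the Nyquist bound lambda/(4 NA) = %.1f nm; simulated intensities will alias",
                    cfg@pixelSizeNm, nyq))
  cfg
}

#' Read an acquisition configuration from a YAML or JSON file
#'
#' Recognized keys: `wavelength_nm`, `bandwidth_nm`, `na`, `na_obs`,
#' `n_medium`, `pixel_size_nm`, `image_shape`, `tau_abs`, `tau_ph`,
#' `orientations_deg`. Missing keys fall back to the [acquisitionConfig()]
#' defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an [AcquisitionConfig-class] object.
#' @export
readAcquisitionConfig <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  pick <- function(key, arg) if (!is.null(lst[[key]])) args[[arg]] <<- lst[[key]]
  pick("wavelength_nm", "wavelengthNm"); pick("bandwidth_nm", "bandwidthNm")
  pick("na", "na"); pick("na_obs", "naObs"); pick("n_medium", "nMedium")
  pick("pixel_size_nm", "pixelSizeNm"); pick("image_shape", "imageShape")
  pick("tau_abs", "tauAbs"); pick("tau_ph", "tauPh")
  pick("orientations_deg", "orientationsDeg")
  do.call(acquisitionConfig, args)
}

#' Binary annular pupil of an obscured (Cassegrain-type) objective
#'
#' Builds the ideal pupil on the centered frequency grid implied by
#' `imageShape` and `pixelSizeNm`: 1 for naObs/lambda <= |u| <= na/lambda
#' (both edges closed), 0 elsewhere. With `naObs = 0` this is the full disc
#' pupil of an unobscured objective.
#'
#' @param config an [AcquisitionConfig-class].
#' @return a [PupilFunction-class].
#' @examples
#' p <- makeAnnularPupil(acquisitionConfig(imageShape = c(128L, 128L)))
#' @export
makeAnnularPupil <- function(config) {
  stopifnot(is(config, "AcquisitionConfig"))
  if (config@naObs >= config@na)
    stop("configuration error: naObs must be smaller than na")
  g <- frequencyGridNm(config@imageShape, config@pixelSizeNm)
  rOut <- config@na / config@wavelengthNm
  rIn <- config@naObs / config@wavelengthNm
  vals <- (g$ur <= rOut & g$ur >= rIn) * 1
  new("PupilFunction", values = vals, fxStep = g$dfx, fyStep = g$dfy,
      na = config@na, naObs = config@naObs, wavelengthNm = config@wavelengthNm)
}

#' Cosine-tapered radial source profile
#'
#' Optional radial weight for [makeHalfringSource()] mimicking the fall-off
#' of illumination towards the highest pupil frequencies caused by the
#' emission profile of a multimode fiber: weight 1 at the inner annulus edge
#' tapering as a half-cosine to `floorWeight` at the outer edge.
#'
#' @param n number of radial samples.
#' @param floorWeight weight at the outer pupil edge.
#' @return numeric vector of length `n`, usable as `radialWeight`.
#' @export
cosineRadialProfile <- function(n = 64, floorWeight = 0.25) {
  stopifnot(n >= 2, floorWeight >= 0, floorWeight <= 1)
  x <- seq(0, 1, length.out = n)
  floorWeight + (1 - floorWeight) * (1 + cos(pi * x)) / 2
}

#' Half-ring illumination source
#'
#' Masks an annular pupil to the half-plane u . d >= 0 where
#' d = (cos angle, sin angle) — the rotatable half-ring amplitude mask placed
#' in a pupil plane of the illumination relay. Pixels exactly on the dividing
#' line are included. An optional radial weight profile (over |u| from the
#' inner to the outer annulus edge) models non-uniform ring illumination.
#'
#' @param pupil a [PupilFunction-class].
#' @param angleDeg orientation of the mean illumination direction (degrees,
#'   CCW from +x).
#' @param radialWeight optional numeric profile (e.g. [cosineRadialProfile()]);
#'   `NULL` for a flat ring.
#' @return a [SourceDistribution-class].
#' @export
makeHalfringSource <- function(pupil, angleDeg, radialWeight = NULL) {
  stopifnot(is(pupil, "PupilFunction"))
  nr <- nrow(pupil@values); nc <- ncol(pupil@values)
  ## rebuild the grid from the stored steps (handles non-square shapes)
  r0 <- gridCenter(nr); c0 <- gridCenter(nc)
  ux <- matrix(rep((seq_len(nc) - c0) * pupil@fxStep, each = nr), nr, nc)
  uy <- matrix(rep(-(seq_len(nr) - r0) * pupil@fyStep, times = nc), nr, nc)
  th <- angleDeg * pi / 180
  d <- c(cos(th), sin(th))
  vals <- Mod(pupil@values) * (ux * d[1] + uy * d[2] >= -1e-15)
  if (!is.null(radialWeight)) {
    ur <- sqrt(ux^2 + uy^2)
    rIn <- pupil@naObs / pupil@wavelengthNm
    rOut <- pupil@na / pupil@wavelengthNm
    frac <- pmin(pmax((ur - rIn) / max(rOut - rIn, .Machine$double.eps), 0), 1)
    w <- stats::approx(seq(0, 1, length.out = length(radialWeight)),
                       radialWeight, xout = as.vector(frac))$y
    vals <- vals * matrix(w, nr, nc)
  }
  new("SourceDistribution", values = vals, orientation = d,
      fxStep = pupil@fxStep, fyStep = pupil@fyStep,
      radialWeight = if (is.null(radialWeight)) numeric(0) else as.numeric(radialWeight))
}

#' Weak-object transfer functions under partially coherent illumination
#'
#' For a source S and pupil P sharing one centered frequency grid, computes
#' the DC background term B = sum S |P|^2 and the absorption and phase
#' weak-object transfer functions
#' \deqn{h_{abs}(u) = -[C_1(u) + C_2(u)], \quad h_{ph}(u) = i [C_1(u) - C_2(u)]}
#' with the pupil cross-correlations
#' \eqn{C_1(u) = \sum_{u'} S(u') P^*(u') P(u'+u)} and
#' \eqn{C_2(u) = \sum_{u'} S(u') P(u') P^*(u'-u)}, evaluated with 2x
#' zero-padding so no correlation lag wraps. The signs make a weak pure
#' absorber reduce the measured intensity: h_abs(0) = -2B, h_ph(0) = 0.
#'
#' @param source a [SourceDistribution-class].
#' @param pupil a [PupilFunction-class] on the same grid.
#' @return a [TransferFunctions-class].
#' @export
computeWOTF <- function(source, pupil) {
  stopifnot(is(source, "SourceDistribution"), is(pupil, "PupilFunction"))
  S <- source@values; P <- pupil@values
  if (!identical(dim(S), dim(P)))
    stop("source and pupil must share one frequency grid")
  B <- sum(S * Mod(P)^2)
  if (B <= 0) stop("degenerate source: zero total weight inside the pupil")
  c1 <- crossCorrelate2(S * Conj(P), P)
  ## C2(u) = sum_w P*(w) (S P)(w + u)
  c2 <- crossCorrelate2(Conj(P), S * P)
  new("TransferFunctions",
      hAbs = -(c1 + c2), hPh = 1i * (c1 - c2), background = B,
      orientation = source@orientation,
      fxStep = source@fxStep, fyStep = source@fyStep)
}
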