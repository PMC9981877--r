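#' Contrast as standard deviation over median
#'
#' Contrast metric for textured regions such as sieve plates: the
#' (population) standard deviation of the ROI pixel values normalized by
#' their median. Invariant under multiplicative rescaling of the image.
#'
#' @param image numeric matrix.
#' @param roi logical/0-1 matrix selecting the region of interest, or `NULL`
#'   for the whole image.
#' @param roiLabel short descriptor stored in the report.
#' @return a [ContrastReport-class] (the Michelson slot is filled too, from
#'   the same ROI).
#' @examples
#' contrastSigmaMedian(matrix(c(1, 3), 4, 4))  # sigma/median = 0.5
#' @export
contrastSigmaMedian <- function(image, roi = NULL, roiLabel = "roi") {
  px <- roiPixels(image, roi)
  med <- stats::median(px)
  if (med == 0) stop("undefined metric: ROI median is zero")
  sig <- sqrt(mean((px - mean(px))^2))
  new("ContrastReport", sigma = sig, median = med,
      sigmaOverMedian = sig / med,
      michelson = michelsonValue(px), roi = roiLabel)
}

roiPixels <- function(image, roi) {
  stopifnot(is.matrix(image))
  if (is.null(roi)) return(as.vector(image))
  px <- image[roi > 0]
  if (length(px) == 0) stop("empty ROI")
  px
}

michelsonValue <- function(px, robustPercentiles = NULL) {
  if (is.null(robustPercentiles)) {
    hi <- max(px); lo <- min(px)
  } else {
    q <- stats::quantile(px, sort(robustPercentiles) / 100, names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  if (hi + lo == 0) stop("undefined metric: Imax + Imin is zero")
  (hi - lo) / (hi + lo)
}

#' Michelson contrast
#'
#' c = (Imax - Imin) / (Imax + Imin) over the ROI. The default uses the true
#' extrema (matching the textbook formula); `robustPercentiles = c(0.1,
#' 99.9)` substitutes percentiles to resist single-pixel outliers.
#'
#' @param image nonnegative numeric matrix.
#' @param roi logical/0-1 ROI mask or `NULL` for the whole image.
#' @param robustPercentiles optional length-2 percentages for robust extrema.
#' @return scalar in [0, 1] for nonnegative images.
#' @export
contrastMichelson <- function(image, roi = NULL, robustPercentiles = NULL) {
  michelsonValue(roiPixels(image, roi), robustPercentiles)
}

#' Contrast improvement ratio
#'
#' Ratio of a new contrast value over a reference contrast, as used to
#' compare qDPC-processed UVC images against brightfield, DIC and
#' holotomography.
#'
#' @param contrastNew contrast of the new modality.
#' @param contrastRef reference contrast (> 0).
#' @return scalar ratio.
#' @examples
#' improvementRatio(0.586, 0.084)  # ~7x over DIC
#' @export
improvementRatio <- function(contrastNew, contrastRef) {
  stopifnot(contrastRef > 0)
  contrastNew / contrastRef
}

#' Bar-target visibility of a reconstruction
#'
#' Michelson visibility of the reconstructed extinction map of a bar target,
#' measured on the mean profile across the bar-normal direction (robust
#' percentile extrema, clamped to [0, 1]). Used to verify which line-pair
#' frequencies the imaging + reconstruction chain resolves.
#'
#' @param recon a [ReconstructionResult-class] of a bar-target acquisition.
#' @param barPhantom the [ComplexPhantom-class] from [makeBarTarget()]
#'   (supplies the line-pair frequency metadata).
#' @param percentiles robust extrema percentages for the profile.
#' @return visibility in [0, 1].
#' @export
barTargetVisibility <- function(recon, barPhantom, percentiles = c(2, 98)) {
  stopifnot(is(recon, "ReconstructionResult"), is(barPhantom, "ComplexPhantom"))
  if (is.null(barPhantom@meta$lpPerMm))
    stop("phantom does not carry lpPerMm metadata; is it a bar target?")
  k <- recon@kMap
  nr <- nrow(k); nc <- ncol(k)
  rows <- seq(floor(nr / 4), ceiling(3 * nr / 4))
  cols <- seq(floor(nc / 4), ceiling(3 * nc / 4))
  profile <- colMeans(k[rows, cols])
  q <- stats::quantile(profile, sort(percentiles) / 100, names = FALSE)
  lo <- q[1]; hi <- q[2]
  if (hi + lo <= 0) return(if (hi > lo) 1 else 0)
  max(0, min(1, (hi - lo) / (hi + lo)))
}
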