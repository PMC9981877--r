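## Seeded synthetic-data generators: LSEC-like complex phantoms, USAF-style
## bar targets and bead fields, all with known ground truth. Every random
## draw flows from the single integer seed passed in; the caller's RNG state
## is left untouched.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Anti-aliased disc coverage rendered into a full-size matrix: fraction of
## each pixel covered by the disc (subpixel supersampling, ss x ss).
discCoverage <- function(shape, rowC, colC, radiusPx, ss = 4L) {
  out <- matrix(0, shape[1], shape[2])
  if (radiusPx <= 0) return(out)
  r1 <- max(1L, floor(rowC - radiusPx - 1)); r2 <- min(shape[1], ceiling(rowC + radiusPx + 1))
  c1 <- max(1L, floor(colC - radiusPx - 1)); c2 <- min(shape[2], ceiling(colC + radiusPx + 1))
  if (r1 > r2 || c1 > c2) return(out)
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  rows <- r1:r2; cols <- c1:c2
  cov <- matrix(0, length(rows), length(cols))
  for (dy in sub) for (dx in sub) {
    dr <- outer((rows + dy) - rowC, rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), (cols + dx) - colC)
    cov <- cov + (dr * dr + dc * dc <= radiusPx^2)
  }
  out[rows, cols] <- cov / (ss * ss)
  out
}

## Hard (pixel-center) mask of a smoothly perturbed ellipse; used for the
## cell body and nucleus so constant-k regions stay exactly two-level.
blobMask <- function(shape, rowC, colC, radiusPx, aspect = 1, wobble = 0.1,
                     harmonics = 2:4, phases = NULL, amps = NULL) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2]) - rowC
  cc <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2]) - colC
  th <- atan2(rr * aspect, cc)
  rad <- sqrt(cc^2 + (rr * aspect)^2)
  if (is.null(phases)) phases <- rep(0, length(harmonics))
  if (is.null(amps)) amps <- rep(0, length(harmonics))
  pert <- matrix(0, shape[1], shape[2])
  for (i in seq_along(harmonics))
    pert <- pert + amps[i] * cos(harmonics[i] * th + phases[i])
  rad <= radiusPx * (1 + wobble * pert)
}

#' Synthetic LSEC-like complex phantom
#'
#' Generates a liver-sinusoidal-endothelial-cell-like ground-truth object: a
#' thin plasma membrane region (drawn thickness 100-200 nm, the expected
#' sieve-plate thickness) around a thicker nucleus, with `nClusters`
#' fenestration-cluster (sieve-plate) sites planted on the membrane. Each
#' cluster is a patch of radius drawn from `clusterRadiusRangeNm` perforated
#' by several sub-diffraction fenestrations: zero-extinction holes (radius
#' from `fenestrationRadiusRangeNm`) each surrounded by an elevated-
#' extinction rim -- the locally denser cytoskeleton around fenestrations.
#' The patch is rescaled so the mean extinction over the cluster's labeled
#' pixels equals `clusterK` exactly. Clusters whose rendered radius falls
#' below one pixel are still recorded in the truth table and rendered as a
#' single pixel at `clusterK`.
#'
#' All maps are reproducible bit-for-bit for a fixed `seed`. If fewer than
#' `nClusters` non-overlapping sites fit on the membrane, the generator warns
#' and the truth table reflects the number actually planted.
#'
#' @param shape integer (rows, cols), at least 128 x 128.
#' @param pixelSizeNm pixel pitch (nm).
#' @param seed integer seed for all randomness.
#' @param nucleusK,membraneK,clusterK extinction-coefficient levels
#'   (defaults: nucleus 8e-4; membrane 2.7e-4 and cluster 3.4e-4, the
#'   reported LSEC means).
#' @param nClusters number of fenestration-cluster sites to plant.
#' @param fenestrationRadiusRangeNm hole radius range (nm), default 50-300.
#' @param clusterRadiusRangeNm sieve-plate footprint radius range (nm).
#' @param fenestrationsPerCluster integer range of fenestrations per cluster.
#' @param membraneThicknessRangeNm membrane thickness range (nm).
#' @param nucleusThicknessNm nucleus thickness (nm); kept moderate so the
#'   weak-object approximation remains valid.
#' @param deltaN real refractive-index increment of cellular pixels.
#' @return a [ComplexPhantom-class].
#' @examples
#' ph <- makeLsecPhantom(shape = c(128L, 128L), nClusters = 5, seed = 2)
#' @export
makeLsecPhantom <- function(shape = c(256L, 256L), pixelSizeNm = 100, seed = 1,
                            nucleusK = 8e-4, membraneK = 2.7e-4, clusterK = 3.4e-4,
                            nClusters = 40,
                            fenestrationRadiusRangeNm = c(50, 300),
                            clusterRadiusRangeNm = c(300, 700),
                            fenestrationsPerCluster = c(4L, 12L),
                            membraneThicknessRangeNm = c(100, 200),
                            nucleusThicknessNm = 500, deltaN = 0.02) {
  shape <- as.integer(shape)
  if (any(shape < 128L)) stop("shape must be at least 128 x 128")
  withSeed(seed, {
    nr <- shape[1]; nc <- shape[2]
    ctr <- c(nr, nc) / 2 + stats::runif(2, -0.03, 0.03) * min(shape)
    cellR <- 0.40 * min(shape)
    cell <- blobMask(shape, ctr[1], ctr[2], cellR,
                     aspect = stats::runif(1, 0.85, 1.15), wobble = 0.12,
                     phases = stats::runif(3, 0, 2 * pi),
                     amps = stats::runif(3, 0.3, 1))
    nucR <- 0.16 * min(shape)
    nth <- stats::runif(1, 0, 2 * pi)
    nctr <- ctr + 0.10 * min(shape) * c(sin(nth), cos(nth))
    nucleus <- blobMask(shape, nctr[1], nctr[2], nucR,
                        aspect = stats::runif(1, 0.9, 1.2), wobble = 0.06,
                        phases = stats::runif(3, 0, 2 * pi),
                        amps = stats::runif(3, 0.3, 1)) & cell

    labels <- matrix(0L, nr, nc)
    labels[cell] <- 1L
    labels[nucleus] <- 2L
    k <- matrix(0, nr, nc)
    k[labels == 1L] <- membraneK
    k[labels == 2L] <- nucleusK

    tMembrane <- stats::runif(1, membraneThicknessRangeNm[1], membraneThicknessRangeNm[2])
    thickness <- matrix(0, nr, nc)
    thickness[labels == 1L] <- tMembrane
    thickness[labels == 2L] <- nucleusThicknessNm
    dn <- matrix(0, nr, nc)
    dn[labels > 0L] <- deltaN

    rimWidthNm <- max(pixelSizeNm, 100)
    maxRcPx <- max(clusterRadiusRangeNm) / pixelSizeNm
    minSepPx <- 2 * maxRcPx + 4
    ## candidate centers: membrane pixels away from any region boundary
    inner <- EBImage::erode(EBImage::Image((labels == 1L) * 1),
                            EBImage::makeBrush(2L * ceiling(maxRcPx) + 3L, "disc"))
    cand <- which(EBImage::imageData(inner) > 0.5, arr.ind = TRUE)
    placed <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    if (nClusters > 0 && nrow(cand) > 0) {
      ord <- sample.int(nrow(cand))
      for (i in ord) {
        if (nrow(placed) >= nClusters) break
        p <- cand[i, ]
        if (nrow(placed) == 0 ||
            min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) >= minSepPx^2) {
          placed <- rbind(placed, p)
          radii <- c(radii, stats::runif(1, clusterRadiusRangeNm[1],
                                         clusterRadiusRangeNm[2]))
        }
      }
      if (nrow(placed) < nClusters)
        warning(sprintf("only %d of %d requested clusters fit on the membrane",
                        nrow(placed), nClusters))
    }

    for (j in seq_len(nrow(placed))) {
      rC <- placed[j, 1]; cC <- placed[j, 2]
      rcPx <- radii[j] / pixelSizeNm
      lab <- discCoverage(shape, rC, cC, max(rcPx, 0.4), ss = 1L) > 0.5  # center inside
      if (rcPx < 0.7 || sum(lab) < 2) {  # sub-pixel site: single-pixel rendering
        k[rC, cC] <- clusterK
        labels[rC, cC] <- 3L
        next
      }
      ## sieve-plate patch: membrane-level base perforated by zero-k holes,
      ## each surrounded by an elevated-k rim (denser cytoskeleton)
      nf <- sample(fenestrationsPerCluster[1]:fenestrationsPerCluster[2], 1)
      patch <- membraneK * (discCoverage(shape, rC, cC, rcPx) > 0)
      for (q in seq_len(nf)) {
        rHole <- stats::runif(1, fenestrationRadiusRangeNm[1],
                              fenestrationRadiusRangeNm[2]) / pixelSizeNm
        rOut <- rHole + rimWidthNm / pixelSizeNm
        a <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * max(rcPx - rOut, 0.1)
        fr <- rC - rad * sin(a); fc <- cC + rad * cos(a)
        covOut <- discCoverage(shape, fr, fc, rOut)
        covIn <- discCoverage(shape, fr, fc, rHole)
        rim <- pmax(covOut - covIn, 0)
        ## carve the hole, then raise the rim above the local level
        patch <- patch * (1 - covIn) + 2 * membraneK * rim
      }
      m <- mean(patch[lab])
      if (m <= 0) { k[rC, cC] <- clusterK; labels[rC, cC] <- 3L; next }
      k[lab] <- patch[lab] * (clusterK / m)
      labels[lab] <- 3L
    }

    truth <- data.frame(row = as.integer(placed[, 1]),
                        col = as.integer(placed[, 2]),
                        radiusNm = radii)
    if (nrow(placed) == 0)
      truth <- data.frame(row = integer(0), col = integer(0), radiusNm = numeric(0))

    new("ComplexPhantom", deltaN = dn, kMap = k, thickness = thickness,
        pixelSizeNm = pixelSizeNm, truthLabels = labels, truthClusters = truth,
        meta = list(kind = "lsec", seed = seed, membraneThicknessNm = tMembrane,
                    nucleusThicknessNm = nucleusThicknessNm,
                    nucleusK = nucleusK, membraneK = membraneK, clusterK = clusterK,
                    rimWidthNm = rimWidthNm))
  })
}

#' USAF-style absorbing bar target
#'
#' Alternating absorbing bars (duty cycle 1/2) at the requested line-pair
#' frequency, rendered with anti-aliased edges by per-column subsampling.
#' Bars run vertically; the pattern varies along columns (+x).
#'
#' @param lpPerMm line pairs per millimetre.
#' @param shape integer (rows, cols).
#' @param pixelSizeNm pixel pitch (nm).
#' @param kContrast extinction coefficient of the absorbing bars; 0 gives an
#'   empty phantom.
#' @param thicknessNm bar layer thickness (nm).
#' @param deltaN refractive-index increment of the bars (default 0: pure
#'   absorption target).
#' @return a [ComplexPhantom-class] carrying `lpPerMm` in its `meta` list.
#' @export
makeBarTarget <- function(lpPerMm, shape = c(256L, 256L), pixelSizeNm = 100,
                          kContrast = 5e-4, thicknessNm = 150, deltaN = 0) {
  shape <- as.integer(shape)
  periodPx <- 1e6 / lpPerMm / pixelSizeNm
  if (periodPx < 2)
    stop(sprintf("aliasing error: bar period %.2f px is below 2 pixels", periodPx))
  ss <- 16L
  xs <- rep(seq_len(shape[2]) - 1, each = ss) + (rep(seq_len(ss), shape[2]) - 0.5) / ss
  bar <- (xs %% periodPx) < periodPx / 2
  cov <- colMeans(matrix(bar, ss, shape[2]))
  k <- matrix(rep(cov * kContrast, each = shape[1]), shape[1], shape[2])
  dn <- matrix(rep(cov * deltaN, each = shape[1]), shape[1], shape[2])
  present <- kContrast > 0 || deltaN != 0
  labels <- matrix(ifelse(present & rep(cov, each = shape[1]) > 0, 1L, 0L),
                   shape[1], shape[2])
  if (!present) { k[] <- 0; dn[] <- 0 }
  thickness <- matrix(0, shape[1], shape[2])
  thickness[k > 0 | dn != 0] <- thicknessNm
  new("ComplexPhantom", deltaN = dn, kMap = k, thickness = thickness,
      pixelSizeNm = pixelSizeNm, truthLabels = labels,
      truthClusters = data.frame(row = integer(0), col = integer(0),
                                 radiusNm = numeric(0)),
      meta = list(kind = "bars", lpPerMm = lpPerMm, periodPx = periodPx,
                  kContrast = kContrast, thicknessNm = thicknessNm))
}

#' Random bead field
#'
#' Field of small absorbing/refracting discs emulating polystyrene beads or
#' scattering debris; the standard fixture for illumination-direction and
#' pupil calibration.
#'
#' @param shape integer (rows, cols).
#' @param pixelSizeNm pixel pitch (nm).
#' @param nBeads number of beads.
#' @param beadRadiusNm bead radius (nm).
#' @param k extinction coefficient of the beads.
#' @param deltaN refractive-index increment of the beads.
#' @param thicknessNm bead thickness (nm).
#' @param seed integer seed.
#' @return a [ComplexPhantom-class].
#' @export
makeBeadPhantom <- function(shape = c(256L, 256L), pixelSizeNm = 100,
                            nBeads = 120, beadRadiusNm = 150, k = 4e-4,
                            deltaN = 0.015, thicknessNm = 200, seed = 1) {
  shape <- as.integer(shape)
  withSeed(seed, {
    rPx <- beadRadiusNm / pixelSizeNm
    margin <- ceiling(rPx) + 2
    kmap <- matrix(0, shape[1], shape[2])
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(placed) < nBeads && tries < nBeads * 50) {
      tries <- tries + 1
      p <- c(stats::runif(1, margin, shape[1] - margin),
             stats::runif(1, margin, shape[2] - margin))
      if (nrow(placed) == 0 ||
          min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) >= (2 * rPx + 2)^2) {
        placed <- rbind(placed, p)
        kmap <- kmap + discCoverage(shape, p[1], p[2], max(rPx, 0.6))
      }
    }
    cov <- pmin(kmap, 1)
    labels <- matrix(0L, shape[1], shape[2]); labels[cov > 0] <- 1L
    thickness <- matrix(0, shape[1], shape[2]); thickness[cov > 0] <- thicknessNm
    new("ComplexPhantom", deltaN = cov * deltaN, kMap = cov * k,
        thickness = thickness, pixelSizeNm = pixelSizeNm, truthLabels = labels,
        truthClusters = data.frame(row = round(placed[, 1]), col = round(placed[, 2]),
                                   radiusNm = rep(beadRadiusNm, nrow(placed))),
        meta = list(kind = "beads", seed = seed, nBeads = nrow(placed)))
  })
}

#' Phantom to effective weak object
#'
#' Converts a complex phantom to the double-pass phase and attenuation maps
#' seen by the reflection-geometry microscope: the reflective geometry
#' doubles the effective path through the sample, so
#' \deqn{\phi = 2 \frac{2\pi}{\lambda} \Delta n \, t, \qquad
#'       \mu = 2 \frac{2\pi}{\lambda} k \, t.}
#' Warns when the weak-object regime (max mu and max |phi| below 0.5) is
#' violated.
#'
#' @param phantom a [ComplexPhantom-class].
#' @param config an [AcquisitionConfig-class] (supplies the wavelength).
#' @return an [EffectiveObject-class].
#' @export
phantomToEffectiveObject <- function(phantom, config) {
  stopifnot(is(phantom, "ComplexPhantom"), is(config, "AcquisitionConfig"))
  f <- 2 * (2 * pi / config@wavelengthNm)
  phi <- f * phantom@deltaN * phantom@thickness
  mu <- f * phantom@kMap * phantom@thickness
  if (max(mu) >= 0.5 || max(abs(phi)) >= 0.5)
    warning(sprintf("object outside the weak regime: max mu = %.3g, max |phi| = %.3g",
                    max(mu), max(abs(phi))))
  new("EffectiveObject", phi = phi, mu = mu, pixelSizeNm = phantom@pixelSizeNm)
}
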