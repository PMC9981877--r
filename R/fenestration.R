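#' Three-class segmentation of an extinction map
#'
#' Splits a reconstructed extinction-coefficient map into background, plasma
#' membrane and nucleus by thresholding a smoothed copy of the map, followed
#' by morphological cleanup. Thresholds are either supplied or derived from
#' a 3-level histogram split (1-D k-means initialized at fixed quantiles, so
#' the split is deterministic). A pluggable replacement for a trainable
#' pixel classifier, preserving the same mask contract.
#'
#' @param kMap extinction-coefficient matrix (finite).
#' @param smoothSigmaPx Gaussian smoothing before thresholding (pixels).
#' @param thresholds optional increasing length-2 numeric (background/membrane
#'   and membrane/nucleus cuts); derived from the histogram if `NULL`.
#' @param cleanupPx brush size for the morphological opening/closing; 0
#'   disables cleanup.
#' @return integer matrix: 0 background, 1 membrane, 2 nucleus (classes are
#'   mutually exclusive and exhaustive).
#' @export
segmentMembrane <- function(kMap, smoothSigmaPx = 2, thresholds = NULL,
                            cleanupPx = 5) {
  stopifnot(is.matrix(kMap), all(is.finite(kMap)))
  sm <- if (smoothSigmaPx > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(kMap), sigma = smoothSigmaPx))
  else kMap
  if (is.null(thresholds)) {
    v <- as.vector(sm)
    if (diff(range(v)) == 0)            # flat map: everything is background
      return(matrix(0L, nrow(kMap), ncol(kMap)))
    init <- stats::quantile(v, c(0.25, 0.7, 0.98), names = FALSE)
    if (anyDuplicated(init))
      stop("segmentation failure: degenerate histogram (no 3-level split)")
    km <- stats::kmeans(v, centers = matrix(init, 3, 1))
    ctr <- sort(km$centers[, 1])
    thresholds <- c(mean(ctr[1:2]), mean(ctr[2:3]))
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lab <- matrix(0L, nrow(kMap), ncol(kMap))
  lab[sm >= thresholds[1]] <- 1L
  lab[sm >= thresholds[2]] <- 2L
  if (cleanupPx > 0) {
    br <- EBImage::makeBrush(2L * floor(cleanupPx / 2) + 1L, "disc")
    nuc <- EBImage::imageData(EBImage::closing(EBImage::opening(
      EBImage::Image((lab == 2L) * 1), br), br)) > 0.5
    cellm <- EBImage::imageData(EBImage::closing(EBImage::opening(
      EBImage::Image((lab >= 1L) * 1), br), br)) > 0.5
    lab <- matrix(0L, nrow(kMap), ncol(kMap))
    lab[cellm] <- 1L
    lab[nuc] <- 2L
  }
  lab
}

## Separable grayscale erosion/dilation with a parabolic structuring
## function b(d) = -c d^2 (1-D passes along rows then columns).
parabolic1D <- function(m, c, win, dilate = FALSE) {
  n <- nrow(m)
  out <- m
  for (s in seq_len(win)) {
    pen <- c * s^2
    up <- rbind(m[-seq_len(s), , drop = FALSE],
                matrix(if (dilate) -Inf else Inf, s, ncol(m)))
    dn <- rbind(matrix(if (dilate) -Inf else Inf, s, ncol(m)),
                m[seq_len(n - s), , drop = FALSE])
    out <- if (dilate) pmax(out, up - pen, dn - pen)
           else pmin(out, up + pen, dn + pen)
  }
  out
}

parabolicMorph <- function(image, c, win, dilate = FALSE) {
  t(parabolic1D(t(parabolic1D(image, c, win, dilate)), c, win, dilate))
}

#' Sliding-paraboloid background estimation
#'
#' Estimates a slowly varying background as the grayscale opening of the
#' image by a paraboloid of revolution, in the spirit of the classical
#' sliding-paraboloid background-removal filter: the paraboloid `z =
#' d^2/(2 radiusPx)` (in units where the image's robust range is 100) slides
#' under the image surface; narrow peaks are cut off while ramps and smooth
#' undulations are followed exactly. The opening is computed separably and
#' is idempotent; `background <= image` and `residual >= 0` hold everywhere.
#'
#' @param image numeric matrix.
#' @param radiusPx paraboloid radius parameter (>= 1); larger values remove
#'   only broader structures.
#' @param intensityScale intensity range mapped to the internal 0-100 scale;
#'   defaults to the image's robust (0.1-99.9 percentile) range. Fixing it
#'   makes repeated applications exactly idempotent.
#' @return list(background = matrix, residual = matrix).
#' @export
slidingParaboloidBackground <- function(image, radiusPx = 10,
                                        intensityScale = NULL) {
  stopifnot(is.matrix(image), radiusPx >= 1)
  q <- stats::quantile(image, c(0.001, 0.999), names = FALSE)
  rng <- if (is.null(intensityScale)) q[2] - q[1] else intensityScale
  if (rng <= 0) rng <- diff(range(image))   # nearly flat: robust range collapses
  if (rng <= 0)
    return(list(background = image, residual = matrix(0, nrow(image), ncol(image))))
  z <- (image - q[1]) / rng * 100
  cc <- 1 / (2 * radiusPx)                 # curvature in scaled units / px^2
  win <- min(ceiling(sqrt((max(z) - min(z)) / cc)) + 1L, max(dim(image)) - 1L)
  er <- parabolicMorph(z, cc, win, dilate = FALSE)
  op <- parabolicMorph(er, cc, win, dilate = TRUE)
  bg <- pmin(op / 100 * rng + q[1], image)
  list(background = bg, residual = image - bg)
}

#' Detect local maxima by topographic prominence
#'
#' Finds local maxima whose topographic prominence -- peak height above the
#' highest saddle connecting it to any higher terrain -- exceeds a
#' threshold, by flood ordering with union-find (pixels visited in
#' decreasing value; when two catchments meet, the lower peak's prominence
#' is the difference between its height and the merge level). 8-connected;
#' plateau maxima count once. The global maximum's prominence is its height
#' above the image minimum.
#'
#' @param residual numeric matrix (typically the residual of
#'   [slidingParaboloidBackground()]).
#' @param prominence threshold (> 0) in image units; the reference analysis
#'   for LSEC extinction maps uses 0.00015.
#' @param mask optional logical matrix restricting detection to a region.
#' @param minDistancePx if > 0, non-maximum suppression: among detections
#'   closer than this distance only the highest-value one is kept (a rim-like
#'   cluster can otherwise contribute several maxima).
#' @return data.frame(row, col, value, prominence), ordered by decreasing
#'   value; zero rows if nothing exceeds the threshold.
#' @export
detectClusters <- function(residual, prominence = 0.00015, mask = NULL,
                           minDistancePx = 0) {
  stopifnot(is.matrix(residual), prominence > 0)
  nr <- nrow(residual); nc <- ncol(residual)
  sel <- if (is.null(mask)) rep(TRUE, nr * nc) else as.vector(mask > 0)
  vals <- as.vector(residual)
  idx <- which(sel)
  ord <- idx[order(vals[idx], decreasing = TRUE)]
  parent <- integer(nr * nc)               # 0 = unassigned
  peakVal <- numeric(0); peakPos <- integer(0); prom <- numeric(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  compId <- integer(nr * nc)               # root pixel -> component index
  nbOff <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (p in ord) {
    r <- ((p - 1L) %% nr) + 1L
    neigh <- p + nbOff
    ok <- rep(TRUE, 8L)
    if (r == 1L) ok[c(1L, 5L, 7L)] <- FALSE
    if (r == nr) ok[c(2L, 6L, 8L)] <- FALSE
    neigh <- neigh[ok]
    neigh <- neigh[neigh >= 1L & neigh <= nr * nc]
    neigh <- neigh[parent[neigh] != 0L]
    if (length(neigh) == 0L) {
      parent[p] <- p
      compId[p] <- length(peakVal) + 1L
      peakVal <- c(peakVal, vals[p]); peakPos <- c(peakPos, p)
      prom <- c(prom, NA_real_)
      next
    }
    roots <- unique(vapply(neigh, findRoot, integer(1)))
    parent[p] <- roots[1]
    if (length(roots) > 1L) {
      cids <- compId[roots]
      winner <- roots[which.max(peakVal[cids])]
      for (rt in roots) {
        if (rt == winner) next
        cid <- compId[rt]
        prom[cid] <- peakVal[cid] - vals[p]  # merge level = current value
        parent[rt] <- winner
      }
      parent[p] <- winner
    }
  }
  lowest <- if (any(sel)) min(vals[sel]) else 0
  prom[is.na(prom)] <- peakVal[is.na(prom)] - lowest
  keep <- which(prom >= prominence)
  out <- data.frame(
    row = ((peakPos[keep] - 1L) %% nr) + 1L,
    col = ((peakPos[keep] - 1L) %/% nr) + 1L,
    value = peakVal[keep],
    prominence = prom[keep])
  out <- out[order(out$value, decreasing = TRUE), , drop = FALSE]
  if (minDistancePx > 0 && nrow(out) > 1) {
    kept <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!any(kept)) { kept[i] <- TRUE; next }
      d2 <- (out$row[kept] - out$row[i])^2 + (out$col[kept] - out$col[i])^2
      if (min(d2) >= minDistancePx^2) kept[i] <- TRUE
    }
    out <- out[kept, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

discMean <- function(m, row, col, radiusPx) {
  if (radiusPx <= 0) return(m[row, col])
  r <- seq(max(1, row - radiusPx), min(nrow(m), row + radiusPx))
  c <- seq(max(1, col - radiusPx), min(ncol(m), col + radiusPx))
  sub <- m[r, c, drop = FALSE]
  d2 <- outer((r - row)^2, (c - col)^2, "+")
  mean(sub[d2 <= radiusPx^2])
}

#' Fenestration-cluster analysis of a reconstruction
#'
#' The sieve-plate analysis chain: segment the plasma membrane on the
#' extinction map, remove its slowly varying component with a sliding-
#' paraboloid filter, detect fenestration-cluster candidates as prominence
#' maxima of the residual (restricted to the membrane), and report
#' per-cluster extinction statistics. Cluster extinction values are read
#' from the *un-background-subtracted* map at the detected peaks (mean over
#' a small disc), since the quantity of interest is the extinction
#' coefficient of the cluster itself; membrane statistics are per-pixel
#' values of the segmented membrane.
#'
#' @param recon a [ReconstructionResult-class] (or a bare extinction matrix).
#' @param prominence prominence threshold for [detectClusters()].
#' @param paraboloidRadiusPx radius for [slidingParaboloidBackground()].
#' @param labels optional precomputed label mask (0 background, 1 membrane,
#'   2 nucleus); segmented from the map when `NULL`.
#' @param onResidual detect on the background-subtracted residual (default)
#'   or on the raw membrane map.
#' @param valueDiscRadiusPx radius of the disc over which per-cluster k is
#'   averaged.
#' @param maskErodePx erosion of the membrane mask before detection;
#'   suppresses the band-limit ringing that concentrates along the
#'   membrane/background and membrane/nucleus boundaries.
#' @param minDistancePx non-maximum suppression distance, see
#'   [detectClusters()].
#' @param ... further arguments passed to [segmentMembrane()].
#' @return a [FenestrationReport-class].
#' @export
analyzeFenestrations <- function(recon, prominence = 0.00015,
                                 paraboloidRadiusPx = 10, labels = NULL,
                                 onResidual = TRUE, valueDiscRadiusPx = 1,
                                 maskErodePx = 3, minDistancePx = 0, ...) {
  k <- if (is(recon, "ReconstructionResult")) recon@kMap else recon
  stopifnot(is.matrix(k))
  if (is.null(labels)) labels <- segmentMembrane(k, ...)
  mem <- labels == 1L
  if (!any(mem)) stop("no membrane region found")
  ## fill non-membrane pixels with the membrane median so the paraboloid
  ## filter sees no artificial cliffs at the region boundary
  km <- k
  km[!mem] <- stats::median(k[mem])
  detMap <- if (onResidual) {
    slidingParaboloidBackground(km, paraboloidRadiusPx)$residual
  } else km
  detMask <- mem
  if (maskErodePx > 0)
    detMask <- EBImage::imageData(EBImage::erode(
      EBImage::Image(mem * 1),
      EBImage::makeBrush(2L * maskErodePx + 1L, "disc"))) > 0.5
  if (!any(detMask)) detMask <- mem
  det <- detectClusters(detMap, prominence, mask = detMask,
                        minDistancePx = minDistancePx)
  clusterK <- if (nrow(det) > 0)
    vapply(seq_len(nrow(det)),
           function(i) discMean(k, det$row[i], det$col[i], valueDiscRadiusPx),
           numeric(1))
  else numeric(0)
  membraneK <- k[mem]
  new("FenestrationReport",
      nClusters = nrow(det),
      clusterK = clusterK, membraneK = membraneK,
      clusterMean = if (length(clusterK)) mean(clusterK) else NA_real_,
      clusterStd = if (length(clusterK) > 1) stats::sd(clusterK) else NA_real_,
      membraneMean = mean(membraneK), membraneStd = stats::sd(membraneK),
      clusters = data.frame(row = det$row, col = det$col, k = clusterK),
      detectionParams = list(paraboloidRadiusPx = paraboloidRadiusPx,
                             prominence = prominence, onResidual = onResidual))
}
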