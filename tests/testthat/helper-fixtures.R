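# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and memoized in this environment.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

cfgSmall <- function() fixture("cfgSmall", function()
  acquisitionConfig(imageShape = c(128L, 128L), pixelSizeNm = 100))

pupilSmall <- function() fixture("pupilSmall", function()
  makeAnnularPupil(cfgSmall()))

lsecSmall <- function() fixture("lsecSmall", function()
  makeLsecPhantom(shape = c(128L, 128L), nClusters = 6, seed = 3))

stackSmall <- function() fixture("stackSmall", function()
  acquireStack(lsecSmall(), cfgSmall(), seed = 5))

## smallest angular distance between two angles (degrees), modulo `period`
angularError <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

## frequency-domain band limit of a real image to |u| <= radius (cycles/nm);
## independent re-implementation used to compare truth maps in-band
bandLimit <- function(m, pixelSizeNm, radiusCycles) {
  nr <- nrow(m); nc <- ncol(m)
  fy <- c(seq(0, floor(nr / 2)), seq(-(ceiling(nr / 2) - 1), -1)) / (nr * pixelSizeNm)
  fx <- c(seq(0, floor(nc / 2)), seq(-(ceiling(nc / 2) - 1), -1)) / (nc * pixelSizeNm)
  mask <- outer(fy^2, fx^2, "+") <= radiusCycles^2
  Re(stats::fft(stats::fft(m) * mask, inverse = TRUE)) / (nr * nc)
}

relRMS <- function(est, truth) {
  sqrt(mean((est - truth)^2)) / sqrt(mean(truth^2))
}

## 8-connected component labels by breadth-first search (small fixtures)
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

## Brute-force topographic prominence oracle for small fixtures: for each
## strict local maximum, lower a threshold level until the connected
## component of {f >= level} containing the peak also contains a strictly
## higher pixel; prominence = peak - that level. Independent of the
## union-find flood implementation (uses per-level connected components).
bruteForceProminence <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  peaks <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nb <- f[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
    if (f[r, c] == max(nb) && sum(nb == max(nb)) == 1) {
      peaks[[length(peaks) + 1]] <- c(r, c)
    }
  }
  levels <- sort(unique(as.vector(f)), decreasing = TRUE)
  out <- data.frame(row = integer(0), col = integer(0), prominence = numeric(0))
  for (p in peaks) {
    v <- f[p[1], p[2]]
    prom <- v - min(f)
    for (lev in levels[levels < v]) {
      lab <- label8(f >= lev)
      compOfPeak <- lab[p[1], p[2]]
      if (max(f[lab == compOfPeak]) > v) {
        prom <- v - lev
        break
      }
    }
    out <- rbind(out, data.frame(row = p[1], col = p[2], prominence = prom))
  }
  out
}

## two overlapping Gaussian bumps with a controlled valley level
twoBumpFixture <- function(n = 48, h = 3e-4, sigma = 3, dist = 11.35) {
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  g <- function(r0, c0) h * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
  b1 <- g(n / 2 - dist / 2, n / 2)
  b2 <- g(n / 2 + dist / 2, n / 2)
  b1 + b2
}
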