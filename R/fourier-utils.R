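## Internal Fourier helpers shared by the optics, forward and reconstruction code.
## Frequency-domain matrices are stored in *centered* layout (DC at
## (floor(nr/2)+1, floor(nc/2)+1)); images and raw fft() output use the
## standard (DC at [1,1]) layout. fftShift2()/ifftShift2() convert between
## the two and are exact inverses of each other for any matrix size.

gridCenter <- function(n) floor(n / 2L) + 1L

fftShift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  sr <- floor(nr / 2L); sc <- floor(nc / 2L)
  x[c(seq_len(nr - sr) + sr, seq_len(sr)), c(seq_len(nc - sc) + sc, seq_len(sc)), drop = FALSE]
}

ifftShift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  sr <- ceiling(nr / 2L); sc <- ceiling(nc / 2L)
  x[c(seq_len(nr - sr) + sr, seq_len(sr)), c(seq_len(nc - sc) + sc, seq_len(sc)), drop = FALSE]
}

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Centered spatial-frequency grid in cycles/nm. x runs along columns (east),
## y along -rows (up), so angles are counter-clockwise from +x with the
## origin at the top-left of the image.
frequencyGridNm <- function(shape, pixelSizeNm) {
  nr <- shape[1]; nc <- shape[2]
  dfy <- 1 / (nr * pixelSizeNm)
  dfx <- 1 / (nc * pixelSizeNm)
  r0 <- gridCenter(nr); c0 <- gridCenter(nc)
  ux <- matrix(rep((seq_len(nc) - c0) * dfx, each = nr), nr, nc)
  uy <- matrix(rep(-(seq_len(nr) - r0) * dfy, times = nc), nr, nc)
  list(ux = ux, uy = uy, ur = sqrt(ux^2 + uy^2), dfx = dfx, dfy = dfy)
}

## Cross-correlation on the centered frequency grid:
##   out(u) = sum_{u'} a(u') * b(u' + u)
## computed with 2x zero padding so no lag wraps around. a and b share one
## grid; the result is returned on that same centered grid.
crossCorrelate2 <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  pr <- 2L * nr; pc <- 2L * nc
  ap <- matrix(0 + 0i, pr, pc); bp <- ap
  ap[seq_len(nr), seq_len(nc)] <- a
  bp[seq_len(nr), seq_len(nc)] <- b
  xc <- stats::fft(Conj(stats::fft(ap)) * stats::fft(bp), inverse = TRUE) / (pr * pc)
  r0 <- gridCenter(nr); c0 <- gridCenter(nc)
  lagr <- ((seq_len(nr) - r0) %% pr) + 1L
  lagc <- ((seq_len(nc) - c0) %% pc) + 1L
  xc[lagr, lagc, drop = FALSE]
}

## Circular shift of a standard-layout spectrum by (dr, dc) grid indices,
## i.e. X(u - u_s) where u_s has integer grid offset (dr, dc).
circShift2 <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  x[((seq_len(nr) - 1L - dr) %% nr) + 1L, ((seq_len(nc) - 1L - dc) %% nc) + 1L, drop = FALSE]
}

## Cosine-tapered low-pass mask: 1 up to radius*(1 - taperFrac), half-cosine
## roll-off to 0 at the radius. taperFrac = 0 gives the hard cutoff.
cosineTaperMask <- function(shape, pixelSizeNm, radiusCycles, taperFrac) {
  g <- frequencyGridNm(shape, pixelSizeNm)
  if (taperFrac <= 0) return((g$ur <= radiusCycles) * 1)
  r0 <- radiusCycles * (1 - taperFrac)
  w <- pmin(pmax((g$ur - r0) / (radiusCycles - r0), 0), 1)
  0.5 * (1 + cos(pi * w))
}

## Smooth-edged radial mask on the centered grid: 1 inside radiusCycles,
## rolled off with a Gaussian edge of sigma edgePx pixels.
smoothRadialMask <- function(shape, pixelSizeNm, radiusCycles, edgePx = 10) {
  g <- frequencyGridNm(shape, pixelSizeNm)
  edge <- edgePx * min(g$dfx, g$dfy)
  if (edge <= 0) return((g$ur <= radiusCycles) * 1)
  exp(-pmax(g$ur - radiusCycles, 0)^2 / (2 * edge^2))
}
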