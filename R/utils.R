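## Internal geometry / image helpers shared across modules.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## round n up to the next odd integer
.oddify <- function(n) {
  n <- as.integer(ceiling(n))
  if (n %% 2L == 0L) n + 1L else n
}

## mirror (reflect) padding of a matrix by (ry, rx) pixels on each side
.reflectPad <- function(m, ry, rx) {
  nr <- nrow(m); nc <- ncol(m)
  if (ry >= nr || rx >= nc)
    .stopf("padding (%d, %d) too large for a %d x %d image", ry, rx, nr, nc)
  ri <- c(rev(seq_len(ry) + 1L), seq_len(nr), nr - seq_len(ry))
  ci <- c(rev(seq_len(rx) + 1L), seq_len(nc), nc - seq_len(rx))
  m[ri, ci, drop = FALSE]
}

## vectorized bilinear interpolation; x = column, y = row (1-based pixel
## centers); returns NA outside the image
.bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 1 & x <= nc & y >= 1 & y <= nr
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  out[ok] <- m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
  out
}

## cumulative arc length along an (x, y) polyline
.arcLength <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

## resample an (x, y) polyline at given arc-length positions
.polylineAt <- function(x, y, at) {
  s <- .arcLength(x, y)
  L <- s[length(s)]
  at <- pmin(pmax(at, 0), L)
  if (length(x) == 1L)
    return(data.frame(x = rep(x, length(at)), y = rep(y, length(at))))
  xi <- stats::approx(s, x, xout = at, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = at, ties = "ordered")$y
  data.frame(x = xi, y = yi)
}

## densify a polyline so consecutive points are <= spacing apart
.polylineDensify <- function(x, y, spacing = 0.5) {
  s <- .arcLength(x, y)
  L <- s[length(s)]
  if (L <= 0) return(data.frame(x = x[1], y = y[1]))
  .polylineAt(x, y, seq(0, L, by = spacing))
}

## binary disc of radius r (pixels with centre distance <= r), odd-sized
.discMatrix <- function(r) {
  r <- max(0L, as.integer(round(r)))
  d <- 2L * r + 1L
  off <- seq_len(d) - r - 1L
  m <- outer(off^2, off^2, "+") <= r^2 + 1e-9
  storage.mode(m) <- "double"
  m
}

## smallest absolute difference between two orientations modulo pi
.angDiffPi <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

## smallest absolute difference between two directions modulo 2*pi
.angDiff2Pi <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

## block-average binning by integer factor, cropping the remainder
.blockBin <- function(m, b) {
  b <- as.integer(b)
  if (b <= 1L) return(m)
  nr <- (nrow(m) %/% b) * b
  nc <- (ncol(m) %/% b) * b
  if (nr < b || nc < b) .stopf("image %d x %d too small to bin by %d",
                               nrow(m), ncol(m), b)
  x <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  dim(x) <- c(b, nr %/% b, b, nc %/% b)
  colMeans(aperm(x, c(1L, 3L, 2L, 4L)), dims = 2L)
}

## FFT frequency grid (cycles per pixel) of length n
.fftFreq <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / n
}
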