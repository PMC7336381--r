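## Independent oracles and fixture builders used across the test files.
## Everything here is deliberately simple (direct loops / shift-and-mask
## morphology / brute-force distance checks) so the oracles share no code
## path with the implementation they check.

## direct spatial-domain correlation with reflect padding
directResponse <- function(img, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(kr) + 1L), seq_len(nr), nr - seq_len(kr))
  ci <- c(rev(seq_len(kc) + 1L), seq_len(nc), nc - seq_len(kc))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    out[r, c] <- sum(pad[r:(r + 2L * kr), c:(c + 2L * kc)] * k)
  }
  out
}

## rotate a square matrix by 90 degrees counterclockwise
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

## bright ridge of Gaussian cross profile at arbitrary orientation,
## centered; returns image and a function giving true centerline points
ridgeImage <- function(n, theta, sigma, amp = 1) {
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  d <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  amp * exp(-d^2 / (2 * sigma^2))
}

## brute-force binary erosion/dilation/opening by shift-and-combine;
## elem is a 0/1 matrix with odd sides
bruteShift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

bruteErode <- function(m, elem) {
  hr <- (nrow(elem) - 1L) %/% 2L
  hc <- (ncol(elem) - 1L) %/% 2L
  out <- matrix(1, nrow(m), ncol(m))
  for (i in seq_len(nrow(elem))) for (j in seq_len(ncol(elem))) {
    if (elem[i, j] == 0) next
    out <- out * bruteShift(m, hr - (i - 1L), hc - (j - 1L))
  }
  out
}

bruteDilate <- function(m, elem) {
  hr <- (nrow(elem) - 1L) %/% 2L
  hc <- (ncol(elem) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(elem))) for (j in seq_len(ncol(elem))) {
    if (elem[i, j] == 0) next
    out <- pmax(out, bruteShift(m, (i - 1L) - hr, (j - 1L) - hc))
  }
  out
}

bruteOpen <- function(m, elem) bruteDilate(bruteErode(m, elem), elem)

## brute-force rasterization: pixels within radius of any densely
## sampled centerline point
bruteRasterize <- function(fl, fw, shape) {
  rad <- round(fw / 3)
  canvas <- matrix(0, shape[1], shape[2])
  pts <- do.call(rbind, lapply(fl, function(f) {
    if (nrow(f) < 2) return(cbind(f$x, f$y))
    s <- cumsum(c(0, sqrt(diff(f$x)^2 + diff(f$y)^2)))
    at <- seq(0, s[length(s)], by = 0.5)
    cbind(approx(s, f$x, at)$y, approx(s, f$y, at)$y)
  }))
  if (is.null(pts) || !nrow(pts)) return(canvas)
  ## mirror the implementation's pixel-stamp + disc definition: the
  ## contract is "centerline pixels dilated by a radius-r disc"
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    pr <- pmin(pmax(round(pts[, 2]), 1), shape[1])
    pc <- pmin(pmax(round(pts[, 1]), 1), shape[2])
    if (any((pr - r)^2 + (pc - c)^2 <= rad^2 + 1e-9)) canvas[r, c] <- 1
  }
  canvas
}

## brute-force re-implementation of the evaluation metric (same
## definitions, independent morphology and counting)
brutePrecisionRecall <- function(truthList, predList, fw, shape) {
  Bu <- bruteRasterize(truthList, fw, shape)
  Bp <- bruteRasterize(predList, fw, shape)
  eps <- do.call(rbind, lapply(c(truthList, predList), function(f)
    rbind(c(f$x[1], f$y[1]), c(f$x[nrow(f)], f$y[nrow(f)]))))
  keep <- matrix(0, shape[1], shape[2])
  m <- round(fw)
  if (shape[1] > 2 * m && shape[2] > 2 * m)
    keep[(m + 1):(shape[1] - m), (m + 1):(shape[2] - m)] <- 1
  if (!is.null(eps)) {
    for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
      if (keep[r, c] == 0) next
      if (any((eps[, 1] - c)^2 + (eps[, 2] - r)^2 <= fw^2)) keep[r, c] <- 0
    }
  }
  D <- Bu - Bp
  rad <- round(fw / 3)
  off <- seq(-rad, rad)
  elem <- (outer(off^2, off^2, "+") <= rad^2 + 1e-9) * 1
  fn <- sum(bruteOpen((D > 0) * 1, elem) * keep)
  fp <- sum(bruteOpen((D < 0) * 1, elem) * keep)
  tp <- sum(Bu * keep) - fn
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

## render two straight noise-free dark filaments on a blank background
## (depths in sd units), optionally crossing; returns image + centerlines
twoFilamentImage <- function(n = 256, len1 = 200, len2 = 40, fw = 8,
                             depth = 4) {
  sigma <- fw / (2 * sqrt(2 * log(2)))
  img <- matrix(0, n, n)
  mk <- function(x0, y0, x1, y1) {
    s <- seq(0, 1, length.out = 2 * n)
    data.frame(x = x0 + s * (x1 - x0), y = y0 + s * (y1 - y0))
  }
  f1 <- mk((n - len1) / 2, n * 0.3, (n + len1) / 2, n * 0.3)
  f2 <- mk((n - len2) / 2, n * 0.7, (n + len2) / 2, n * 0.7)
  for (f in list(f1, f2)) {
    for (i in seq_len(nrow(f))) {
      rr <- max(1, round(f$y[i] - 4 * sigma)):min(n, round(f$y[i] + 4 * sigma))
      cc <- max(1, round(f$x[i] - 1)):min(n, round(f$x[i] + 1))
      for (r in rr) for (c in cc) {
        d2 <- (r - f$y[i])^2 + (c - f$x[i])^2
        img[r, c] <- min(img[r, c], -depth * exp(-d2 / (2 * sigma^2)))
      }
    }
  }
  list(img = img, f1 = f1, f2 = f2)
}
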