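makeRidge <- function(n = 64, y0 = 32.3, sigma = 2) {
  img <- matrix(0, n, n)
  for (r in seq_len(n)) img[r, ] <- exp(-(r - y0)^2 / (2 * sigma^2))
  img
}

test_that("Gaussian derivative stack behaves like calculus says", {
  const <- matrix(3.2, 48, 48)
  d <- gaussianDerivatives(const, 2)
  for (p in c("rx", "ry", "rxx", "rxy", "ryy"))
    expect_lt(max(abs(d[[p]])), 1e-8)
  ramp <- matrix(seq_len(48), 48, 48, byrow = TRUE)   # I(x) = column
  d <- gaussianDerivatives(ramp, 2)
  inner <- 15:34
  expect_equal(mean(d$rx[inner, inner]), 1, tolerance = 5e-3)
  expect_lt(max(abs(d$rxx[inner, inner])), 1e-6)
  ## Gaussian ridge: smoothed curvature at the centerline matches the
  ## closed form of the convolved profile's second derivative
  s <- 3; sig <- 2
  img <- makeRidge(64, 32, s)
  d <- gaussianDerivatives(img, sig)
  seff2 <- s^2 + sig^2
  want <- -s / sqrt(seff2) / seff2       # d2/dy2 of convolved profile at 0
  expect_equal(d$ryy[32, 32], want, tolerance = 0.05)
  expect_error(gaussianDerivatives(img, -1), "positive")
})

test_that("line points sit on the ridge with subpixel accuracy", {
  flat <- matrix(1, 48, 48)
  lp <- linePoints(gaussianDerivatives(flat, 2))
  expect_equal(sum(lp$s), 0)
  expect_false(any(lp$valid))
  img <- makeRidge(64, 32.3, 2)
  lp <- linePoints(gaussianDerivatives(img, 2))
  expect_true(all(lp$s >= 0 & lp$s <= 1))
  rows <- which(apply(lp$valid, 1, any))
  expect_true(all(abs(rows - 32.3) <= 1))
  on <- which(lp$valid, arr.ind = TRUE)
  ## subpixel offsets stay within the pixel
  expect_true(all(abs(lp$py[on] - on[, 1]) <= 0.5 + 1e-9))
  expect_true(all(abs(lp$px[on] - on[, 2]) <= 0.5 + 1e-9))
  inner <- on[, 2] > 8 & on[, 2] < 56
  expect_lt(max(abs(lp$py[on][inner] - 32.3)), 0.1)
})

test_that("linking recovers one line from one ridge and splits crossings", {
  img <- makeRidge(64, 32.3, 2)
  ls <- linkLines(linePoints(gaussianDerivatives(img, 2)), 0.9, 0.3)
  big <- Filter(function(l) nrow(l) >= 5, ls$lines)
  expect_length(big, 1L)
  expect_equal(sum(ls$junctionMap), 0)
  ## plus-shaped crossing
  n <- 101
  img2 <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) {
    img2[r, c] <- exp(-(r - 51)^2 / 8) + exp(-(c - 51)^2 / 8)
  }
  ls2 <- linkLines(linePoints(gaussianDerivatives(img2, 2)), 0.3, 0.1)
  j <- which(ls2$junctionMap, arr.ind = TRUE)
  expect_gte(nrow(j), 1L)
  expect_lte(min(sqrt((j[, 1] - 51)^2 + (j[, 2] - 51)^2)), 2)
  segs <- sum(sapply(ls2$lines, nrow) >= 5)
  expect_true(segs >= 3 && segs <= 4)
  expect_error(linkLines(linePoints(gaussianDerivatives(img, 2)), 0.2, 0.5),
               "lower")
})

test_that("every surviving point lands in exactly one line", {
  set.seed(4)
  img <- makeRidge(64, 30.7, 2) + 0.3 * matrix(runif(64^2), 64)
  lp <- linePoints(gaussianDerivatives(img, 2))
  for (th in list(c(0.5, 0.1), c(0.9, 0.6))) {
    ls <- linkLines(lp, th[1], th[2])
    pix <- unlist(lapply(ls$lines, function(l) (l$col - 1L) * 64L + l$row))
    expect_false(any(duplicated(pix)))
  }
})

test_that("linked point counts are monotone in the thresholds", {
  set.seed(5)
  img <- makeRidge(64, 31.4, 2) + 0.2 * matrix(runif(64^2), 64)
  lp <- linePoints(gaussianDerivatives(img, 2))
  nAt <- function(u, l) sum(sapply(linkLines(lp, u, l)$lines, nrow))
  expect_lte(nAt(1, 1), nAt(0, 0))
  ## raising lower never increases the linked point count
  counts <- sapply(c(0, 0.2, 0.4, 0.6), function(l) nAt(0.8, l))
  expect_true(all(diff(counts) <= 0))
})

test_that("width estimation recovers the profile FWHM", {
  sig <- sigmaFromFWHM(8)                # true width 8 px
  img <- makeRidge(64, 32.3, sig)
  d <- gaussianDerivatives(img, sig)
  ls <- linkLines(linePoints(d), 0.9, 0.3)
  ln <- estimateWidth(ls$lines[[1]], d)
  expect_lt(abs(mean(ln$width, na.rm = TRUE) - 8) / 8, 0.2)
  ## symmetric ridge: left and right half-widths agree
  expect_lt(mean(abs(ln$edgeLeft - ln$edgeRight), na.rm = TRUE), 0.5)
})

test_that("width search flags missing edges near the border", {
  sig <- sigmaFromFWHM(8)
  img <- makeRidge(64, 5, sig)           # ridge hugging the top border
  d <- gaussianDerivatives(img, sig)
  ls <- linkLines(linePoints(d), 0.9, 0.3)
  expect_gte(length(ls$lines), 1L)
  ln <- estimateWidth(ls$lines[[1]], d)  # must not error
  expect_true(any(is.na(ln$width)))
})

test_that("position refinement is bounded, inert on symmetric ridges, and helps on asymmetric ones", {
  y0 <- 32.3
  sym <- makeRidge(64, y0, 3.4)
  d <- gaussianDerivatives(sym, 3.4)
  ln <- estimateWidth(linkLines(linePoints(d), 0.9, 0.3)$lines[[1]], d)
  ref <- refinePositions(ln)
  expect_lt(mean(abs(ref$shift)), 0.05)
  expect_true(all(abs(ref$shift) <= 1))
  ## asymmetric flanks: half-Gaussians of different spread
  img <- matrix(0, 64, 64)
  for (r in 1:64) {
    dr <- r - y0
    img[r, ] <- ifelse(dr < 0, exp(-dr^2 / (2 * 2^2)),
                       exp(-dr^2 / (2 * 4^2)))
  }
  d2 <- gaussianDerivatives(img, 2)
  ln2 <- estimateWidth(linkLines(linePoints(d2), 0.9, 0.3)$lines[[1]], d2)
  ref2 <- refinePositions(ln2)
  rmsBefore <- sqrt(mean((ln2$y - y0)^2))
  rmsAfter <- sqrt(mean((ref2$y - y0)^2))
  expect_lt(rmsAfter, rmsBefore)
  expect_true(all(abs(ref2$shift) <= 1))
})

test_that("a noise-free straight ridge is recovered almost completely", {
  sig <- 2
  for (th in c(0, 0.35, pi / 3)) {
    img <- ridgeImage(97, th, sig)
    ls <- detectRidges(img, sig, 0.9, 0.3, widths = FALSE, refine = FALSE)
    pts <- do.call(rbind, ls$lines)
    ## perpendicular distance of detected points to the true centerline
    cx <- (97 + 1) / 2
    dperp <- abs(-(pts$x - cx) * sin(th) + (pts$y - cx) * cos(th))
    expect_lt(mean(dperp), 0.5)
    ## coverage: centerline pixels away from a 2*sigma border margin
    m <- ceiling(2 * sig) + 1
    tpos <- seq(-cx + m + 2, cx - m - 2, by = 1)
    hit <- sapply(tpos, function(t) {
      px <- cx + t * cos(th); py <- cx + t * sin(th)
      any((pts$x - px)^2 + (pts$y - py)^2 <= 1.5^2)
    })
    expect_gte(mean(hit), 0.95)
  }
})
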