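test_that("FWHM-to-sigma conversion matches the Gaussian identity", {
  expect_equal(sigmaFromFWHM(2 * sqrt(2 * log(2))), 1)
  expect_equal(sigmaFromFWHM(100), 100 / (2 * sqrt(2 * log(2))),
               tolerance = 1e-12)
  expect_equal(round(sigmaFromFWHM(100), 3), 42.466)
  expect_error(sigmaFromFWHM(0), "positive")
  expect_error(sigmaFromFWHM(-3), "positive")
})

test_that("oriented kernels are zero-sum, point-symmetric and pi-periodic", {
  for (th in c(0, 0.3, pi / 4, 1.2, 2.9)) {
    k <- orientedKernel(8, 40, th)
    v <- k@values
    expect_lt(abs(sum(v)), 1e-10)
    ## point symmetry about the center
    expect_equal(v, v[nrow(v):1, ncol(v):1], tolerance = 1e-12)
    ## pi-periodic: theta and theta + pi give the same kernel
    k2 <- orientedKernel(8, 40, th + pi)
    expect_equal(v, k2@values, tolerance = 1e-12)
  }
  expect_error(orientedKernel(8, 40, 0, support = 32), "odd")
})

test_that("theta = 0 and theta = pi/2 kernels agree after array rotation", {
  k0 <- orientedKernel(6, 30, 0)@values
  k90 <- orientedKernel(6, 30, pi / 2)@values
  expect_equal(rot90(k0), k90, tolerance = 1e-10)
})

test_that("across-ridge profile has a negative core and positive flanks", {
  k <- orientedKernel(8, 100, 0)
  v <- k@values
  mid <- (ncol(v) + 1L) %/% 2L
  prof <- v[, mid]                       # across-ridge cut (theta = 0)
  center <- (length(prof) + 1L) %/% 2L
  expect_lt(prof[center], 0)
  ## exactly two sign changes along the cross-ridge axis near the core
  sgn <- sign(prof[abs(seq_along(prof) - center) <= 3 * k@sigmaX])
  changes <- sum(diff(sgn) != 0)
  expect_equal(changes, 2L)
})

test_that("oriented response is zero on constants and offset-invariant", {
  k <- orientedKernel(6, 20, 0.7)
  const <- matrix(5, 64, 64)
  expect_lt(max(abs(orientedResponse(const, k))), 1e-8)
  img <- ridgeImage(64, 0.7, 3)
  r1 <- orientedResponse(img, k)
  r2 <- orientedResponse(img + 17.3, k)
  expect_equal(r1, r2, tolerance = 1e-8)
  big <- orientedKernel(6, 200, 0)
  expect_error(orientedResponse(matrix(0, 32, 32), big), "larger")
})

test_that("frequency-domain response matches a direct spatial oracle", {
  set.seed(11)
  img <- matrix(rnorm(64 * 64), 64, 64)
  for (th in c(0, 1.1)) {
    k <- orientedKernel(5, 12, th)
    got <- orientedResponse(img, k)
    want <- directResponse(img, k@values)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("a ridge responds stronger under its own orientation", {
  th <- 0.5
  img <- -ridgeImage(64, th, 3)          # dark ridge
  kOn <- orientedKernel(7, 30, th, support = 63)
  kOff <- orientedKernel(7, 30, th + pi / 2, support = 63)
  on <- orientedResponse(img, kOn)
  off <- orientedResponse(img, kOff)
  ## compare on centerline pixels away from the border
  cx <- (64 + 1) / 2
  for (t in seq(-15, 15, by = 3)) {
    r <- round(cx + t * sin(th)); c <- round(cx + t * cos(th))
    expect_gt(on[r, c], off[r, c])
  }
})

test_that("single-kernel bank reproduces its response; V is constant", {
  bank <- filterBank(6, 20, nAngles = 1L)
  img <- -ridgeImage(64, 0, 3)
  maps <- enhanceOrient(img, bank)
  expect_equal(enhancedImage(maps),
               orientedResponse(img, bank@kernels[[1]]),
               tolerance = 1e-10)
  expect_true(all(directionMap(maps) == bank@angles[1]))
})

test_that("V on a straight filament equals the nearest bank angle", {
  bank <- filterBank(6, 30, nAngles = 36L)
  th <- 0.42                              # between bank angles
  img <- -ridgeImage(96, th, sigmaFromFWHM(6))
  maps <- enhanceOrient(img, bank)
  nearest <- bank@angles[which.min(abs(bank@angles - th))]
  cx <- (96 + 1) / 2
  for (t in seq(-20, 20, by = 5)) {
    r <- round(cx + t * sin(th)); c <- round(cx + t * cos(th))
    expect_equal(directionMap(maps)[r, c], nearest)
  }
})

test_that("enhancement commutes with 90-degree image rotation", {
  set.seed(3)
  img <- -ridgeImage(64, 0.3, 2.5) + 0.05 * matrix(rnorm(64^2), 64)
  bank <- filterBank(5, 16, nAngles = 12L)
  U1 <- enhancedImage(enhanceOrient(img, bank))
  U2 <- enhancedImage(enhanceOrient(rot90(img), bank))
  ## rotating the input rotates U (up to boundary effects)
  inner <- 10:54
  expect_equal(rot90(U1)[inner, inner], U2[inner, inner],
               tolerance = 0.02)
})

test_that("V's circular error stays within half the bank's angular step", {
  bank <- filterBank(6, 30, nAngles = 36L)
  step <- pi / 36
  set.seed(21)
  for (i in 1:5) {
    th <- runif(1, 0, pi)
    img <- -ridgeImage(96, th, sigmaFromFWHM(6))
    V <- directionMap(enhanceOrient(img, bank))
    cx <- (96 + 1) / 2
    errs <- sapply(seq(-20, 20, by = 4), function(t) {
      r <- round(cx + t * sin(th)); c <- round(cx + t * cos(th))
      d <- abs(V[r, c] - th) %% pi
      min(d, pi - d)
    })
    expect_lte(max(errs), step / 2 + 1e-9)
  }
})
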