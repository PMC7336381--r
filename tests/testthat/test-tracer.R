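test_that("boxes on one straight line trace into a single ordered filament", {
  b <- data.frame(x = seq(50, 245, by = 15), y = rep(100, 14), size = 20)
  V <- matrix(0, 300, 300)               # horizontal everywhere
  tr <- traceFilaments(b, V, traceConfig(seed = 5))
  expect_length(tr, 1L)
  expect_setequal(tr[[1]], seq_len(14))
  expect_true(all(diff(tr[[1]]) == 1) || all(diff(tr[[1]]) == -1))
  expect_identical(traceFilaments(data.frame(x = numeric(0),
                                             y = numeric(0)),
                                  V, traceConfig()), list())
})

test_that("perpendicular lines stay separate and are never merged", {
  V <- matrix(0, 300, 300)
  V[150:300, ] <- pi / 2
  b <- rbind(data.frame(x = seq(50, 245, by = 15), y = rep(100, 14),
                        size = 20),
             data.frame(x = rep(150, 10), y = seq(150, 285, by = 15),
                        size = 20))
  tr <- traceFilaments(b, V, traceConfig(seed = 2, mergeAngleTol = 30))
  big <- tr[lengths(tr) >= 3]
  expect_length(big, 2L)
  grp <- lapply(big, function(v) sort(v))
  expect_true(list(1:14) %in% grp || Position(function(g)
    identical(g, 1:14), grp) > 0)
  ## an L-shaped pair meeting at 90 degrees must not merge either
  bl <- rbind(data.frame(x = seq(60, 150, by = 15), y = rep(80, 7),
                         size = 20),
              data.frame(x = rep(150, 6), y = seq(95, 170, by = 15),
                         size = 20))
  Vl <- matrix(0, 300, 300); Vl[81:300, ] <- pi / 2
  trl <- traceFilaments(bl, Vl, traceConfig(seed = 3, mergeAngleTol = 30))
  sets <- lapply(trl, sort)
  expect_false(any(vapply(sets, function(s)
    any(s %in% 1:7) && any(s %in% 8:13), logical(1))))
})

test_that("tracing partitions the boxes and is seed-independent here", {
  set.seed(40)
  V <- matrix(0, 300, 300)
  V[150:300, ] <- pi / 2
  b <- rbind(data.frame(x = seq(50, 245, by = 15), y = rep(100, 14),
                        size = 20),
             data.frame(x = rep(150, 10), y = seq(150, 285, by = 15),
                        size = 20))
  canon <- function(p) sort(vapply(p, function(v)
    paste(sort(v), collapse = ","), character(1)))
  p1 <- traceFilaments(b, V, traceConfig(seed = 11))
  p2 <- traceFilaments(b, V, traceConfig(seed = 97))
  expect_false(any(duplicated(unlist(p1))))
  expect_setequal(unlist(p1), seq_len(nrow(b)))
  expect_identical(canon(p1), canon(p2))
})

test_that("resampling emits evenly spaced boxes along the fitted polyline", {
  b <- data.frame(x = seq(50, 150, by = 10), y = rep(60, 11), size = 20)
  tr <- list(seq_len(11))
  rs <- boxes(resampleBoxes(tr, b, traceConfig(boxDistance = 20)))
  expect_equal(nrow(rs), 6L)             # floor(100/20)+1
  expect_equal(rs$x, seq(50, 150, by = 20))
  ## single-box filaments fall below the minimum and are dropped...
  rs1 <- resampleBoxes(list(1L), b, traceConfig(boxDistance = 20))
  expect_equal(nrow(boxes(rs1)), 0L)
  ## ...unless the minimum is lowered
  rs2 <- resampleBoxes(list(1L), b,
                       traceConfig(boxDistance = 20, minBoxes = 1L))
  expect_equal(nrow(boxes(rs2)), 1L)
  ## zig-zag support points: spacing follows the polyline's arc length
  zz <- data.frame(x = seq(0, 200, by = 10) + 30,
                   y = 100 + rep(c(0, 8), length.out = 21), size = 20)
  rsz <- boxes(resampleBoxes(list(seq_len(21)), zz,
                             traceConfig(boxDistance = 20)))
  s <- filatrace:::.arcLength(zz$x, zz$y)
  pos <- sapply(seq_len(nrow(rsz)), function(i) {
    d2 <- (zz$x - rsz$x[i])^2 + (zz$y - rsz$y[i])^2
    s[which.min(d2)]
  })
  expect_true(all(abs(diff(pos) - 20) <= 1 + 8))  # vertex snap slack
  expect_equal(nrow(rsz), floor(s[length(s)] / 20) + 1)
})

test_that("tracing covers true candidates and isolates spurious ones", {
  sc <- generateScene(sceneSpec(seed = 42, snr = 1))
  cfg <- pickConfig(fw = 6, mw = 20, binFactor = 4)
  prep <- preprocessMicrograph(sc$micrograph, cfg)
  bank <- filterBank(6, 20, 36L)
  V <- directionMap(enhanceOrient(imageData(prep), bank))
  cand <- do.call(rbind, lapply(filaments(sc$truth), function(f) {
    s <- filatrace:::.arcLength(f$x, f$y)
    filatrace:::.polylineAt(f$x, f$y, seq(0, s[length(s)], by = 15))
  }))
  nTrue <- nrow(cand)
  set.seed(9)
  spur <- data.frame(x = runif(round(nTrue * 0.1), 50, 974),
                     y = runif(round(nTrue * 0.1), 50, 974))
  all <- rbind(cand, spur)
  all$size <- 30
  tr <- traceFilaments(all, V, traceConfig(seed = 3), scale = 4)
  expect_false(any(duplicated(unlist(tr))))
  big <- tr[lengths(tr) >= 3]
  coverage <- sum(seq_len(nTrue) %in% unlist(big)) / nTrue
  expect_gte(coverage, 0.9)
  ## filaments made purely of spurious boxes stay below 3 members
  pureSpur <- tr[vapply(tr, function(v) all(v > nTrue), logical(1))]
  expect_true(all(lengths(pureSpur) < 3))
})
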