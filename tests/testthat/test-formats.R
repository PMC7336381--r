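test_that("MRC mode-2 images round-trip with pixel size", {
  m <- matrix(rnorm(48 * 64), 48, 64)
  f <- withr::local_tempfile(fileext = ".mrc")
  writeMRC(Micrograph(m, 1.32), f)
  r <- readMRC(f)
  expect_equal(imageData(r), m, tolerance = 1e-6)
  expect_equal(pixelSize(r), 1.32, tolerance = 1e-6)
})

test_that("TIFF and MRC of the same data read back identically", {
  m <- matrix(runif(32 * 32), 32, 32)    # [0,1] so float TIFF is exact
  fm <- withr::local_tempfile(fileext = ".mrc")
  ft <- withr::local_tempfile(fileext = ".tif")
  writeMRC(m, fm)
  tiff::writeTIFF(m, ft, bits.per.sample = 32L)
  a <- readMicrographFile(fm)
  b <- readMicrographFile(ft)
  expect_equal(imageData(a), imageData(b), tolerance = 1e-6)
})

test_that("corrupt or unsupported micrograph files raise errors", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeMRC(matrix(rnorm(64 * 64), 64, 64), f)
  g <- withr::local_tempfile(fileext = ".mrc")
  writeBin(readBin(f, "raw", 3000), g)
  expect_error(readMRC(g), "runcated")
  h <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(1:100), h)
  expect_error(readMRC(h), "corrupt|short")
  ## 3-D stack: patch nz in the header
  raw <- readBin(f, "raw", file.size(f))
  raw[9:12] <- writeBin(2L, raw(), size = 4L, endian = "little")
  writeBin(raw, g)
  expect_error(readMRC(g), "stack")
})

test_that("EMAN helical files preserve grouping and coordinates", {
  bs <- BoxSet(data.frame(
    x = c(10.25, 30.25, 50.25, 80.5, 80.5, 80.5),
    y = c(20, 20, 20, 35.75, 55.75, 75.75),
    size = 24, filament = rep(1:2, each = 3), ord = rep(1:3, 2)))
  f <- withr::local_tempfile(fileext = ".box")
  writeBoxes(bs, f, "eman_helical")
  txt <- readLines(f)
  expect_length(txt, 6L)
  flags <- as.integer(vapply(strsplit(txt, "\t"), `[[`, "", 5L))
  expect_equal(flags, c(-1L, 0L, -2L, -1L, 0L, -2L))
  r <- readBoxes(f, "eman_helical")
  expect_equal(boxes(r)$x, boxes(bs)$x, tolerance = 1e-4)
  expect_equal(boxes(r)$y, boxes(bs)$y, tolerance = 1e-4)
  expect_equal(boxes(r)$filament, boxes(bs)$filament)
  expect_equal(boxes(r)$ord, boxes(bs)$ord)
})

test_that("single-box filaments survive the EMAN dialect", {
  bs <- BoxSet(data.frame(x = c(10, 40), y = c(10, 40), size = 16,
                          filament = 1:2, ord = 1L))
  f <- withr::local_tempfile(fileext = ".box")
  writeBoxes(bs, f, "eman_helical")
  r <- readBoxes(f, "eman_helical")
  expect_equal(boxes(r)$filament, 1:2)
  expect_equal(boxes(r)$x, c(10, 40), tolerance = 1e-4)
})

test_that("STAR files round-trip and regroup shuffled rows", {
  bs <- BoxSet(data.frame(
    x = c(10.5, 30.5, 50.5, 15, 35, 55), y = c(20, 21, 22, 80, 81, 82),
    size = 24, filament = rep(1:2, each = 3), ord = rep(1:3, 2)))
  f <- withr::local_tempfile(fileext = ".star")
  writeBoxes(bs, f, "star")
  r <- readBoxes(f, "star")
  expect_equal(boxes(r)$x, boxes(bs)$x, tolerance = 1e-4)
  expect_equal(boxes(r)$filament, boxes(bs)$filament)
  ## shuffle the data rows: grouping comes back via the id column
  ln <- readLines(f)
  hdr <- ln[1:7]; dat <- ln[-(1:7)]
  set.seed(1)
  writeLines(c(hdr, sample(dat)), f)
  r2 <- readBoxes(f, "star")
  expect_equal(boxes(r2)$filament, boxes(bs)$filament)
  expect_equal(sort(boxes(r2)$x), sort(boxes(bs)$x), tolerance = 1e-4)
})

test_that("cross-dialect conversion preserves box centers exactly", {
  bs <- BoxSet(data.frame(x = c(12.25, 44.75), y = c(30.5, 60.25),
                          size = 20, filament = c(1L, 1L), ord = 1:2))
  fe <- withr::local_tempfile(fileext = ".box")
  fs <- withr::local_tempfile(fileext = ".star")
  writeBoxes(bs, fe, "eman_helical")
  writeBoxes(readBoxes(fe, "eman_helical"), fs, "star")
  r <- readBoxes(fs, "star")
  expect_equal(boxes(r)$x, boxes(bs)$x, tolerance = 1e-4)
  expect_equal(boxes(r)$y, boxes(bs)$y, tolerance = 1e-4)
})

test_that("malformed box files raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".box")
  writeLines(c("1 2 24 24 -1", "oops"), f)
  expect_error(readBoxes(f, "eman_helical"), "line 2")
  expect_error(readBoxes(f, "nonsense"), "arg")
  g <- withr::local_tempfile(fileext = ".star")
  writeLines(c("data_", "loop_", "_rlnCoordinateX #1",
               "_rlnCoordinateY #2", "1.0 x"), g)
  expect_error(readBoxes(g, "star"), "line 5|malformed")
})
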