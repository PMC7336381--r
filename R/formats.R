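#' @include AllClasses.R utils.R
NULL

## ---------------------------------------------------------------------
## MRC2014 (mode 2, 32-bit float, single section)
##
## Minimal reader/writer for the subset of MRC this package needs:
## 2-D float micrographs and masks. Data are stored x-fastest
## (columns), little-endian; pixel size is cella/mx when the header
## provides a cell.
## ---------------------------------------------------------------------

#' Read a 2-D MRC image
#'
#' Supports MRC2014 mode 2 (32-bit float) and modes 0/1/6 (integer)
#' single-section files. Stacks (\code{nz > 1}) are rejected.
#'
#' @param path file path.
#' @return A \linkS4class{Micrograph}; pixel size is filled from the
#'   header cell when present.
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  sz <- file.size(path)
  if (sz < 1024) .stopf("corrupt MRC header (file %s too short)", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (any(!is.finite(c(nx, ny, nz))) || nx <= 0 || ny <= 0 || nz <= 0 ||
      nx > 1e6 || ny > 1e6)
    .stopf("corrupt MRC header in %s", path)
  if (nz != 1L)
    .stopf("%s is a %d-section stack; only single 2-D images are supported",
           path, nz)
  mxyz <- hdr[8:10]                     # words 8-10: mx my mz
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 92L)                        # word 24: nsymbt
  nsymbt <- readBin(con, "integer", 1L, 4L, endian = "little")
  bytesPer <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L,
                     "6" = 2L, NULL)
  if (is.null(bytesPer)) .stopf("unsupported MRC mode %d in %s", mode, path)
  need <- 1024 + nsymbt + as.numeric(nx) * ny * bytesPer
  if (sz < need)
    .stopf("truncated MRC file %s (%d bytes, need %d)", path, sz, need)
  seek(con, 1024 + nsymbt)
  npix <- nx * ny
  v <- switch(as.character(mode),
    "0" = readBin(con, "integer", npix, 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", npix, 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", npix, 4L, endian = "little"),
    "6" = readBin(con, "integer", npix, 2L, signed = FALSE,
                  endian = "little"))
  if (length(v) < npix) .stopf("truncated MRC data in %s", path)
  ## x fastest in the file -> fill a nx x ny matrix then transpose so
  ## rows = y, cols = x
  m <- t(matrix(as.numeric(v), nrow = nx, ncol = ny))
  ps <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else NA_real_
  Micrograph(m, ps)
}

#' Write a 2-D image as MRC2014 mode 2
#'
#' @param image \linkS4class{Micrograph} or numeric matrix.
#' @param path output file path.
#' @param pixelSize Angstrom per pixel stored in the header cell
#'   (default: the micrograph's own, else 1).
#' @return \code{path}, invisibly.
#' @export
writeMRC <- function(image, path, pixelSize = NULL) {
  m <- .asImageMatrix(image)
  if (is.null(pixelSize))
    pixelSize <- if (is(image, "Micrograph") && is.finite(image@pixelSize))
      image@pixelSize else 1
  nx <- ncol(m); ny <- nrow(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wInt(c(nx, ny, 1L, 2L))               # nx ny nz mode
  wInt(c(0L, 0L, 0L))                   # nxstart nystart nzstart
  wInt(c(nx, ny, 1L))                   # mx my mz
  wFlt(c(nx, ny, 1) * pixelSize)        # cella
  wFlt(c(90, 90, 90))                   # cellb
  wInt(c(1L, 2L, 3L))                   # mapc mapr maps
  wFlt(c(min(m), max(m), mean(m)))      # dmin dmax dmean
  wInt(c(1L, 0L))                       # ispg nsymbt
  wInt(rep(0L, 25L))                    # extra
  wInt(c(0L, 0L, 0L))                   # origin (words 50-52)
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(stats::sd(m))                    # rms
  wInt(0L)                              # nlabl
  writeBin(raw(800L), con)              # labels
  wFlt(as.numeric(t(m)))                # x fastest
  invisible(path)
}

#' Read a micrograph from MRC or TIFF
#'
#' Dispatches on the file extension: \code{.mrc}/\code{.mrcs} go through
#' \code{\link{readMRC}}, \code{.tif}/\code{.tiff} through the tiff
#' package (multi-directory TIFFs are rejected; greyscale only).
#'
#' @param path file path.
#' @return A \linkS4class{Micrograph}.
#' @export
readMicrographFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs", "map")) return(readMRC(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, all = TRUE)
    if (is.list(img)) {
      if (length(img) != 1L)
        .stopf("%s holds %d images; only single 2-D images are supported",
               path, length(img))
      img <- img[[1L]]
    }
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] != 1L)
        .stopf("%s is not a greyscale image", path)
      img <- img[, , 1L]
    }
    return(Micrograph(img))
  }
  .stopf("unsupported micrograph format: %s", path)
}

## ---------------------------------------------------------------------
## Box coordinate files
##
## Internal frame: x = column, y = row, 1-based pixel centers. The EMAN
## helical dialect stores 0-based lower-left box corners (center -
## size/2 - 1 off the internal frame) with segment-end flags in a fifth
## column: -1 opens a filament, -2 closes it, 0 marks interior boxes.
## The STAR dialect stores 0-based box centers, one row per box, with a
## configurable filament-id column.
## ---------------------------------------------------------------------

.boxesToGroups <- function(boxSet) {
  b <- if (is(boxSet, "BoxSet")) boxSet@boxes else as.data.frame(boxSet)
  split(b, b$filament)
}

#' Write boxes to an EMAN helical box or STAR coordinate file
#'
#' @param boxSet a \linkS4class{BoxSet} (internal 1-based center
#'   coordinates).
#' @param path output path.
#' @param dialect \code{"eman_helical"} or \code{"star"}.
#' @param idColumn STAR filament-id column name (default
#'   \code{"_rlnHelicalTubeID"}).
#' @return \code{path}, invisibly.
#' @export
writeBoxes <- function(boxSet, path,
                       dialect = c("eman_helical", "star"),
                       idColumn = "_rlnHelicalTubeID") {
  dialect <- match.arg(dialect)
  groups <- .boxesToGroups(boxSet)
  if (dialect == "eman_helical") {
    lines <- character(0)
    for (g in groups) {
      n <- nrow(g)
      flag <- rep(0L, n)
      flag[1L] <- -1L
      if (n > 1L) flag[n] <- -2L
      lines <- c(lines, sprintf("%.4f\t%.4f\t%d\t%d\t%d",
                                g$x - g$size / 2 - 1, g$y - g$size / 2 - 1,
                                as.integer(round(g$size)),
                                as.integer(round(g$size)), flag))
    }
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("", "data_", "", "loop_",
                 "_rlnCoordinateX #1", "_rlnCoordinateY #2",
                 paste0(idColumn, " #3")), con)
    b <- do.call(rbind, groups)
    writeLines(sprintf("%.4f\t%.4f\t%d", b$x - 1, b$y - 1,
                       as.integer(b$filament)), con)
  }
  invisible(path)
}

.parseNum <- function(txt, path, lineNo) {
  v <- suppressWarnings(as.numeric(txt))
  if (any(is.na(v)))
    .stopf("malformed row at line %d of %s", lineNo[which(is.na(v))[1L]],
           path)
  v
}

#' Read boxes from an EMAN helical box or STAR coordinate file
#'
#' EMAN helical files preserve filament grouping through the segment
#' flags; STAR rows may appear in any order and are regrouped by the
#' filament-id column (all rows form a single group when the file has
#' no id column).
#'
#' @param path input path.
#' @param dialect \code{"eman_helical"} or \code{"star"}.
#' @param idColumn STAR filament-id column (default
#'   \code{"_rlnHelicalTubeID"}).
#' @return A \linkS4class{BoxSet} in internal 1-based center
#'   coordinates.
#' @export
readBoxes <- function(path, dialect = c("eman_helical", "star"),
                      idColumn = "_rlnHelicalTubeID") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  raw <- readLines(path)
  if (dialect == "eman_helical") {
    keep <- which(nzchar(trimws(raw)))
    rows <- strsplit(trimws(raw[keep]), "[ \t]+")
    bad <- which(lengths(rows) < 4L)
    if (length(bad))
      .stopf("malformed row at line %d of %s", keep[bad[1L]], path)
    m <- matrix(NA_real_, length(rows), 5L)
    for (j in 1:4)
      m[, j] <- .parseNum(vapply(rows, `[[`, "", j), path, keep)
    m[, 5L] <- vapply(seq_along(rows), function(i)
      if (length(rows[[i]]) >= 5L)
        .parseNum(rows[[i]][[5L]], path, keep[i]) else 0, numeric(1))
    fid <- integer(nrow(m))
    cur <- 0L
    open <- FALSE
    for (i in seq_len(nrow(m))) {
      if (m[i, 5L] == -1 || !open) { cur <- cur + 1L; open <- TRUE }
      fid[i] <- cur
      if (m[i, 5L] == -2) open <- FALSE
    }
    size <- m[, 3L]
    b <- data.frame(x = m[, 1L] + size / 2 + 1, y = m[, 2L] + size / 2 + 1,
                    size = size, filament = fid,
                    ord = stats::ave(fid, fid, FUN = seq_along))
    return(BoxSet(b))
  }
  ## STAR: find the loop_ column declarations, then data rows
  txt <- trimws(raw)
  loopAt <- which(txt == "loop_")
  if (!length(loopAt)) .stopf("no loop_ block in %s", path)
  i <- loopAt[1L] + 1L
  cols <- character(0)
  while (i <= length(txt) && startsWith(txt[i], "_")) {
    cols <- c(cols, sub("\\s+#\\d+$", "", txt[i]))
    i <- i + 1L
  }
  xi <- which(cols == "_rlnCoordinateX")
  yi <- which(cols == "_rlnCoordinateY")
  if (!length(xi) || !length(yi))
    .stopf("%s lacks _rlnCoordinateX/_rlnCoordinateY columns", path)
  ii <- which(cols == idColumn)
  dataIdx <- i:length(txt)
  dataIdx <- dataIdx[nzchar(txt[dataIdx]) & !startsWith(txt[dataIdx], "data_")]
  if (!length(dataIdx)) {
    return(BoxSet(data.frame(x = numeric(0), y = numeric(0),
                             size = numeric(0), filament = integer(0),
                             ord = integer(0))))
  }
  rows <- strsplit(txt[dataIdx], "[ \t]+")
  bad <- which(lengths(rows) < length(cols))
  if (length(bad)) .stopf("malformed row at line %d of %s",
                          dataIdx[bad[1L]], path)
  x <- .parseNum(vapply(rows, `[[`, "", xi), path, dataIdx) + 1
  y <- .parseNum(vapply(rows, `[[`, "", yi), path, dataIdx) + 1
  fid <- if (length(ii))
    as.integer(.parseNum(vapply(rows, `[[`, "", ii), path, dataIdx))
  else rep(1L, length(x))
  o <- order(fid, seq_along(fid))       # regroup shuffled rows by id
  b <- data.frame(x = x[o], y = y[o], size = NA_real_, filament = fid[o],
                  ord = stats::ave(fid[o], fid[o], FUN = seq_along))
  BoxSet(b)
}
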