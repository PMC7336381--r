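#' @include AllClasses.R utils.R
NULL

#' Rasterize filament centerlines into a binary image
#'
#' Every pixel within a local radius of \code{fw / 3} (rounded to the
#' nearest integer) of any centerline point is set to 1. Centerlines are
#' densified to sub-pixel spacing before stamping, so the result is the
#' filled tube around the traced path.
#'
#' @param filaments a \linkS4class{FilamentSet} (or list of data frames
#'   with \code{x}, \code{y}).
#' @param fw filament width in pixels; the rasterization radius is
#'   \code{round(fw / 3)}.
#' @param shape image dimensions \code{c(nrow, ncol)}; defaults to the
#'   set's \code{imageDim}.
#' @return Binary (0/1) numeric matrix of the requested shape.
#' @export
rasterizeFilaments <- function(filaments, fw, shape = NULL) {
  fl <- if (is(filaments, "FilamentSet")) filaments@filaments else filaments
  if (is.null(shape)) {
    if (!is(filaments, "FilamentSet"))
      .stopf("shape required when filaments is a plain list")
    shape <- filaments@imageDim
  }
  shape <- as.integer(shape)
  canvas <- matrix(0, shape[1], shape[2])
  if (!length(fl)) return(canvas)
  for (f in fl) {
    if (!nrow(f)) next
    dd <- .polylineDensify(f$x, f$y, 0.5)
    r <- pmin(pmax(round(dd$y), 1L), shape[1])
    c <- pmin(pmax(round(dd$x), 1L), shape[2])
    canvas[cbind(r, c)] <- 1
  }
  rad <- as.integer(round(fw / 3))
  if (rad > 0L)
    canvas <- EBImage::dilate(canvas, .discMatrix(rad))
  canvas
}

## counting mask: 1 where pixels are scored, 0 within the border margin
## and within a disc of radius `margin` around each filament endpoint
.exclusionMask <- function(shape, endpoints, margin) {
  nr <- shape[1]; nc <- shape[2]
  keep <- matrix(1, nr, nc)
  m <- as.integer(round(margin))
  if (m > 0L) {
    keep[] <- 0
    if (nr > 2L * m && nc > 2L * m)
      keep[(m + 1L):(nr - m), (m + 1L):(nc - m)] <- 1
  }
  if (nrow(endpoints)) {
    r2 <- margin^2
    for (i in seq_len(nrow(endpoints))) {
      ex <- endpoints[i, 1L]; ey <- endpoints[i, 2L]
      rr <- max(1L, floor(ey - margin)):min(nr, ceiling(ey + margin))
      cc <- max(1L, floor(ex - margin)):min(nc, ceiling(ex + margin))
      if (!length(rr) || !length(cc)) next
      d2 <- outer((rr - ey)^2, (cc - ex)^2, "+")
      sub <- keep[rr, cc, drop = FALSE]
      sub[d2 <= r2] <- 0
      keep[rr, cc] <- sub
    }
  }
  keep
}

.endpointsOf <- function(fl) {
  eps <- lapply(fl, function(f) {
    if (!nrow(f)) return(NULL)
    rbind(c(f$x[1L], f$y[1L]), c(f$x[nrow(f)], f$y[nrow(f)]))
  })
  do.call(rbind, c(list(matrix(0, 0, 2)), eps))
}

#' Pixel-level precision and recall of predicted filaments
#'
#' Both filament sets are rasterized (\code{\link{rasterizeFilaments}});
#' the difference image \code{D = Bu - Bp} is split into its positive
#' part \code{D1} and negative part \code{Dm1}; false negatives are the
#' pixels of \code{D1} surviving a morphological opening with an
#' all-ones \code{fw x fw} structuring element, false positives the
#' pixels of \code{Dm1} after the same opening, and true positives are
#' \code{|Bu| - FN}. Opening removes mismatch blobs smaller than the
#' element, so sub-\code{fw} jitter between prediction and truth does
#' not count as error. Pixels within a border margin of \code{fw} and
#' within a radius \code{fw} of any filament start or end point are
#' excluded from all pixel counts, because those picks carry high
#' manual-selection uncertainty. A metric whose denominator
#' is zero is reported as undefined (\code{NA} plus flag), never as 0.
#'
#' @param truth \linkS4class{FilamentSet} of reference (user-selected)
#'   filaments.
#' @param pred \linkS4class{FilamentSet} of predicted filaments.
#' @param fw filament width in pixels.
#' @param shape image dimensions \code{c(nrow, ncol)}; defaults to the
#'   truth set's \code{imageDim}.
#' @return An \linkS4class{EvalReport}.
#' @export
precisionRecall <- function(truth, pred, fw, shape = NULL) {
  if (is.null(shape)) {
    if (!is(truth, "FilamentSet")) .stopf("shape required")
    shape <- truth@imageDim
  }
  shape <- as.integer(shape)
  Bu <- rasterizeFilaments(truth, fw, shape)
  tfl <- if (is(truth, "FilamentSet")) truth@filaments else truth
  .prCore(Bu, .endpointsOf(tfl), pred, fw, shape)
}

## core of precisionRecall with the truth raster and endpoints
## precomputed (the grid-search optimizer re-evaluates predictions
## against a fixed annotation many times)
.prCore <- function(Bu, truthEndpoints, pred, fw, shape) {
  Bp <- rasterizeFilaments(pred, fw, shape)
  pfl <- if (is(pred, "FilamentSet")) pred@filaments else pred
  eps <- rbind(truthEndpoints, .endpointsOf(pfl))
  keep <- .exclusionMask(shape, eps, fw)
  D <- Bu - Bp
  D1 <- (D > 0) * 1
  Dm1 <- (D < 0) * 1
  ## The opening element is a disc matched to the rasterized tube radius
  ## round(fw/3): opening then reproduces a fully missing tube exactly
  ## (the tube is the dilation of its centerline by this disc) while
  ## removing jitter slivers narrower than the tube, in any orientation.
  ## An fw x fw all-ones square would exceed the tube width and erase
  ## whole missing filaments from D1 (degenerating recall), and acts
  ## orientation-dependently on diagonal tubes.
  elem <- .discMatrix(round(fw / 3))
  ## the excluded border/endpoint zones are removed from the counts, not
  ## from the images: opening acts on the intact difference images
  fn <- sum(EBImage::opening(D1, elem) * keep)
  fp <- sum(EBImage::opening(Dm1, elem) * keep)
  tp <- sum(Bu * keep) - fn
  precDef <- (tp + fp) > 0
  recDef <- (tp + fn) > 0
  new("EvalReport",
      tp = tp, fp = fp, fn = fn,
      precision = if (precDef) tp / (tp + fp) else NA_real_,
      recall = if (recDef) tp / (tp + fn) else NA_real_,
      precisionDefined = precDef, recallDefined = recDef,
      fw = as.numeric(fw))
}
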