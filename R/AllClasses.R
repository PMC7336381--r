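#' @import methods
NULL

#' Micrograph: a 2-D float image with optional pixel size
#'
#' Container for a single transmission electron micrograph (or any 2-D
#' image the pipeline operates on). The matrix is indexed \code{[row, col]}
#' with \code{x = column} and \code{y = row}; coordinates throughout the
#' package are 1-based pixel centers in this frame.
#'
#' @slot data numeric matrix of pixel values.
#' @slot pixelSize physical pixel size in Angstrom per pixel, \code{NA}
#'   when unknown.
#' @export
setClass("Micrograph",
  representation(data = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = NA_real_),
  validity = function(object) {
    if (!is.numeric(object@data)) return("data must be a numeric matrix")
    if (length(object@pixelSize) != 1L) return("pixelSize must be length 1")
    TRUE
  })

#' Construct a Micrograph
#'
#' @param data numeric matrix (\code{[row, col]}).
#' @param pixelSize Angstrom per pixel, or \code{NA}.
#' @return A \linkS4class{Micrograph}.
#' @export
Micrograph <- function(data, pixelSize = NA_real_) {
  new("Micrograph", data = as.matrix(data), pixelSize = as.numeric(pixelSize))
}

## accept either a Micrograph or a bare matrix everywhere
.asImageMatrix <- function(x) {
  if (is(x, "Micrograph")) x@data else as.matrix(x)
}

#' Oriented second-derivative Gaussian kernel
#'
#' Discretized second derivative (taken across the ridge) of an
#' anisotropic Gaussian, rotated so that it responds maximally to a line
#' oriented at \code{theta}. The discrete sum is exactly zero.
#'
#' @slot values numeric matrix with odd side lengths.
#' @slot sigmaX across-ridge spread in pixels (sets the line width the
#'   kernel enhances).
#' @slot sigmaY along-ridge averaging spread in pixels.
#' @slot theta line orientation in radians, in \code{[0, pi)}.
#' @export
setClass("OrientedKernel",
  representation(values = "matrix", sigmaX = "numeric", sigmaY = "numeric",
                 theta = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (any(d %% 2L == 0L)) return("kernel side lengths must be odd")
    if (abs(sum(object@values)) > 1e-8) return("kernel must sum to zero")
    if (object@sigmaX <= 0 || object@sigmaY <= 0)
      return("sigmaX and sigmaY must be positive")
    if (object@theta < 0 || object@theta >= pi)
      return("theta must lie in [0, pi)")
    TRUE
  })

#' Bank of oriented kernels at equally spaced orientations
#'
#' @slot kernels list of \linkS4class{OrientedKernel}, one per angle.
#' @slot fw filament width (FWHM across the ridge) in pixels.
#' @slot mw mask width (FWHM of the along-ridge averaging) in pixels.
#' @slot angles strictly increasing orientations in radians, spanning
#'   less than pi.
#' @export
setClass("FilterBank",
  representation(kernels = "list", fw = "numeric", mw = "numeric",
                 angles = "numeric"),
  validity = function(object) {
    a <- object@angles
    if (length(a) < 1L) return("bank needs at least one angle")
    if (length(a) != length(object@kernels))
      return("angles and kernels lengths differ")
    if (length(a) > 1L && any(diff(a) <= 0))
      return("angles must be strictly increasing")
    if (max(a) - min(a) >= pi) return("angles must span less than pi")
    TRUE
  })

#' Enhanced image and directional map
#'
#' \code{U} holds, per pixel, the maximum oriented-filter response over
#' the bank; \code{V} holds the orientation (radians) attaining that
#' maximum (ties broken toward the smallest angle).
#'
#' @slot U numeric matrix of maximal responses.
#' @slot V numeric matrix of orientations in \code{[0, pi)}.
#' @export
setClass("EnhancedMaps",
  representation(U = "matrix", V = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@U), dim(object@V)))
      return("U and V must have identical dimensions")
    TRUE
  })

#' A set of filament centerlines
#'
#' Each filament is a data frame with numeric columns \code{x} and
#' \code{y} (ordered subpixel centerline points, 1-based pixel centers)
#' and optionally \code{width}. \code{imageDim} records the
#' \code{c(nrow, ncol)} of the image the coordinates refer to.
#'
#' @slot filaments list of data frames.
#' @slot imageDim integer vector of length 2.
#' @export
setClass("FilamentSet",
  representation(filaments = "list", imageDim = "integer"),
  validity = function(object) {
    if (length(object@imageDim) != 2L) return("imageDim must be length 2")
    for (f in object@filaments) {
      if (!all(c("x", "y") %in% names(f)))
        return("each filament needs x and y columns")
    }
    TRUE
  })

#' Construct a FilamentSet
#' @param filaments list of data frames with columns \code{x}, \code{y}.
#' @param imageDim \code{c(nrow, ncol)} of the reference image.
#' @return A \linkS4class{FilamentSet}.
#' @export
FilamentSet <- function(filaments = list(), imageDim = c(0L, 0L)) {
  new("FilamentSet", filaments = unname(filaments),
      imageDim = as.integer(imageDim))
}

#' Picked boxes along filaments
#'
#' @slot boxes data frame with columns \code{x}, \code{y} (box centers),
#'   \code{size} (box side length in pixels), \code{filament} (id) and
#'   \code{ord} (index along the filament).
#' @slot convention coordinate convention of \code{x}, \code{y};
#'   \code{"center1"} = 1-based pixel centers (the package-internal frame).
#' @export
setClass("BoxSet",
  representation(boxes = "data.frame", convention = "character"),
  validity = function(object) {
    need <- c("x", "y", "size", "filament", "ord")
    if (!all(need %in% names(object@boxes)))
      return(paste("boxes must have columns", paste(need, collapse = ", ")))
    TRUE
  })

#' Construct a BoxSet
#' @param boxes data frame with columns \code{x}, \code{y}, \code{size},
#'   \code{filament}, \code{ord}.
#' @param convention coordinate convention tag.
#' @return A \linkS4class{BoxSet}.
#' @export
BoxSet <- function(boxes, convention = "center1") {
  new("BoxSet", boxes = as.data.frame(boxes), convention = convention)
}

#' Pixel-level evaluation report
#'
#' False negatives, false positives and true positives are pixel counts
#' after rasterization, differencing and morphological opening; precision
#' and recall are \code{NA} (with the corresponding flag \code{FALSE})
#' when their denominator is zero.
#'
#' @slot tp,fp,fn pixel counts.
#' @slot precision,recall metric values in \code{[0, 1]} or \code{NA}.
#' @slot precisionDefined,recallDefined logical flags.
#' @slot fw filament width used for rasterization/opening.
#' @export
setClass("EvalReport",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 precision = "numeric", recall = "numeric",
                 precisionDefined = "logical", recallDefined = "logical",
                 fw = "numeric"))

#' Synthetic scene specification
#'
#' Parameters of the synthetic micrograph generator. \code{snr} is the
#' peak centerline depth of a rendered filament divided by the standard
#' deviation of the additive Gaussian noise.
#'
#' @slot imageDim image size \code{c(nrow, ncol)}.
#' @slot nFilaments number of filaments (including crossing/close-pair
#'   members).
#' @slot fw filament width (FWHM of the dark cross profile) in pixels.
#' @slot curvature maximum centerline curvature (1/pixels).
#' @slot nCrossings number of filaments constructed to cross an earlier one.
#' @slot gapRate expected discontinuities per 100 px of centerline.
#' @slot closePairGap centerline separation of a near-parallel close
#'   pair in pixels; \code{NA} disables the pair.
#' @slot carbonEdge logical; add a dark half-plane with a sharp edge.
#' @slot carbonFraction fraction of the image width covered by carbon.
#' @slot snr contrast-to-noise ratio (see above); \code{Inf} = noise-free.
#' @slot seed RNG seed.
#' @export
setClass("SceneSpec",
  representation(imageDim = "integer", nFilaments = "integer",
                 fw = "numeric", curvature = "numeric",
                 nCrossings = "integer", gapRate = "numeric",
                 closePairGap = "numeric", carbonEdge = "logical",
                 carbonFraction = "numeric", snr = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@snr <= 0) return("snr must be positive")
    if (object@fw < 3) return("fw must be at least 3 px")
    if (object@nFilaments < 1) return("need at least one filament")
    if (object@curvature < 0) return("curvature must be non-negative")
    TRUE
  })

#' Ground truth accompanying a synthetic scene
#'
#' @slot centerlines \linkS4class{FilamentSet} of true centerlines
#'   (complete, including any rendered gaps).
#' @slot mask binary matrix, 1 = valid picking region (0 over carbon).
#' @slot gaps list (one per filament) of 2-column matrices of arc-length
#'   gap intervals that were left unrendered.
#' @export
setClass("GroundTruth",
  representation(centerlines = "FilamentSet", mask = "matrix",
                 gaps = "list"))

#' Configuration of the end-to-end picking pipeline
#'
#' Lengths \code{fw} and \code{mw} are in pixels of the preprocessed
#' (binned) working image; \code{minLength}, \code{boxDistance} and
#' \code{boxSize} are in pixels of the original (unbinned) micrograph,
#' the frame all output coordinates use.
#'
#' @slot fw filament width (px, working image).
#' @slot mw mask width (px, working image); default 100.
#' @slot upper,lower hysteresis thresholds in \code{[0, 1]}.
#' @slot minLength minimum filament arc length (px, unbinned).
#' @slot boxDistance distance between consecutive boxes (px, unbinned).
#' @slot boxSize box side length (px, unbinned); \code{NA} = 1.5 fw
#'   scaled to unbinned pixels.
#' @slot binFactor integer binning factor; default 4.
#' @slot lowpassCutoff absolute cutoff frequency (cycles/px on the binned
#'   image); default 0.1.
#' @slot clipSigma saturation bound after z-normalization; default 3.
#' @slot nAngles number of bank orientations; default 36.
#' @export
setClass("PickConfig",
  representation(fw = "numeric", mw = "numeric", upper = "numeric",
                 lower = "numeric", minLength = "numeric",
                 boxDistance = "numeric", boxSize = "numeric",
                 binFactor = "integer", lowpassCutoff = "numeric",
                 clipSigma = "numeric", nAngles = "integer"),
  validity = function(object) {
    if (object@lower > object@upper) return("lower must be <= upper")
    if (object@binFactor < 1L) return("binFactor must be >= 1")
    if (object@lowpassCutoff <= 0 || object@lowpassCutoff > 0.5)
      return("lowpassCutoff must be in (0, 0.5]")
    if (object@fw <= 0 || object@mw <= 0) return("fw and mw must be positive")
    TRUE
  })

#' Construct a PickConfig
#'
#' @param fw filament width in pixels of the binned working image.
#' @param mw mask width (default 100 px).
#' @param upper,lower hysteresis thresholds.
#' @param minLength minimum filament length in unbinned pixels.
#' @param boxDistance box spacing in unbinned pixels (default 20).
#' @param boxSize box side in unbinned pixels (default 1.5 fw, unbinned).
#' @param binFactor binning factor (default 4).
#' @param lowpassCutoff low-pass cutoff in cycles/pixel (default 0.1).
#' @param clipSigma saturation bound (default 3).
#' @param nAngles bank orientations (default 36).
#' @return A \linkS4class{PickConfig}.
#' @export
pickConfig <- function(fw, mw = 100, upper = 0.5, lower = 0.1,
                          minLength = 0, boxDistance = 20, boxSize = NA,
                          binFactor = 4L, lowpassCutoff = 0.1,
                          clipSigma = 3, nAngles = 36L) {
  new("PickConfig", fw = fw, mw = mw, upper = upper, lower = lower,
      minLength = minLength, boxDistance = boxDistance,
      boxSize = as.numeric(boxSize), binFactor = as.integer(binFactor),
      lowpassCutoff = lowpassCutoff, clipSigma = clipSigma,
      nAngles = as.integer(nAngles))
}

#' Configuration of the directional-map tracer
#'
#' @slot alpha full opening angle of the search cone in degrees
#'   (default 120).
#' @slot radiusFactor search radius = \code{radiusFactor} x box size.
#' @slot mergeAngleTol maximal direction difference (degrees) for merging
#'   two traced segments; default 30.
#' @slot boxDistance output box spacing in pixels.
#' @slot minBoxes minimum number of member boxes a filament needs to be
#'   resampled; default 2.
#' @slot seed RNG seed for the random choice of start boxes.
#' @export
setClass("TraceConfig",
  representation(alpha = "numeric", radiusFactor = "numeric",
                 mergeAngleTol = "numeric", boxDistance = "numeric",
                 minBoxes = "integer", seed = "integer"),
  validity = function(object) {
    if (object@alpha <= 0 || object@alpha >= 360)
      return("alpha must be in (0, 360)")
    if (object@radiusFactor <= 0) return("radiusFactor must be positive")
    TRUE
  })

#' Construct a TraceConfig
#' @param alpha search-cone full angle in degrees (default 120).
#' @param radiusFactor search radius as a multiple of box size (default 1.5).
#' @param mergeAngleTol merge tolerance in degrees (default 30).
#' @param boxDistance output box spacing in pixels (default 20).
#' @param minBoxes minimum member boxes per filament (default 2).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{TraceConfig}.
#' @export
traceConfig <- function(alpha = 120, radiusFactor = 1.5, mergeAngleTol = 30,
                        boxDistance = 20, minBoxes = 2L, seed = 1L) {
  new("TraceConfig", alpha = alpha, radiusFactor = radiusFactor,
      mergeAngleTol = mergeAngleTol, boxDistance = boxDistance,
      minBoxes = as.integer(minBoxes), seed = as.integer(seed))
}
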