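#' @include AllClasses.R
NULL

#' Accessors
#'
#' Accessor generics for the package's S4 containers: image and pixel
#' size of a \linkS4class{Micrograph}, enhanced image and directional map
#' of \linkS4class{EnhancedMaps}, filament list of a
#' \linkS4class{FilamentSet}, box table of a \linkS4class{BoxSet}.
#'
#' @param x the object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "Micrograph", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("enhancedImage", function(x) standardGeneric("enhancedImage"))
#' @rdname accessors
#' @export
setMethod("enhancedImage", "EnhancedMaps", function(x) x@U)

#' @rdname accessors
#' @export
setGeneric("directionMap", function(x) standardGeneric("directionMap"))
#' @rdname accessors
#' @export
setMethod("directionMap", "EnhancedMaps", function(x) x@V)

#' @rdname accessors
#' @export
setGeneric("filaments", function(x) standardGeneric("filaments"))
#' @rdname accessors
#' @export
setMethod("filaments", "FilamentSet", function(x) x@filaments)
#' @rdname accessors
#' @export
setMethod("filaments", "GroundTruth", function(x) x@centerlines@filaments)

#' @rdname accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))
#' @rdname accessors
#' @export
setMethod("boxes", "BoxSet", function(x) x@boxes)

#' Number of filaments in a set
#' @param x a \linkS4class{FilamentSet}.
#' @return Integer count.
#' @export
setMethod("length", "FilamentSet", function(x) length(x@filaments))

#' Arc lengths of filaments
#'
#' @param x a \linkS4class{FilamentSet}.
#' @return Numeric vector of centerline arc lengths in pixels.
#' @export
filamentLengths <- function(x) {
  vapply(x@filaments, function(f) {
    s <- .arcLength(f$x, f$y); if (length(s)) s[length(s)] else 0
  }, numeric(1))
}

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@data)
  cat(sprintf("Micrograph %d x %d px, pixel size %s A/px\n", d[1], d[2],
              ifelse(is.na(object@pixelSize), "unknown",
                     format(object@pixelSize))))
})

setMethod("show", "OrientedKernel", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "OrientedKernel %d x %d, sigmaX=%.3f sigmaY=%.3f theta=%.1f deg\n",
    d[1], d[2], object@sigmaX, object@sigmaY, object@theta * 180 / pi))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank: %d angles over [0, pi), fw=%.1f mw=%.1f px\n",
              length(object@angles), object@fw, object@mw))
})

setMethod("show", "EnhancedMaps", function(object) {
  d <- dim(object@U)
  cat(sprintf("EnhancedMaps %d x %d (U: max response, V: orientation)\n",
              d[1], d[2]))
})

setMethod("show", "FilamentSet", function(object) {
  cat(sprintf("FilamentSet: %d filament(s) on a %d x %d image\n",
              length(object@filaments), object@imageDim[1],
              object@imageDim[2]))
  if (length(object@filaments)) {
    L <- filamentLengths(object)
    cat(sprintf("  arc lengths: %s px\n",
                paste(format(round(L, 1)), collapse = ", ")))
  }
})

setMethod("show", "BoxSet", function(object) {
  cat(sprintf("BoxSet: %d box(es) in %d filament(s) [%s]\n",
              nrow(object@boxes), length(unique(object@boxes$filament)),
              object@convention))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (fw = %g px)\n", object@fw))
  cat(sprintf("  TP = %g, FP = %g, FN = %g\n", object@tp, object@fp,
              object@fn))
  cat(sprintf("  precision = %s, recall = %s\n",
              ifelse(object@precisionDefined,
                     sprintf("%.4f", object@precision), "undefined"),
              ifelse(object@recallDefined,
                     sprintf("%.4f", object@recall), "undefined")))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec %d x %d: %d filaments (fw=%g px), %d crossings, snr=%g\n",
    object@imageDim[1], object@imageDim[2], object@nFilaments, object@fw,
    object@nCrossings, object@snr))
})
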