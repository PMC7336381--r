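#' @include AllClasses.R utils.R
NULL

#' Convert a full width at half maximum to a Gaussian sigma
#'
#' Filament width \code{fw} and mask width \code{mw} are specified as the
#' full width at half maximum of the corresponding Gaussian profile; the
#' kernel spreads are obtained as \code{sigma = width / (2 sqrt(2 ln 2))}.
#'
#' @param width positive width in pixels (FWHM).
#' @return The equivalent Gaussian sigma in pixels.
#' @examples
#' sigmaFromFWHM(2 * sqrt(2 * log(2)))  # 1
#' @export
sigmaFromFWHM <- function(width) {
  if (!is.numeric(width) || any(!is.finite(width)) || any(width <= 0))
    .stopf("width must be a positive finite number")
  width / (2 * sqrt(2 * log(2)))
}

#' Build an oriented second-derivative Gaussian kernel
#'
#' Samples the second derivative, taken across the ridge, of an
#' anisotropic Gaussian with across-ridge spread
#' \code{sigmaFromFWHM(fw)} and along-ridge averaging spread
#' \code{sigmaFromFWHM(mw)}, rotated so that a dark line oriented at
#' \code{theta} (after image negation the kernel sees a bright line)
#' yields the maximal response. The kernel is mean-subtracted so its
#' discrete sum is exactly zero, making all responses invariant to
#' additive image offsets.
#'
#' @param fw filament width in pixels (FWHM across the ridge).
#' @param mw mask width in pixels (FWHM of the along-ridge averaging);
#'   large values average over long straight stretches.
#' @param theta line orientation in radians; mapped into \code{[0, pi)}.
#' @param support odd kernel side length in pixels; defaults to a
#'   3-sigma truncation of the larger spread.
#' @return An \linkS4class{OrientedKernel}.
#' @export
orientedKernel <- function(fw, mw = 100, theta = 0, support = NULL) {
  sx <- sigmaFromFWHM(fw)
  sy <- sigmaFromFWHM(mw)
  if (is.null(support)) support <- .oddify(2 * ceiling(3 * max(sx, sy)) + 1)
  support <- as.integer(support)
  if (support %% 2L == 0L) .stopf("kernel support must be odd, got %d", support)
  theta <- theta %% pi
  h <- (support - 1L) %/% 2L
  off <- seq.int(-h, h)
  ## x = column offset, y = row offset; along-ridge unit = (cos, sin),
  ## across-ridge unit = (-sin, cos)
  u <- matrix(off, support, support, byrow = TRUE)   # x offset
  v <- matrix(off, support, support)                 # y offset
  a <- -u * sin(theta) + v * cos(theta)              # across-ridge coord
  l <- u * cos(theta) + v * sin(theta)               # along-ridge coord
  g2 <- (a^2 / sx^4 - 1 / sx^2) * exp(-a^2 / (2 * sx^2))
  g  <- exp(-l^2 / (2 * sy^2))
  m <- g2 * g / (2 * pi * sx * sy)
  m <- m - mean(m)                                   # exact zero sum
  new("OrientedKernel", values = m, sigmaX = sx, sigmaY = sy, theta = theta)
}

#' Build a bank of oriented kernels
#'
#' @param fw filament width in pixels (FWHM).
#' @param mw mask width in pixels (default 100).
#' @param nAngles number of equally spaced orientations over
#'   \code{[0, pi)} (default 36, a 5 degree step).
#' @param support odd kernel side length shared by all bank members;
#'   defaults to the 3-sigma truncation. Pass a smaller value to clamp
#'   the kernel to the working image (it must stay no larger than any
#'   image it is applied to).
#' @return A \linkS4class{FilterBank}.
#' @export
filterBank <- function(fw, mw = 100, nAngles = 36L, support = NULL) {
  nAngles <- as.integer(nAngles)
  if (nAngles < 1L) .stopf("nAngles must be at least 1")
  angles <- (seq_len(nAngles) - 1L) * pi / nAngles
  kernels <- lapply(angles, function(th)
    orientedKernel(fw, mw, th, support = support))
  new("FilterBank", kernels = kernels, fw = fw, mw = mw, angles = angles)
}

## reflect-pad then FFT-filter with EBImage, cropping back to shape
.filterReflect <- function(img, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  pad <- .reflectPad(img, kr, kc)
  res <- EBImage::filter2(pad, k, boundary = "circular")
  res[kr + seq_len(nrow(img)), kc + seq_len(ncol(img)), drop = FALSE]
}

#' Oriented filter response of an image
#'
#' Correlates the image with an oriented kernel in the frequency domain
#' (the kernels are point-symmetric, so correlation and convolution
#' coincide). The image is reflect-padded by the kernel half-size before
#' the FFT, so the result has the same shape as the input.
#'
#' @param image \linkS4class{Micrograph} or numeric matrix; must be
#'   finite-valued.
#' @param kernel an \linkS4class{OrientedKernel}.
#' @return Numeric matrix of responses, same shape as the image.
#' @export
orientedResponse <- function(image, kernel) {
  img <- .asImageMatrix(image)
  if (any(!is.finite(img))) .stopf("image must be finite-valued")
  k <- kernel@values
  if (nrow(k) > nrow(img) || ncol(k) > ncol(img))
    .stopf("kernel (%d x %d) larger than image (%d x %d)",
           nrow(k), ncol(k), nrow(img), ncol(img))
  .filterReflect(img, k)
}

#' Enhance line structures and extract the dominating orientation
#'
#' Applies every kernel of the bank and keeps, per pixel, the maximal
#' response (\code{U}, enhancing lines of arbitrary orientation) and the
#' orientation attaining it (\code{V}, the directional map). Ties are
#' broken toward the smallest bank angle. Cryo-EM protein is dark on a
#' lighter background; with \code{polarity = "bright"} the image is
#' negated first so bright ridges are enhanced instead.
#'
#' @param image \linkS4class{Micrograph} or numeric matrix.
#' @param bank a \linkS4class{FilterBank}.
#' @param polarity \code{"dark"} (default) if filaments are darker than
#'   background, \code{"bright"} otherwise.
#' @return An \linkS4class{EnhancedMaps} object.
#' @export
enhanceOrient <- function(image, bank, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  img <- .asImageMatrix(image)
  if (any(!is.finite(img))) .stopf("image must be finite-valued")
  if (identical(polarity, "bright")) img <- -img
  if (length(bank@kernels) == 0L) .stopf("filter bank is empty")
  k1 <- bank@kernels[[1L]]@values
  if (nrow(k1) > nrow(img) || ncol(k1) > ncol(img))
    .stopf("bank kernels (%d x %d) larger than image (%d x %d)",
           nrow(k1), ncol(k1), nrow(img), ncol(img))
  kr <- (nrow(k1) - 1L) %/% 2L
  kc <- (ncol(k1) - 1L) %/% 2L
  pad <- .reflectPad(img, kr, kc)
  ri <- kr + seq_len(nrow(img))
  ci <- kc + seq_len(ncol(img))
  U <- NULL
  V <- NULL
  for (i in seq_along(bank@kernels)) {
    r <- EBImage::filter2(pad, bank@kernels[[i]]@values,
                          boundary = "circular")[ri, ci, drop = FALSE]
    if (is.null(U)) {
      U <- r
      V <- matrix(bank@angles[i], nrow(img), ncol(img))
    } else {
      upd <- r > U                       # strict: ties keep smaller angle
      U[upd] <- r[upd]
      V[upd] <- bank@angles[i]
    }
  }
  new("EnhancedMaps", U = U, V = V)
}
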