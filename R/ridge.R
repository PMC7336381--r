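#' @include AllClasses.R utils.R linefilter.R
NULL

## separable correlation with reflect boundary; kx along columns (x),
## ky along rows (y)
.sepFilter <- function(img, ky, kx) {
  r <- .filterReflect(img, matrix(ky, length(ky), 1L))
  .filterReflect(r, matrix(kx, 1L, length(kx)))
}

#' Gaussian derivative stack of an image
#'
#' Filters the image with the derivatives of a Gaussian smoothing kernel
#' at scale \code{sigma}, yielding the smoothed first and second partial
#' derivatives needed for differential-geometric line detection.
#' \code{x} is the column direction, \code{y} the row direction.
#'
#' @param image \linkS4class{Micrograph} or numeric matrix.
#' @param sigma positive smoothing scale in pixels.
#' @return A list of class \code{"DerivativeStack"} with matrices
#'   \code{rx}, \code{ry}, \code{rxx}, \code{rxy}, \code{ryy}, the
#'   smoothed image \code{r}, and \code{sigma}.
#' @export
gaussianDerivatives <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    .stopf("sigma must be a positive number")
  img <- .asImageMatrix(image)
  h <- max(2L, as.integer(ceiling(3.5 * sigma)))
  h <- min(h, nrow(img) - 1L, ncol(img) - 1L,
           (nrow(img) - 1L) %/% 2L, (ncol(img) - 1L) %/% 2L)
  t <- seq.int(-h, h)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -(t / sigma^2) * g
  g2 <- (t^2 / sigma^4 - 1 / sigma^2) * g
  g2 <- g2 - mean(g2)                 # exact zero response on constants
  structure(list(
    r   = .sepFilter(img, g, g),
    rx  = .sepFilter(img, g, g1),
    ry  = .sepFilter(img, g1, g),
    rxx = .sepFilter(img, g, g2),
    rxy = .sepFilter(img, g1, g1),
    ryy = .sepFilter(img, g2, g),
    sigma = sigma), class = "DerivativeStack")
}

#' Extract subpixel line points
#'
#' Per pixel, the eigenvector of the Hessian belonging to the most
#' negative eigenvalue gives the direction normal to a (bright) line;
#' the pixel is a line point when the subpixel extremum of the intensity
#' profile along that normal falls inside the pixel. The strength
#' \code{s} is the magnitude of that eigenvalue normalized per image to
#' \code{[0, 1]}; non-line pixels carry \code{s = 0}.
#'
#' @param derivs a \code{"DerivativeStack"} from
#'   \code{\link{gaussianDerivatives}}.
#' @return A list of class \code{"LinePointField"} with matrices
#'   \code{s}, \code{nx}, \code{ny} (unit normal), \code{px}, \code{py}
#'   (subpixel positions), and logical \code{valid}.
#' @export
linePoints <- function(derivs) {
  if (!inherits(derivs, "DerivativeStack"))
    .stopf("derivs must come from gaussianDerivatives()")
  rxx <- derivs$rxx; rxy <- derivs$rxy; ryy <- derivs$ryy
  rx <- derivs$rx; ry <- derivs$ry
  nr <- nrow(rxx); nc <- ncol(rxx)
  m <- (rxx + ryy) / 2
  q <- sqrt(((rxx - ryy) / 2)^2 + rxy^2)
  lam <- m - q                                    # most negative eigenvalue
  ## eigenvector of lam: (rxy, lam - rxx) or (lam - ryy, rxy); pick the
  ## numerically larger representation per pixel
  v1x <- rxy;        v1y <- lam - rxx
  v2x <- lam - ryy;  v2y <- rxy
  n1 <- v1x^2 + v1y^2
  n2 <- v2x^2 + v2y^2
  use1 <- n1 >= n2
  nx <- ifelse(use1, v1x, v2x)
  ny <- ifelse(use1, v1y, v2y)
  nrm <- sqrt(nx^2 + ny^2)
  deg <- nrm < 1e-12                              # isotropic/flat pixels
  nrm[deg] <- 1
  nx <- nx / nrm; ny <- ny / nrm
  nx[deg] <- 1; ny[deg] <- 0
  denom <- lam
  denom[abs(denom) < 1e-12] <- NA
  tt <- -(rx * nx + ry * ny) / denom
  xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  yg <- matrix(seq_len(nr), nr, nc)
  valid <- !is.na(tt) & lam < 0 &
    abs(tt * nx) <= 0.5 + 1e-9 & abs(tt * ny) <= 0.5 + 1e-9
  valid[is.na(valid)] <- FALSE
  s <- matrix(0, nr, nc)
  if (any(valid)) {
    sv <- -lam[valid]
    smax <- max(sv)
    if (smax > 0) s[valid] <- sv / smax
  }
  px <- xg; py <- yg
  px[valid] <- xg[valid] + tt[valid] * nx[valid]
  py[valid] <- yg[valid] + tt[valid] * ny[valid]
  structure(list(s = s, nx = nx, ny = ny, px = px, py = py, valid = valid),
            class = "LinePointField")
}

## 8-neighborhood offsets
.nbrOff <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Link line points into lines with junction splitting
#'
#' A generalization of hysteresis thresholding: points with
#' \code{s < lower} are dropped; new lines are seeded at the unvisited
#' point of highest strength (seeds require \code{s >= upper}) and
#' extended in both directions through the 8-neighbor of highest
#' strength whose normal direction is compatible (differs by less than
#' 45 degrees modulo pi). When an extension selects a point belonging to
#' another line, that point is marked as a junction and the touched line
#' is split in two at that point. Every surviving point ends up in at
#' most one line.
#'
#' @param lp a \code{"LinePointField"} from \code{\link{linePoints}}.
#' @param upper,lower hysteresis thresholds, \code{0 <= lower <= upper
#'   <= 1}.
#' @return A list of class \code{"LineSet"}: \code{lines} (list of data
#'   frames with columns \code{x}, \code{y}, \code{s}, \code{row},
#'   \code{col}, \code{junction}), and \code{junctionMap} (logical
#'   matrix of junction pixels).
#' @export
linkLines <- function(lp, upper, lower) {
  if (!inherits(lp, "LinePointField"))
    .stopf("lp must come from linePoints()")
  if (!is.numeric(upper) || !is.numeric(lower) || lower > upper ||
      lower < 0 || upper > 1)
    .stopf("need 0 <= lower <= upper <= 1")
  nr <- nrow(lp$s); nc <- ncol(lp$s)
  ## candidates carry at least 1% of the maximal saliency; anything below
  ## is numerical noise and only inflates the linking workload
  cand <- lp$valid & lp$s >= max(lower, 0.01)
  phi <- atan2(lp$ny, lp$nx) %% pi
  sMat <- lp$s
  idxCand <- which(cand)
  ord <- idxCand[order(sMat[idxCand], decreasing = TRUE)]
  visited <- matrix(0L, nr, nc)
  junction <- matrix(FALSE, nr, nc)
  lines <- list()

  neighborBest <- function(cur, prev, id) {
    r <- ((cur - 1L) %% nr) + 1L
    c <- ((cur - 1L) %/% nr) + 1L
    rr <- r + .nbrOff[, 1L]
    cc <- c + .nbrOff[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!is.na(prev)) {
      ## forbid backtracking: keep steps within 90 degrees of the current
      ## growth direction
      pr <- ((prev - 1L) %% nr) + 1L
      pc <- ((prev - 1L) %/% nr) + 1L
      dr <- r - pr; dc <- c - pc
      ok <- ok & (.nbrOff[, 1L] * dr + .nbrOff[, 2L] * dc >= 0L)
    }
    if (!any(ok)) return(NA_integer_)
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    nb <- nb[cand[nb] & visited[nb] != id]
    if (!length(nb)) return(NA_integer_)
    compat <- nb[.angDiffPi(phi[nb], phi[cur]) < pi / 4]
    if (length(compat)) return(compat[which.max(sMat[compat])])
    ## no compatible continuation; if a neighbor belongs to another line
    ## we still terminate on it as a junction (normals are unreliable at
    ## crossings)
    tch <- nb[visited[nb] > 0L]
    if (length(tch)) return(tch[which.max(sMat[tch])])
    NA_integer_
  }

  for (seed in ord) {
    if (sMat[seed] < upper) break            # ord is sorted descending
    if (visited[seed] != 0L) next
    id <- length(lines) + 1L
    cur <- seed
    pts <- seed
    visited[seed] <- id
    for (pass in 1:2) {
      repeat {
        np <- length(pts)
        best <- neighborBest(pts[np], if (np > 1L) pts[np - 1L] else
                             NA_integer_, id)
        if (is.na(best)) break
        if (visited[best] == 0L) {
          pts <- c(pts, best)
          visited[best] <- id
        } else {
          ## collision with another line: junction, split the touched
          ## line (singleton spurs alongside a line are not junctions)
          if (length(pts) >= 2L) {
            other <- visited[best]
            junction[best] <- TRUE
            opts <- lines[[other]]
            k <- match(best, opts)
            if (!is.na(k) && k > 1L && k < length(opts)) {
              lines[[other]] <- opts[seq_len(k)]
              second <- opts[(k + 1L):length(opts)]
              nid <- length(lines) + 1L
              if (nid == id) {                # current id not stored yet
                lines[[id]] <- pts            # placeholder, updated below
                nid <- id + 1L
              }
              lines[[nid]] <- second
              visited[second] <- nid
            }
          }
          break
        }
      }
      pts <- rev(pts)                         # grow the other direction
    }
    lines[[id]] <- pts
  }

  out <- lapply(lines, function(p) {
    data.frame(x = lp$px[p], y = lp$py[p], s = sMat[p],
               row = ((p - 1L) %% nr) + 1L,
               col = ((p - 1L) %/% nr) + 1L,
               junction = junction[p])
  })
  structure(list(lines = out, junctionMap = junction, dim = c(nr, nc)),
            class = "LineSet")
}

#' Estimate line width along each line point's normal
#'
#' For every point, the gradient magnitude of the image is sampled along
#' both senses of the normal; the positions of its maxima mark the left
#' and right line edges and their distance is the local width. Points
#' where an edge is not found inside the search range (or runs off the
#' image) get a missing width.
#'
#' @param line data frame of a linked line (from \code{\link{linkLines}}).
#' @param derivs the \code{"DerivativeStack"} of the same image.
#' @param maxDist search range in pixels on each side (default
#'   \code{4 * sigma} of the stack).
#' @return The line data frame with added columns \code{width},
#'   \code{edgeLeft}, \code{edgeRight} (distances, \code{NA} when
#'   missing).
#' @export
estimateWidth <- function(line, derivs, maxDist = NULL) {
  if (!inherits(derivs, "DerivativeStack"))
    .stopf("derivs must come from gaussianDerivatives()")
  if (is.null(maxDist)) maxDist <- 4 * derivs$sigma
  gm <- sqrt(derivs$rx^2 + derivs$ry^2)
  ## 1-px stepping keeps the parabolic peak fit well conditioned on the
  ## bilinearly interpolated gradient magnitude (finer steps snap to the
  ## piecewise-linear kinks at pixel nodes)
  step <- 1
  ts <- seq(step, max(maxDist, 3 * step), by = step)
  n <- nrow(line)
  eL <- eR <- rep(NA_real_, n)
  ## normal direction per point from the field is not stored in the data
  ## frame; recover it from the local gradient of the smoothed Hessian is
  ## overkill -- the linking step kept points ordered, so use the local
  ## tangent of the line and take its perpendicular.
  tx <- ty <- rep(NA_real_, n)
  if (n >= 2L) {
    tx <- c(line$x[2L] - line$x[1L], diff(line$x, lag = 2L) / 2,
            line$x[n] - line$x[n - 1L])
    ty <- c(line$y[2L] - line$y[1L], diff(line$y, lag = 2L) / 2,
            line$y[n] - line$y[n - 1L])
  } else {
    tx <- 1; ty <- 0
  }
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm < 1e-12] <- 1
  nxv <- -ty / nrm; nyv <- tx / nrm
  sideMax <- function(x0, y0, nx, ny) {
    v <- .bilinear(gm, x0 + ts * nx, y0 + ts * ny)
    if (all(is.na(v))) return(NA_real_)
    k <- which.max(v)
    if (is.na(v[k]) || k <= 1L || k >= length(ts) ||
        any(is.na(v[seq_len(k + 1L)])))
      return(NA_real_)
    ## parabolic subpixel refinement of the gradient maximum
    den <- v[k - 1L] - 2 * v[k] + v[k + 1L]
    off <- if (abs(den) < 1e-12) 0 else 0.5 * (v[k - 1L] - v[k + 1L]) / den
    ts[k] + step * pmin(pmax(off, -0.5), 0.5)
  }
  for (i in seq_len(n)) {
    eR[i] <- sideMax(line$x[i], line$y[i], nxv[i], nyv[i])
    eL[i] <- sideMax(line$x[i], line$y[i], -nxv[i], -nyv[i])
  }
  line$edgeLeft <- eL
  line$edgeRight <- eR
  line$widthRaw <- eL + eR
  ## The gradient maxima of a Gaussian cross profile (spread sp) observed
  ## at detection scale sigma sit at sqrt(sp^2 + sigma^2); deconvolve the
  ## detection scale and report the FWHM of the underlying profile.
  sd2 <- derivs$sigma^2
  halfFWHM <- function(e) sqrt(2 * log(2)) * sqrt(pmax(e^2 - sd2, 0))
  line$width <- halfFWHM(eL) + halfFWHM(eR)
  line$nxNormal <- nxv
  line$nyNormal <- nyv
  line
}

#' Refine line positions for asymmetric contrast
#'
#' Smoothing biases the detected ridge of a line with unequal flanks
#' toward the broader flank. Using the estimated edge distances as a
#' measure of that asymmetry, each point is moved along its normal
#' toward the narrower flank by half the edge-distance imbalance,
#' clamped to at most 1 px. Symmetric lines are left in place.
#'
#' @param line data frame with width columns from
#'   \code{\link{estimateWidth}}.
#' @param gain correction gain applied to the imbalance (default 1).
#' @return The line data frame with refined \code{x}, \code{y} and the
#'   applied \code{shift}.
#' @export
refinePositions <- function(line, gain = 1) {
  if (!all(c("edgeLeft", "edgeRight", "nxNormal", "nyNormal") %in%
           names(line)))
    .stopf("line must carry width estimates (run estimateWidth first)")
  shift <- -gain * (line$edgeRight - line$edgeLeft) / 2
  shift[is.na(shift)] <- 0
  shift <- pmin(pmax(shift, -1), 1)
  line$x <- line$x + shift * line$nxNormal
  line$y <- line$y + shift * line$nyNormal
  line$shift <- shift
  line
}

#' Detect ridges in an image
#'
#' Convenience wrapper running \code{\link{gaussianDerivatives}},
#' \code{\link{linePoints}}, \code{\link{linkLines}}, and optionally
#' width estimation and position refinement.
#'
#' @param image \linkS4class{Micrograph} or numeric matrix with bright
#'   ridges (e.g. an enhanced image \code{U}).
#' @param sigma detection scale in pixels.
#' @param upper,lower hysteresis thresholds.
#' @param widths estimate widths? (default TRUE)
#' @param refine refine positions? (default TRUE; implies widths)
#' @return A \code{"LineSet"} whose lines carry width columns when
#'   requested.
#' @export
detectRidges <- function(image, sigma, upper, lower, widths = TRUE,
                         refine = TRUE) {
  derivs <- gaussianDerivatives(image, sigma)
  lp <- linePoints(derivs)
  ls <- linkLines(lp, upper, lower)
  if (widths || refine) {
    ls$lines <- lapply(ls$lines, function(ln) {
      ln <- estimateWidth(ln, derivs)
      if (refine) ln <- refinePositions(ln)
      ln
    })
  }
  ls
}
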