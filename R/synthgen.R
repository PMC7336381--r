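#' @include AllClasses.R utils.R
NULL

#' Construct a SceneSpec
#'
#' Defaults describe the synthetic study conditions used throughout the
#' package's tests: 1024 x 1024 px scenes with 5 filaments of 24 px
#' width, gentle curvature, 2 crossings and a contrast-to-noise ratio
#' of 0.5 (dark filaments whose centerline depth is half the noise
#' standard deviation, the regime where plain ridge detection fails and
#' oriented averaging is required).
#'
#' @param imageDim image size \code{c(nrow, ncol)} (default 1024 x 1024).
#' @param nFilaments number of filaments (default 5).
#' @param fw filament width in pixels, FWHM of the dark Gaussian cross
#'   profile (default 24).
#' @param curvature maximum centerline curvature in 1/px (default 0.002).
#' @param nCrossings filaments forced to cross an earlier one (default 2).
#' @param gapRate expected discontinuities per 100 px of centerline
#'   (default 0).
#' @param closePairGap centerline separation in px of a near-parallel
#'   close pair; \code{NA} (default) disables it.
#' @param carbonEdge add a dark half-plane with a sharp vertical edge
#'   (default FALSE).
#' @param carbonFraction fraction of the width covered by carbon
#'   (default 0.25).
#' @param snr peak filament depth over noise standard deviation
#'   (default 0.5; \code{Inf} = noise-free).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(imageDim = c(1024L, 1024L), nFilaments = 5L, fw = 24,
                      curvature = 0.002, nCrossings = 2L, gapRate = 0,
                      closePairGap = NA, carbonEdge = FALSE,
                      carbonFraction = 0.25, snr = 0.5, seed = 1L) {
  new("SceneSpec", imageDim = as.integer(imageDim),
      nFilaments = as.integer(nFilaments), fw = fw, curvature = curvature,
      nCrossings = as.integer(nCrossings), gapRate = gapRate,
      closePairGap = as.numeric(closePairGap),
      carbonEdge = isTRUE(carbonEdge), carbonFraction = carbonFraction,
      snr = snr, seed = as.integer(seed))
}

## one smooth random centerline: random walk of the heading with bounded
## curvature, fixed step; stops at the image margin
.randomCenterline <- function(dimv, curvature, margin, start = NULL,
                              heading = NULL, minLen = 300,
                              maxLen = 900, xmin = 0) {
  step <- 4
  maxTurn <- curvature * step
  for (try in 1:40) {
    x <- if (is.null(start)) stats::runif(1, xmin + margin,
                                          dimv[2] - margin)
         else start[1]
    y <- if (is.null(start)) stats::runif(1, margin, dimv[1] - margin)
         else start[2]
    h <- if (is.null(heading)) stats::runif(1, 0, 2 * pi) else heading
    L <- stats::runif(1, minLen, maxLen)
    n <- ceiling(L / step)
    xs <- numeric(n + 1); ys <- numeric(n + 1)
    xs[1] <- x; ys[1] <- y
    i <- 1L
    while (i <= n) {
      h <- h + stats::runif(1, -maxTurn, maxTurn)
      nx <- xs[i] + step * cos(h)
      ny <- ys[i] + step * sin(h)
      if (nx < xmin + margin || nx > dimv[2] - margin ||
          ny < margin || ny > dimv[1] - margin) break
      xs[i + 1L] <- nx; ys[i + 1L] <- ny
      i <- i + 1L
    }
    xs <- xs[seq_len(i)]; ys <- ys[seq_len(i)]
    if ((i - 1L) * step >= minLen)
      return(data.frame(x = xs, y = ys))
  }
  NULL
}

## a centerline forced through `point` at absolute angle `ang`: straight
## walk with bounded-curvature wobble in both directions from the point
.crossingCenterline <- function(dimv, curvature, margin, point, ang,
                                halfLen = 300, xmin = 0) {
  step <- 4
  maxTurn <- curvature * step
  one <- function(h0) {
    xs <- point[1]; ys <- point[2]; h <- h0
    for (i in seq_len(ceiling(halfLen / step))) {
      h <- h + stats::runif(1, -maxTurn, maxTurn)
      nx <- xs[length(xs)] + step * cos(h)
      ny <- ys[length(ys)] + step * sin(h)
      if (nx < xmin + margin || nx > dimv[2] - margin ||
          ny < margin || ny > dimv[1] - margin) break
      xs <- c(xs, nx); ys <- c(ys, ny)
    }
    data.frame(x = xs, y = ys)
  }
  a <- one(ang)
  b <- one(ang + pi)
  data.frame(x = c(rev(b$x[-1]), a$x), y = c(rev(b$y[-1]), a$y))
}

#' Generate a synthetic micrograph with ground truth
#'
#' Draws smooth random centerlines with bounded curvature, renders each
#' as a dark ridge with a Gaussian cross profile of FWHM \code{fw},
#' optionally inserts crossings, unrendered gap intervals, a
#' near-parallel close pair and a dark carbon half-plane with a sharp
#' vertical edge, then adds white Gaussian noise of unit standard
#' deviation scaled so that peak filament depth / noise sd equals
#' \code{snr}. The output is deterministic given \code{spec@seed}.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return A list with elements \code{micrograph}
#'   (\linkS4class{Micrograph}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  dimv <- spec@imageDim
  margin <- max(3 * spec@fw, 32)
  if (2 * margin >= min(dimv))
    .stopf("image %d x %d too small for fw = %g", dimv[1], dimv[2],
           spec@fw)
  ## rough packing feasibility: each filament needs ~minLen px of path
  if (spec@nFilaments * 300 * spec@fw > 4 * prod(dimv))
    .stopf("too many filaments (%d) for a %d x %d image",
           spec@nFilaments, dimv[1], dimv[2])
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec@seed)

  nPlain <- spec@nFilaments
  hasPair <- is.finite(spec@closePairGap)
  nCross <- min(spec@nCrossings, spec@nFilaments - 1L - hasPair)
  ## filaments stay off the carbon half-plane so that masking affects
  ## only the spurious edge/carbon picks, not the true filaments
  xmin <- if (spec@carbonEdge)
    round(spec@carbonFraction * dimv[2]) else 0
  cls <- list()
  ## plain filaments first
  for (i in seq_len(nPlain - nCross - hasPair)) {
    cl <- .randomCenterline(dimv, spec@curvature, margin, xmin = xmin)
    if (is.null(cl)) .stopf("could not place filament %d", i)
    cls[[length(cls) + 1L]] <- cl
  }
  if (!length(cls)) .stopf("need at least one plain filament")
  ## close pair: parallel copy of the first filament
  if (hasPair) {
    f1 <- cls[[1L]]
    n <- nrow(f1)
    tx <- c(f1$x[2] - f1$x[1], diff(f1$x, lag = 2) / 2,
            f1$x[n] - f1$x[n - 1])
    ty <- c(f1$y[2] - f1$y[1], diff(f1$y, lag = 2) / 2,
            f1$y[n] - f1$y[n - 1])
    nrm <- sqrt(tx^2 + ty^2); nrm[nrm < 1e-12] <- 1
    px <- f1$x - ty / nrm * spec@closePairGap
    py <- f1$y + tx / nrm * spec@closePairGap
    keep <- px >= margin & px <= dimv[2] - margin &
      py >= margin & py <= dimv[1] - margin
    cls[[length(cls) + 1L]] <- data.frame(x = px[keep], y = py[keep])
  }
  ## crossing filaments through a random interior point of an earlier one
  for (j in seq_len(nCross)) {
    host <- cls[[1L + (j - 1L) %% length(cls)]]
    k <- sample(floor(nrow(host) * 0.3):ceiling(nrow(host) * 0.7), 1L)
    hostAng <- atan2(host$y[min(k + 1L, nrow(host))] - host$y[k],
                     host$x[min(k + 1L, nrow(host))] - host$x[k])
    ang <- hostAng + stats::runif(1, 40, 140) * pi / 180
    cls[[length(cls) + 1L]] <-
      .crossingCenterline(dimv, spec@curvature, margin,
                          c(host$x[k], host$y[k]), ang, xmin = xmin)
  }

  ## gap intervals per filament (arc length), left unrendered
  gaps <- vector("list", length(cls))
  for (i in seq_along(cls)) {
    s <- .arcLength(cls[[i]]$x, cls[[i]]$y)
    L <- s[length(s)]
    ng <- if (spec@gapRate > 0) stats::rpois(1, spec@gapRate * L / 100)
          else 0L
    iv <- matrix(numeric(0), 0, 2)
    if (ng > 0) {
      for (g in seq_len(ng)) {
        gl <- stats::runif(1, 1, 2) * spec@fw
        g0 <- stats::runif(1, 0, max(L - gl, 0))
        iv <- rbind(iv, c(g0, g0 + gl))
      }
    }
    gaps[[i]] <- iv
  }

  ## render: per filament, distance map to the (gap-free) centerline
  ## pixels, then a dark Gaussian cross profile of FWHM fw
  sigma <- spec@fw / (2 * sqrt(2 * log(2)))
  noiseSd <- 1
  ## noise-free scenes (snr = Inf) keep a unit-depth ridge
  depth <- if (is.finite(spec@snr)) spec@snr * noiseSd else 1
  img <- matrix(0, dimv[1], dimv[2])
  for (i in seq_along(cls)) {
    dd <- .polylineDensify(cls[[i]]$x, cls[[i]]$y, 0.5)
    s <- .arcLength(dd$x, dd$y)
    keep <- rep(TRUE, nrow(dd))
    iv <- gaps[[i]]
    for (g in seq_len(nrow(iv)))
      keep <- keep & !(s >= iv[g, 1] & s <= iv[g, 2])
    if (!any(keep)) next
    stamp <- matrix(1, dimv[1], dimv[2])
    r <- pmin(pmax(round(dd$y[keep]), 1L), dimv[1])
    c <- pmin(pmax(round(dd$x[keep]), 1L), dimv[2])
    stamp[cbind(r, c)] <- 0
    dmap <- EBImage::distmap(stamp)
    prof <- exp(-dmap^2 / (2 * sigma^2))
    prof[dmap > 4 * sigma] <- 0
    img <- img - depth * prof
  }

  ## carbon: dark half-plane with a sharp vertical edge
  mask <- matrix(1, dimv[1], dimv[2])
  if (spec@carbonEdge) {
    e <- max(1L, as.integer(round(spec@carbonFraction * dimv[2])))
    img[, seq_len(e)] <- img[, seq_len(e)] - 2 * noiseSd
    mask[, seq_len(e)] <- 0
  }

  if (is.finite(spec@snr))
    img <- img + matrix(stats::rnorm(prod(dimv), 0, noiseSd),
                        dimv[1], dimv[2])

  truth <- FilamentSet(cls, dimv)
  list(micrograph = Micrograph(img),
       truth = new("GroundTruth", centerlines = truth, mask = mask,
                   gaps = gaps))
}
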