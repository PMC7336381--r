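#' @include AllClasses.R utils.R
NULL

#' Trace candidate boxes into filaments using the directional map
#'
#' Candidate boxes (e.g. CNN picks) carry no filament assignment. A box
#' is chosen at random (seeded RNG), the local filament direction is
#' read from the directional map \code{V}, and the nearest untraced box
#' within a search radius proportional to the box size and within the
#' \code{+/- alpha/2} cone around that direction (both senses, since
#' filaments are unoriented) is appended; the search continues from the
#' new box. When no box is found the trace grows from the seed in the
#' opposite sense, then a new filament is started from another random
#' untraced box. When a search selects a box already belonging to
#' another filament and the two segments' end directions differ by at
#' most \code{mergeAngleTol}, the segments are merged. Every input box
#' ends up in at most one filament.
#'
#' @param candidates data frame with columns \code{x}, \code{y} (box
#'   centers, px) and optionally \code{size}; or a \linkS4class{BoxSet}.
#' @param directionMap matrix of orientations in \code{[0, pi)} (the
#'   \code{V} of \code{\link{enhanceOrient}}), covering all box centers.
#' @param cfg a \linkS4class{TraceConfig}.
#' @param boxSize box size in px used for the search radius when the
#'   candidates carry none (default 20).
#' @param scale factor mapping candidate coordinates to directional-map
#'   pixels (e.g. the binning factor; default 1).
#' @return List of integer vectors; each vector holds the row indices of
#'   \code{candidates} forming one filament, in traced order.
#' @export
traceFilaments <- function(candidates, directionMap, cfg, boxSize = 20,
                           scale = 1) {
  if (is(candidates, "BoxSet")) candidates <- candidates@boxes
  n <- nrow(candidates)
  if (!n) return(list())
  V <- if (is(directionMap, "EnhancedMaps")) directionMap@V
       else as.matrix(directionMap)
  x <- candidates$x; y <- candidates$y
  sz <- if ("size" %in% names(candidates) && all(is.finite(candidates$size)))
    candidates$size else rep(boxSize, n)
  vr <- pmin(pmax(round(y / scale), 1L), nrow(V))
  vc <- pmin(pmax(round(x / scale), 1L), ncol(V))
  if (any(round(y / scale) < 0.5 | round(y / scale) > nrow(V) + 0.5) ||
      any(round(x / scale) < 0.5 | round(x / scale) > ncol(V) + 0.5))
    .stopf("direction map does not cover all box centers")
  dirAt <- V[cbind(vr, vc)]
  halfCone <- (cfg@alpha / 2) * pi / 180

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg@seed)

  assignment <- integer(n)              # 0 = untraced
  fils <- list()

  ## direction of a filament at one of its ends (pointing outward)
  endDir <- function(idx, atStart) {
    if (length(idx) == 1L) return(dirAt[idx[1L]])
    if (atStart)
      atan2(y[idx[1L]] - y[idx[2L]], x[idx[1L]] - x[idx[2L]])
    else {
      m <- length(idx)
      atan2(y[idx[m]] - y[idx[m - 1L]], x[idx[m]] - x[idx[m - 1L]])
    }
  }

  ## find the nearest box (traced or not) within radius and cone of the
  ## search direction from box `from`
  findNext <- function(from, dir, exclude, bothSenses) {
    r <- cfg@radiusFactor * sz[from]
    dx <- x - x[from]; dy <- y - y[from]
    d <- sqrt(dx^2 + dy^2)
    ok <- d > 1e-9 & d <= r
    ok[exclude] <- FALSE
    if (!any(ok)) return(NA_integer_)
    stepAng <- atan2(dy, dx)
    inCone <- .angDiff2Pi(stepAng, dir) <= halfCone
    if (bothSenses)
      inCone <- inCone | .angDiff2Pi(stepAng, dir + pi) <= halfCone
    ok <- ok & inCone
    if (!any(ok)) return(NA_integer_)
    which(ok)[which.min(d[ok])]
  }

  growFrom <- function(chain, sense) {
    ## sense +1: grow at tail; -1: grow at head (chain reversed first)
    if (sense < 0) chain <- rev(chain)
    repeat {
      cur <- chain[length(chain)]
      ## once the chain has a direction, search only forward; a single
      ## seed box only knows its orientation, so both senses are allowed
      dir <- if (length(chain) >= 2L) {
        prev <- chain[length(chain) - 1L]
        atan2(y[cur] - y[prev], x[cur] - x[prev])
      } else dirAt[cur]
      nxt <- findNext(cur, dir, exclude = chain,
                      bothSenses = length(chain) < 2L)
      if (is.na(nxt)) break
      if (assignment[nxt] != 0L) {
        ## merge with a previously traced segment if directions are
        ## comparable and we touch one of its ends
        fid <- assignment[nxt]
        seg <- fils[[fid]]
        tol <- cfg@mergeAngleTol * pi / 180
        myDir <- dir
        if (identical(nxt, seg[1L])) {
          if (.angDiffPi(myDir %% pi, endDir(seg, TRUE) %% pi) <= tol) {
            chain <- c(chain, seg)
            fils[[fid]] <<- integer(0)
            assignment[seg] <<- 0L        # re-assigned by caller
            next
          }
        } else if (identical(nxt, seg[length(seg)])) {
          if (.angDiffPi(myDir %% pi, endDir(seg, FALSE) %% pi) <= tol) {
            chain <- c(chain, rev(seg))
            fils[[fid]] <<- integer(0)
            assignment[seg] <<- 0L
            next
          }
        }
        break
      }
      chain <- c(chain, nxt)
    }
    if (sense < 0) rev(chain) else chain
  }

  while (any(assignment == 0L)) {
    pool <- which(assignment == 0L)
    seed <- if (length(pool) == 1L) pool else sample(pool, 1L)
    chain <- seed
    assignment[seed] <- -1L             # provisional
    chain <- growFrom(chain, +1L)
    chain <- growFrom(chain, -1L)
    fid <- length(fils) + 1L
    fils[[fid]] <- chain
    assignment[chain] <- fid
  }
  fils[lengths(fils) > 0L]
}

#' Resample traced filaments into evenly spaced boxes
#'
#' Fits a polyline through each filament's member-box centers (in traced
#' order) and emits boxes at arc-length multiples of \code{boxDistance},
#' the same contract as \code{\link{placeBoxes}}. Filaments with fewer
#' than \code{cfg@minBoxes} members are dropped (isolated boxes are not
#' filaments).
#'
#' @param traced list of index vectors from \code{\link{traceFilaments}}.
#' @param candidates the candidate table the indices refer to.
#' @param cfg a \linkS4class{TraceConfig}.
#' @param boxSize output box size in px (default: the candidates' size
#'   column, else 20).
#' @return A \linkS4class{BoxSet}.
#' @export
resampleBoxes <- function(traced, candidates, cfg, boxSize = NULL) {
  if (is(candidates, "BoxSet")) candidates <- candidates@boxes
  if (is.null(boxSize))
    boxSize <- if ("size" %in% names(candidates))
      stats::median(candidates$size) else 20
  rows <- list()
  fid <- 0L
  for (idx in traced) {
    if (length(idx) < cfg@minBoxes) next
    fid <- fid + 1L
    xs <- candidates$x[idx]; ys <- candidates$y[idx]
    s <- .arcLength(xs, ys)
    L <- s[length(s)]
    at <- seq(0, L, by = cfg@boxDistance)
    pts <- .polylineAt(xs, ys, at)
    rows[[length(rows) + 1L]] <-
      data.frame(x = pts$x, y = pts$y, size = boxSize, filament = fid,
                 ord = seq_along(at))
  }
  b <- if (length(rows)) do.call(rbind, rows)
       else data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                       filament = integer(0), ord = integer(0))
  BoxSet(b)
}
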