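#' @include AllClasses.R utils.R linefilter.R ridge.R metrics.R
NULL

#' Preprocess a micrograph for line detection
#'
#' Bins by block averaging, low-pass filters with a Gaussian roll-off at
#' the absolute cutoff frequency (cycles per pixel on the binned image),
#' z-normalizes (subtract mean, divide by standard deviation) and
#' saturates values beyond \code{+/- clipSigma}.
#'
#' @param micrograph \linkS4class{Micrograph} or numeric matrix.
#' @param cfg a \linkS4class{PickConfig}.
#' @return A \linkS4class{Micrograph} holding the binned, filtered,
#'   normalized, clipped image.
#' @export
preprocessMicrograph <- function(micrograph, cfg) {
  img <- .asImageMatrix(micrograph)
  if (min(dim(img)) < cfg@binFactor)
    .stopf("micrograph smaller than the binning factor")
  img <- .blockBin(img, cfg@binFactor)
  ## Gaussian low-pass, sigma_f = cutoff in cycles/px
  f2 <- outer(.fftFreq(nrow(img))^2, .fftFreq(ncol(img))^2, "+")
  H <- exp(-f2 / (2 * cfg@lowpassCutoff^2))
  img <- Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / length(img)
  s <- stats::sd(img)
  if (!is.finite(s) || s < 1e-12)
    .stopf("micrograph has zero variance after filtering")
  img <- (img - mean(img)) / s
  img <- pmin(pmax(img, -cfg@clipSigma), cfg@clipSigma)
  ps <- if (is(micrograph, "Micrograph")) micrograph@pixelSize else NA_real_
  Micrograph(img, ps * cfg@binFactor)
}

## kernel support for the bank, 3-sigma truncated but clamped to fit the
## working image
.bankSupport <- function(cfg, dimWorking) {
  sy <- sigmaFromFWHM(max(cfg@fw, cfg@mw))
  sup <- .oddify(2 * ceiling(3 * sy) + 1)
  maxSup <- min(dimWorking) - 1L
  if (maxSup %% 2L == 0L) maxSup <- maxSup - 1L
  min(sup, maxSup)
}

## precompute everything threshold-independent for one preprocessed
## micrograph; reused by the grid-search optimizer
.detectionState <- function(prep, cfg) {
  img <- .asImageMatrix(prep)
  support <- .bankSupport(cfg, dim(img))
  bank <- filterBank(cfg@fw, cfg@mw, cfg@nAngles, support = support)
  maps <- enhanceOrient(img, bank)
  derivs <- gaussianDerivatives(maps@U, sigmaFromFWHM(cfg@fw))
  list(maps = maps, derivs = derivs, lp = linePoints(derivs),
       dim = dim(img))
}

## local tangent angles (radians, mod pi) along an ordered point chain;
## a wide difference baseline keeps the angles stable against subpixel
## refinement jitter
.chainTangents <- function(x, y, lag = 3L) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  lag <- min(lag, n - 1L)
  i0 <- pmax(seq_len(n) - lag, 1L)
  i1 <- pmin(seq_len(n) + lag, n)
  atan2(y[i1] - y[i0], x[i1] - x[i0]) %% pi
}

## is the junction at (row, col) of host line `h` transversal, i.e. does
## some other line pass it at a clearly different orientation? Collinear
## collisions (noise stubs rejoining their own ridge) are not crossings.
.isTransversal <- function(jr, jc, hostAng, pixLine, pixAng, h, dims) {
  rr <- max(1L, jr - 2L):min(dims[1], jr + 2L)
  cc <- max(1L, jc - 2L):min(dims[2], jc + 2L)
  for (r in rr) for (c in cc) {
    l <- pixLine[r, c]
    if (l == 0L || l == h) next
    a <- pixAng[r, c]
    if (!is.na(a) && !is.na(hostAng) &&
        .angDiffPi(a, hostAng) > pi / 6) return(TRUE)
  }
  FALSE
}

## merge collinear pieces whose free ends face each other across a small
## gap; ends cut at transversal junctions never merge, so crossings stay
## skipped
.mergeCollinear <- function(pieces, gap, tolRad) {
  ## cap the merge workload under pathological threshold settings where
  ## thousands of noise stubs appear; the longest pieces always take part
  if (length(pieces) > 400L) {
    o <- order(vapply(pieces, function(p) nrow(p$f), integer(1)),
               decreasing = TRUE)
    rest <- pieces[o[-seq_len(400L)]]
    pieces <- c(.mergeCollinearCore(pieces[o[seq_len(400L)]], gap, tolRad),
                rest)
  } else {
    pieces <- .mergeCollinearCore(pieces, gap, tolRad)
  }
  pieces
}

.mergeCollinearCore <- function(pieces, gap, tolRad) {
  np <- length(pieces)
  if (np < 2L) return(pieces)
  ## end table: one row per free (non-junction) piece end
  rows <- list()
  for (i in seq_len(np)) {
    f <- pieces[[i]]$f
    n <- nrow(f)
    bl <- min(8L, n)                     # tangent baseline in points
    if (!pieces[[i]]$jStart)
      rows[[length(rows) + 1L]] <-
        c(i, 1, f$x[1L], f$y[1L],
          atan2(f$y[1L] - f$y[bl], f$x[1L] - f$x[bl]))
    if (!pieces[[i]]$jEnd)
      rows[[length(rows) + 1L]] <-
        c(i, 2, f$x[n], f$y[n],
          atan2(f$y[n] - f$y[n - bl + 1L], f$x[n] - f$x[n - bl + 1L]))
  }
  if (length(rows) < 2L) return(pieces)
  E <- do.call(rbind, rows)
  ne <- nrow(E)
  dx <- outer(E[, 3], E[, 3], "-")
  dy <- outer(E[, 4], E[, 4], "-")
  d <- sqrt(dx^2 + dy^2)
  samePiece <- outer(E[, 1], E[, 1], "==")
  cand <- which(upper.tri(d) & d <= gap & !samePiece, arr.ind = TRUE)
  if (!nrow(cand)) return(pieces)
  ## collinearity: both end tangents within tol of the connecting line
  conn <- (atan2(E[cand[, 2], 4] - E[cand[, 1], 4],
                 E[cand[, 2], 3] - E[cand[, 1], 3])) %% pi
  ok <- .angDiffPi(E[cand[, 1], 5] %% pi, conn) <= tolRad &
        .angDiffPi(E[cand[, 2], 5] %% pi, conn) <= tolRad
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(pieces)
  o <- order(d[cand])
  cand <- cand[o, , drop = FALSE]
  ## greedy matching: each end used once; no cycles (union-find)
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  endUsed <- logical(ne)
  edges <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (endUsed[a] || endUsed[b]) next
    ra <- find(E[a, 1]); rb <- find(E[b, 1])
    if (ra == rb) next
    parent[ra] <- rb
    endUsed[a] <- endUsed[b] <- TRUE
    edges[[length(edges) + 1L]] <- c(E[a, 1], E[a, 2], E[b, 1], E[b, 2])
  }
  if (!length(edges)) return(pieces)
  ## assemble each connected component into one ordered chain of pieces
  adj <- vector("list", np)             # per piece: list of (otherPiece, myEnd, otherEnd)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], list(c(e[3], e[2], e[4])))
    adj[[e[3]]] <- c(adj[[e[3]]], list(c(e[1], e[4], e[2])))
  }
  deg <- lengths(adj)
  done <- logical(np)
  out <- list()
  orient <- function(p, joinEndLast) {
    ## joinEndLast: the end (1 or 2) that must come last
    if (joinEndLast == 1L) {
      p$f <- p$f[rev(seq_len(nrow(p$f))), , drop = FALSE]
      tmp <- p$jStart; p$jStart <- p$jEnd; p$jEnd <- tmp
    }
    p
  }
  for (i in seq_len(np)) {
    if (done[i] || deg[i] > 1L) next
    if (deg[i] == 0L) { out[[length(out) + 1L]] <- pieces[[i]]; done[i] <- TRUE; next }
    ## walk the path starting at this degree-1 piece
    chain <- list()
    cur <- i
    prevEnd <- NA_integer_              # end of cur joined to previous piece
    repeat {
      done[cur] <- TRUE
      nxt <- NULL
      for (l in adj[[cur]]) if (!done[l[1]]) { nxt <- l; break }
      if (is.null(nxt)) {
        joinLast <- if (is.na(prevEnd)) 2L else (3L - prevEnd)
        ## orient so the previously joined end comes first
        p <- pieces[[cur]]
        if (!is.na(prevEnd) && prevEnd == 2L) p <- orient(p, 1L)
        chain[[length(chain) + 1L]] <- p
        break
      }
      p <- pieces[[cur]]
      myJoin <- nxt[2]
      if (!is.na(prevEnd)) {
        ## joined to previous at prevEnd (must be first), to next at myJoin
        if (prevEnd == 2L) p <- orient(p, 1L)
      } else {
        ## first piece: its joined end must come last
        p <- orient(p, myJoin)
        myJoin <- 2L
      }
      chain[[length(chain) + 1L]] <- p
      prevEnd <- nxt[3]
      cur <- nxt[1]
    }
    f <- do.call(rbind, lapply(chain, `[[`, "f"))
    out[[length(out) + 1L]] <-
      list(f = f, jStart = chain[[1L]]$jStart,
           jEnd = chain[[length(chain)]]$jEnd)
  }
  ## cycles (all degree 2) cannot occur thanks to union-find
  out
}

## linked lines -> FilamentSet in unbinned coordinates: junction
## trimming (transversal junctions only), gap merging, rescaling,
## minimum-length filtering
.filamentsFromLines <- function(ls, cfg, dimWorking) {
  b <- cfg@binFactor
  trim <- cfg@fw / 2 + 2          # junction-localization margin of 2 px
  dims <- ls$dim
  ## pixel -> line id and local tangent maps for the transversal test
  pixLine <- matrix(0L, dims[1], dims[2])
  pixAng <- matrix(NA_real_, dims[1], dims[2])
  for (li in seq_along(ls$lines)) {
    ln <- ls$lines[[li]]
    if (!nrow(ln)) next
    idx <- cbind(ln$row, ln$col)
    pixLine[idx] <- li
    pixAng[idx] <- .chainTangents(ln$x, ln$y)
  }
  pieces <- list()
  for (li in seq_along(ls$lines)) {
    ln <- ls$lines[[li]]
    n <- nrow(ln)
    if (n < 2L) next
    tang <- .chainTangents(ln$x, ln$y)
    jidx <- which(ln$junction)
    ## ends terminating next to a junction pixel count as junction ends
    for (e in c(1L, n)) {
      rr <- max(1L, ln$row[e] - 1L):min(dims[1], ln$row[e] + 1L)
      cc <- max(1L, ln$col[e] - 1L):min(dims[2], ln$col[e] + 1L)
      if (any(ls$junctionMap[rr, cc])) jidx <- c(jidx, e)
    }
    jidx <- sort(unique(jidx))
    jidx <- jidx[vapply(jidx, function(j)
      .isTransversal(ln$row[j], ln$col[j], tang[j], pixLine, pixAng, li,
                     dims), logical(1))]
    keep <- rep(TRUE, n)
    if (length(jidx)) {
      s <- .arcLength(ln$x, ln$y)
      for (j in jidx) keep <- keep & abs(s - s[j]) > trim
    }
    if (sum(keep) < 2L) next
    runs <- split(which(keep), cumsum(c(1L, diff(which(keep)) != 1L)))
    for (rn in runs) {
      if (length(rn) < 2L) next
      cut1 <- rn[1L] != 1L          # this end was created by a trim
      cut2 <- rn[length(rn)] != n
      f <- data.frame(x = ln$x[rn], y = ln$y[rn])
      if ("width" %in% names(ln)) f$width <- ln$width[rn]
      pieces[[length(pieces) + 1L]] <-
        list(f = f, jStart = cut1, jEnd = cut2)
    }
  }
  pieces <- .mergeCollinear(pieces, gap = 3 * cfg@fw, tolRad = 25 * pi / 180)
  out <- list()
  for (p in pieces) {
    f <- p$f
    ## map working-image pixel centers to unbinned pixel centers
    f$x <- (f$x - 0.5) * b + 0.5
    f$y <- (f$y - 0.5) * b + 0.5
    if ("width" %in% names(f)) f$width <- f$width * b
    s <- .arcLength(f$x, f$y)
    if (s[length(s)] >= cfg@minLength) out[[length(out) + 1L]] <- f
  }
  FilamentSet(out, as.integer(c(dimWorking[1], dimWorking[2]) * b))
}

#' Detect filaments in a preprocessed micrograph
#'
#' Enhances lines with the oriented kernel bank, runs ridge detection on
#' the enhanced image with the configured hysteresis thresholds, splits
#' lines at junctions and trims their ends clear of crossings, rescales
#' coordinates back to unbinned pixels and drops filaments shorter than
#' \code{minLength}.
#'
#' @param prep preprocessed \linkS4class{Micrograph} (see
#'   \code{\link{preprocessMicrograph}}).
#' @param cfg a \linkS4class{PickConfig}.
#' @return A \linkS4class{FilamentSet} in unbinned coordinates.
#' @export
detectFilaments <- function(prep, cfg) {
  st <- .detectionState(prep, cfg)
  ls <- linkLines(st$lp, cfg@upper, cfg@lower)
  ls$lines <- lapply(ls$lines, function(ln) estimateWidth(ln, st$derivs))
  ls$lines <- lapply(ls$lines, refinePositions)
  .filamentsFromLines(ls, cfg, st$dim)
}

#' Remove filament points in masked-out regions
#'
#' Drops centerline points falling where the binary mask is invalid
#' (zero), splits filaments at the removed runs and re-applies the
#' minimum-length filter.
#'
#' @param filamentSet a \linkS4class{FilamentSet} in unbinned
#'   coordinates.
#' @param mask binary matrix of the unbinned micrograph's shape;
#'   nonzero = valid picking region.
#' @param minLength minimum arc length (px) for the surviving pieces
#'   (default 0).
#' @return A filtered \linkS4class{FilamentSet}.
#' @export
applyMask <- function(filamentSet, mask, minLength = 0) {
  stopifnot(is(filamentSet, "FilamentSet"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), as.integer(filamentSet@imageDim)) &&
      !identical(as.integer(dim(mask)), as.integer(filamentSet@imageDim)))
    .stopf("mask shape (%d x %d) does not match image (%d x %d)",
           nrow(mask), ncol(mask), filamentSet@imageDim[1],
           filamentSet@imageDim[2])
  out <- list()
  for (f in filamentSet@filaments) {
    if (!nrow(f)) next
    r <- pmin(pmax(round(f$y), 1L), nrow(mask))
    c <- pmin(pmax(round(f$x), 1L), ncol(mask))
    ok <- mask[cbind(r, c)] != 0
    if (!any(ok)) next
    runs <- split(which(ok), cumsum(c(1L, diff(which(ok)) != 1L)))
    for (rn in runs) {
      if (length(rn) < 2L) next
      piece <- f[rn, , drop = FALSE]
      s <- .arcLength(piece$x, piece$y)
      if (s[length(s)] >= minLength)
        out[[length(out) + 1L]] <- piece
    }
  }
  FilamentSet(out, filamentSet@imageDim)
}

#' Place boxes along filament centerlines
#'
#' Arc-length parameterizes each centerline and places box centers at
#' positions 0, d, 2d, ... from the filament start, giving
#' \code{floor(length / d) + 1} boxes per filament.
#'
#' @param filamentSet a \linkS4class{FilamentSet}.
#' @param boxDistance spacing d between box centers in pixels.
#' @param boxSize box side length in pixels.
#' @return A \linkS4class{BoxSet}.
#' @export
placeBoxes <- function(filamentSet, boxDistance, boxSize) {
  stopifnot(is(filamentSet, "FilamentSet"))
  if (!is.numeric(boxDistance) || boxDistance <= 0)
    .stopf("boxDistance must be positive")
  rows <- list()
  for (i in seq_along(filamentSet@filaments)) {
    f <- filamentSet@filaments[[i]]
    if (!nrow(f)) next
    s <- .arcLength(f$x, f$y)
    L <- s[length(s)]
    at <- seq(0, L, by = boxDistance)
    pts <- .polylineAt(f$x, f$y, at)
    rows[[length(rows) + 1L]] <-
      data.frame(x = pts$x, y = pts$y, size = boxSize, filament = i,
                 ord = seq_along(at))
  }
  b <- if (length(rows)) do.call(rbind, rows)
       else data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                       filament = integer(0), ord = integer(0))
  BoxSet(b)
}

#' End-to-end picking of one micrograph
#'
#' Runs \code{\link{preprocessMicrograph}}, \code{\link{detectFilaments}},
#' optional masking and \code{\link{placeBoxes}}.
#'
#' @param micrograph raw \linkS4class{Micrograph} or matrix.
#' @param cfg a \linkS4class{PickConfig}.
#' @param mask optional binary mask (unbinned shape), nonzero = valid.
#' @return A list with \code{filaments} (\linkS4class{FilamentSet}) and
#'   \code{boxes} (\linkS4class{BoxSet}).
#' @export
pickFilaments <- function(micrograph, cfg, mask = NULL) {
  prep <- preprocessMicrograph(micrograph, cfg)
  fs <- detectFilaments(prep, cfg)
  if (!is.null(mask)) fs <- applyMask(fs, mask, cfg@minLength)
  size <- if (is.na(cfg@boxSize)) 1.5 * cfg@fw * cfg@binFactor
          else cfg@boxSize
  list(filaments = fs, boxes = placeBoxes(fs, cfg@boxDistance, size))
}

#' Grid-search optimization of the hysteresis thresholds
#'
#' Phase 1 fixes the lower threshold at 0 and scans the upper threshold
#' on a regular grid, keeping the value that maximizes pixel-level
#' recall of the annotation (ties resolved toward the larger, more
#' selective threshold). Phase 2 raises the lower threshold stepwise to
#' remove false positives for as long as recall stays within a
#' tolerance of its phase-1 value.
#'
#' @param annotated list of annotated micrographs; each element is a
#'   list with components \code{micrograph} (raw image) and
#'   \code{truth} (\linkS4class{FilamentSet}, unbinned coordinates).
#' @param cfg a \linkS4class{PickConfig}; its thresholds are ignored.
#' @param upperGrid grid of candidate upper thresholds; by default a
#'   coarse-to-fine scan (0.05 steps, then 0.01 steps around the coarse
#'   optimum) that resolves the optimum to 0.01 with far fewer full
#'   evaluations than an exhaustive 0.01 grid.
#' @param lowerStep step of the phase-2 scan (default 0.01).
#' @param recallTol tolerated recall loss in phase 2 (default 0.02).
#' @return A list with \code{upper}, \code{lower}, and \code{log}, a
#'   data frame of the scanned settings with mean recall and precision.
#' @export
optimizeThresholds <- function(annotated, cfg, upperGrid = NULL,
                               lowerStep = 0.01, recallTol = 0.02) {
  if (!length(annotated)) .stopf("need at least one annotated micrograph")
  fwU <- cfg@fw * cfg@binFactor
  states <- lapply(annotated, function(a) {
    prep <- preprocessMicrograph(a$micrograph, cfg)
    .detectionState(prep, cfg)
  })
  truths <- lapply(annotated, `[[`, "truth")
  rasters <- lapply(truths, function(tr)
    list(Bu = rasterizeFilaments(tr, fwU, tr@imageDim),
         eps = .endpointsOf(tr@filaments), shape = tr@imageDim))
  evalAt <- function(upper, lower) {
    pr <- mapply(function(st, ra) {
      ls <- linkLines(st$lp, upper, lower)
      fs <- .filamentsFromLines(ls, cfg, st$dim)
      rep <- .prCore(ra$Bu, ra$eps, fs, fwU, ra$shape)
      c(rec = if (rep@recallDefined) rep@recall else 0,
        prec = if (rep@precisionDefined) rep@precision else 0)
    }, states, rasters)
    rowMeans(pr)
  }
  log <- data.frame()
  scan <- function(grid) {
    for (u in grid) {
      m <- evalAt(u, 0)
      log <<- rbind(log, data.frame(upper = u, lower = 0,
                                    recall = m["rec"],
                                    precision = m["prec"]))
    }
  }
  ## recall is nearly flat over a plateau of upper thresholds, but its
  ## low end owes part of that recall to noise lines (precision
  ## collapse) while very large values start missing detections on
  ## images whose contrast differs from the training draw. Within the
  ## recall plateau, the smallest u that already achieves (near-)best
  ## precision is the robust representative.
  pick <- function() {
    p1 <- log[log$lower == 0, ]
    ok <- p1$recall >= max(p1$recall) - recallTol
    cand <- p1[ok, , drop = FALSE]
    good <- cand$precision >= max(cand$precision) - 0.05
    min(cand$upper[good])
  }
  if (is.null(upperGrid)) {
    scan(seq(0.05, 0.95, by = 0.05))
    coarse <- pick()
    fine <- setdiff(round(seq(coarse - 0.04, coarse + 0.04, by = 0.01), 2),
                    seq(0.05, 0.95, by = 0.05))
    scan(fine[fine > 0 & fine < 1])
  } else {
    scan(upperGrid)
  }
  upper <- pick()
  recall0 <- log$recall[log$lower == 0 & log$upper == upper][1L]
  lower <- 0
  l <- lowerStep
  while (l <= upper) {
    m <- evalAt(upper, l)
    log <- rbind(log, data.frame(upper = upper, lower = l,
                                 recall = m["rec"],
                                 precision = m["prec"]))
    if (m["rec"] < recall0 - recallTol) break
    lower <- l
    l <- l + lowerStep
  }
  rownames(log) <- NULL
  list(upper = upper, lower = lower, log = log)
}
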