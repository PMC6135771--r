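## Bin-edge construction.  Integer-valued coordinates get unit bins centred
## on the integers; continuous coordinates a fixed width (default 0.5 A).
.makeBreaks <- function(values, spec) {
  if (is.numeric(spec) && length(spec) > 2L) return(spec)  # explicit edges
  if (is.null(spec)) spec <- list()
  integer <- isTRUE(spec$integer)
  if (integer) {
    lo <- floor(min(values)); hi <- ceiling(max(values))
    return(seq(lo - 0.5, hi + 0.5, by = 1))
  }
  width <- if (!is.null(spec$width)) spec$width else 0.5
  lo <- if (!is.null(spec$min)) spec$min else min(values)
  hi <- if (!is.null(spec$max)) spec$max else max(values)
  if (hi <= lo) hi <- lo + width
  edges <- seq(lo, hi, by = width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + width)
  edges
}

.binIndex <- function(values, breaks) {
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = FALSE)
  idx[values < breaks[1L] | values > breaks[length(breaks)]] <- NA_integer_
  idx
}

.feFromCounts <- function(counts, kT) {
  mask <- counts <= 0
  if (all(mask)) stop("all bins are empty")
  p <- counts / sum(counts)
  F <- ifelse(mask, NA_real_, -kT * log(p))
  F <- F - min(F, na.rm = TRUE)
  lev <- seq(0, max(F, na.rm = TRUE), by = kT)
  list(F = F, mask = mask, levels = lev)
}

#' One-dimensional free-energy profile
#'
#' F(x) = -kT ln p(x) from a (optionally weighted) histogram of samples,
#' min-shifted so the deepest populated bin sits at 0.  Empty bins are
#' masked (NA) and never enter the minimum.  Contour levels are integer
#' multiples of kT.
#'
#' @param values samples of the coordinate (e.g. N_HB over production
#'   frames).
#' @param kT thermal energy in the energy unit of the output (kB * T).
#' @param binSpec explicit break vector, or a list with \code{integer =
#'   TRUE} for unit bins on integers, or \code{width}/\code{min}/\code{max}
#'   for continuous coordinates (default width 0.5).
#' @param weights optional nonnegative per-sample weights.
#' @param name axis name.
#' @return an \linkS4class{FESurface} with one axis.
#' @export
feProfile1D <- function(values, kT, binSpec = list(integer = TRUE),
                        weights = NULL, name = "x") {
  stopifnot(length(values) >= 1L, kT > 0)
  breaks <- .makeBreaks(values, binSpec)
  nb <- length(breaks) - 1L
  idx <- .binIndex(values, breaks)
  if (is.null(weights)) weights <- rep(1, length(values))
  keep <- !is.na(idx)
  counts <- vapply(seq_len(nb), function(b)
    sum(weights[keep][idx[keep] == b]), 0)
  fe <- .feFromCounts(counts, kT)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  new("FESurface",
      axes = list(list(name = name, breaks = breaks, mids = mids)),
      F = fe$F, mask = fe$mask, kT = kT, counts = counts,
      contourLevels = fe$levels)
}

#' Two-dimensional free-energy surface
#'
#' 2D analogue of \code{\link{feProfile1D}}: F(x, y) = -kT ln p(x, y) on a
#' product grid, min-shifted, empty bins masked, contours at every kT.
#' Typical uses: (N_SC, N_HB) folding surfaces and (end-to-end distance,
#' number of native contacts) surfaces.
#'
#' @param x,y paired samples of the two coordinates.
#' @param kT thermal energy.
#' @param xBinSpec,yBinSpec as \code{binSpec} in \code{\link{feProfile1D}}.
#' @param weights optional per-sample weights.
#' @param xName,yName axis names.
#' @return an \linkS4class{FESurface} with two axes; \code{surfaceGrid}
#'   rows follow x, columns y.
#' @export
feSurface2D <- function(x, y, kT, xBinSpec = list(integer = TRUE),
                        yBinSpec = list(integer = TRUE), weights = NULL,
                        xName = "x", yName = "y") {
  stopifnot(length(x) == length(y), length(x) >= 1L, kT > 0)
  bx <- .makeBreaks(x, xBinSpec); by <- .makeBreaks(y, yBinSpec)
  nx <- length(bx) - 1L; ny <- length(by) - 1L
  ix <- .binIndex(x, bx); iy <- .binIndex(y, by)
  if (is.null(weights)) weights <- rep(1, length(x))
  keep <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0, nx, ny)
  for (k in which(keep))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + weights[k]
  fe <- .feFromCounts(counts, kT)
  new("FESurface",
      axes = list(list(name = xName, breaks = bx,
                       mids = (bx[-1L] + bx[-length(bx)]) / 2),
                  list(name = yName, breaks = by,
                       mids = (by[-1L] + by[-length(by)]) / 2)),
      F = fe$F, mask = fe$mask, kT = kT, counts = counts,
      contourLevels = fe$levels)
}

#' Free-energy barrier between two coordinate values on a 1D profile
#'
#' Height of the highest intervening bin above the shallower of the two
#' basin minima; a convenience for asserting bimodality.
#'
#' @param surface 1D \linkS4class{FESurface}.
#' @return list: \code{barrier} (kT units of the surface's energy),
#'   \code{minima} (bin mids of the local minima found).
#' @export
profileBarrier <- function(surface) {
  f <- surface@F
  stopifnot(!is.matrix(f))
  ok <- which(!surface@mask)
  v <- f[ok]
  # local minima over populated bins
  locmin <- ok[which(diff(sign(diff(c(Inf, v, Inf)))) == 2)]
  if (length(locmin) < 2L)
    return(list(barrier = 0, minima = surface@axes[[1L]]$mids[locmin]))
  # highest saddle between the two deepest minima
  o <- locmin[order(f[locmin])][1:2]
  lo <- min(o); hi <- max(o)
  saddle <- max(f[lo:hi], na.rm = TRUE)
  list(barrier = saddle - max(f[lo], f[hi]),
       minima = surface@axes[[1L]]$mids[locmin])
}

## 8-connected neighbours of linear index v on an nx x ny grid
.gridNeighbours <- function(v, nx, ny) {
  i <- ((v - 1L) %% nx) + 1L
  j <- ((v - 1L) %/% nx) + 1L
  out <- integer()
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0L && dj == 0L) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny)
      out <- c(out, (jj - 1L) * nx + ii)
  }
  out
}

#' Minimal-energy path across a free-energy surface
#'
#' The path between two bins that minimizes the maximum free energy
#' encountered (the bottleneck-optimal path) over 8-connected grid moves
#' through unmasked bins; among bottleneck-optimal paths, ties are broken
#' by the smaller total F along the path, then lexicographically on the
#' bin sequence, so the result is deterministic.  This is the dashed
#' "minimal energy path" construction for 2D folding surfaces.
#'
#' @param surface a 2D \linkS4class{FESurface} (1D vectors also work:
#'   treated as an n x 1 grid).
#' @param startBin,endBin integer pairs (row, col) of the two endpoint
#'   bins (1-based, rows = first axis); both must be unmasked.
#' @return list: \code{path} (matrix of (row, col) per step),
#'   \code{bottleneck} (max F on the path), \code{totalF}.
#' @export
minimalEnergyPath <- function(surface, startBin, endBin) {
  f <- surface@F
  if (!is.matrix(f)) f <- matrix(f, ncol = 1L)
  mask <- surface@mask
  if (!is.matrix(mask)) mask <- matrix(mask, ncol = 1L)
  nx <- nrow(f); ny <- ncol(f)
  toLin <- function(b) (b[2L] - 1L) * nx + b[1L]
  s <- toLin(startBin); e <- toLin(endBin)
  if (mask[startBin[1L], startBin[2L]] || mask[endBin[1L], endBin[2L]])
    stop("start or end bin is masked")
  fv <- as.numeric(f)
  open <- !as.numeric(mask)

  # --- stage 1: minimal bottleneck value (minimax Dijkstra) -----------
  n <- nx * ny
  bot <- rep(Inf, n); bot[s] <- fv[s]
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(bot))
    if (!length(cand)) break
    v <- cand[which.min(bot[cand])]
    done[v] <- TRUE
    if (v == e) break
    for (w in .gridNeighbours(v, nx, ny)) {
      if (!open[w] || done[w]) next
      nb <- max(bot[v], fv[w])
      if (nb < bot[w]) bot[w] <- nb
    }
  }
  if (!is.finite(bot[e]))
    stop("no connected path through unmasked bins")
  B <- bot[e] + 1e-12

  # --- stage 2: min total F restricted to bins with F <= B ------------
  ok <- open & fv <= B
  dist <- rep(Inf, n); dist[s] <- fv[s]
  paths <- vector("list", n); paths[[s]] <- s
  done <- rep(FALSE, n)
  lexLess <- function(a, b) {
    k <- min(length(a), length(b))
    for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    # among equal-dist candidates pick lexicographically smallest path
    eq <- cand[abs(dist[cand] - dist[v]) < 1e-12]
    if (length(eq) > 1L)
      for (u in eq) if (lexLess(paths[[u]], paths[[v]])) v <- u
    done[v] <- TRUE
    if (v == e) break
    for (w in .gridNeighbours(v, nx, ny)) {
      if (!ok[w] || done[w]) next
      nd <- dist[v] + fv[w]
      np <- c(paths[[v]], w)
      if (nd < dist[w] - 1e-12 ||
          (abs(nd - dist[w]) <= 1e-12 && lexLess(np, paths[[w]]))) {
        dist[w] <- nd
        paths[[w]] <- np
      }
    }
  }
  lin <- paths[[e]]
  path <- cbind(row = ((lin - 1L) %% nx) + 1L,
                col = ((lin - 1L) %/% nx) + 1L)
  list(path = path, bottleneck = max(fv[lin]), totalF = sum(fv[lin]))
}

#' Per-state loop-distance distributions
#'
#' Normalized densities of the loop distance separately for the folded and
#' unfolded sub-ensembles (histogram densities; each integrates to 1 over
#' its bins).  Empty sub-ensembles are omitted with a warning.
#'
#' @param loop numeric loop distances per frame.
#' @param labels classification factor from \code{\link{classifyState}}.
#' @param binWidth histogram bin width, Angstrom (default 0.5).
#' @return named list (\code{folded}, \code{unfolded} as available) of
#'   data.frames with \code{mid} and \code{density}.
#' @export
loopDistanceDistributions <- function(loop, labels, binWidth = 0.5) {
  stopifnot(length(loop) == length(labels))
  breaks <- .makeBreaks(loop, list(width = binWidth))
  out <- list()
  for (st in c("folded", "unfolded")) {
    v <- loop[labels == st]
    if (!length(v)) {
      warning("no ", st, " frames; density omitted")
      next
    }
    idx <- .binIndex(v, breaks)
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    dens <- counts / (sum(counts) * binWidth)
    out[[st]] <- data.frame(
      mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
      density = dens)
  }
  out
}

#' Plot a free-energy surface
#'
#' 1D profiles as lines over bin centres; 2D surfaces as filled images
#' with contours at every kT (masked bins blank).
#'
#' @param x an \linkS4class{FESurface}.
#' @param y ignored.
#' @param ... passed to the underlying plot call.
#' @export
setMethod("plot", signature(x = "FESurface", y = "missing"),
  function(x, y, ...) {
  if (is.matrix(x@F)) {
    graphics::image(x@axes[[1L]]$mids, x@axes[[2L]]$mids, x@F,
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                    xlab = x@axes[[1L]]$name, ylab = x@axes[[2L]]$name, ...)
    graphics::contour(x@axes[[1L]]$mids, x@axes[[2L]]$mids, x@F,
                      levels = x@contourLevels, add = TRUE)
  } else {
    graphics::plot(x@axes[[1L]]$mids[!x@mask], x@F[!x@mask], type = "b",
                   xlab = x@axes[[1L]]$name, ylab = "F", ...)
  }
  invisible(x)
})

#' Two-state barrier of an N_HB free-energy profile
#'
#' Height of the highest free-energy bin strictly between the unfolded
#' basin (minimum over bins with N_HB <= \code{unfoldedMax}) and the
#' folded basin (minimum over bins with N_HB >= \code{foldedMin}), above
#' the shallower of the two basins; clipped at 0.  A cooperative two-state
#' profile has a substantial positive barrier, a downhill profile has
#' none.
#'
#' @param surface 1D \linkS4class{FESurface} over integer N_HB bins.
#' @param foldedMin,unfoldedMax classification thresholds.
#' @return list: \code{barrier} (energy units of the surface),
#'   \code{unfoldedMin}, \code{foldedMin} (basin free energies),
#'   \code{saddle}.
#' @export
twoStateBarrier <- function(surface, foldedMin = 4L, unfoldedMax = 1L) {
  f <- surface@F
  stopifnot(!is.matrix(f))
  x <- surface@axes[[1L]]$mids
  fu <- f[!surface@mask & x <= unfoldedMax]
  ff <- f[!surface@mask & x >= foldedMin]
  if (!length(fu) || !length(ff))
    stop("profile does not cover both basins")
  iu <- which(x <= unfoldedMax & !surface@mask)
  iu <- iu[which.min(f[iu])]
  ifo <- which(x >= foldedMin & !surface@mask)
  ifo <- ifo[which.min(f[ifo])]
  lo <- min(iu, ifo); hi <- max(iu, ifo)
  between <- if (hi - lo >= 2L) f[(lo + 1L):(hi - 1L)] else numeric()
  saddle <- if (length(between)) max(between, na.rm = TRUE) else -Inf
  list(barrier = max(0, saddle - max(f[iu], f[ifo])),
       unfoldedMin = f[iu], foldedMin = f[ifo],
       saddle = if (is.finite(saddle)) saddle else NA_real_)
}
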