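## OPTICS density ordering and Xi cluster extraction (Ankerst et al.),
## implemented internally: reachability ordering via the standard
## smallest-reachability expansion with kNN core distances, followed by the
## steep-area Xi method (with the usual sign corrections for Definitions 9
## and 11; predecessor correction is not applied). Euclidean (Minkowski
## p = 2) metric. O(n^2), adequate for motif-set sizes.

#' OPTICS reachability ordering
#'
#' @param X numeric matrix (rows = points).
#' @param minSamples neighbourhood size for core distances (the point
#'   itself counts, as usual).
#' @param maxEps maximum neighbourhood radius (default Inf).
#' @return List with `order` (visit order, 1-based point indices),
#'   `reachability` (per point, Inf for seeds / unreachable) and
#'   `coreDist` (per point).
#' @export
opticsOrdering <- function(X, minSamples = 20L, maxEps = Inf) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < minSamples)
    stop(sprintf("need at least minSamples = %d points, got %d", minSamples, n))
  D <- as.matrix(stats::dist(X))
  coreDist <- apply(D, 1L, function(r) sort(r, partial = minSamples)[minSamples])
  coreDist[coreDist > maxEps] <- Inf
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  for (step in seq_len(n)) {
    idx <- which(!processed)
    p <- idx[which.min(reach[idx])]   # ties: smallest index
    processed[p] <- TRUE
    ord[step] <- p
    if (is.finite(coreDist[p])) {
      un <- which(!processed)
      if (length(un)) {
        d <- D[p, un]
        ok <- d <= maxEps
        if (any(ok)) {
          newReach <- pmax(coreDist[p], d[ok])
          upd <- newReach < reach[un[ok]]
          reach[un[ok][upd]] <- newReach[upd]
        }
      }
    }
  }
  list(order = ord, reachability = reach, coreDist = coreDist)
}

## Extend a steep region (shared for up/down): a region may contain at most
## minSamples consecutive non-steep points that still move in the region's
## direction, and ends at the last steep point.
extendRegion <- function(steep, xward, start, minSamples, n) {
  nonXward <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep[index]) {
      nonXward <- 0L
      end <- index
    } else if (!xward[index]) {
      nonXward <- nonXward + 1L
      if (nonXward > minSamples) break
    } else {
      return(end)
    }
    index <- index + 1L
  }
  end
}

## Xi cluster extraction on a reachability plot (values in visit order).
## Returns a matrix of [start, end] index pairs (inclusive, plot order),
## smaller (nested) clusters before the larger ones containing them.
xiClusters <- function(rplot, xi, minSamples, minClusterSize) {
  r <- c(rplot, Inf)
  n <- length(rplot)
  comp <- 1 - xi
  ratio <- r[seq_len(n)] / r[seq_len(n) + 1L]
  ratio[is.nan(ratio)] <- 1
  steepUp <- ratio <= comp
  steepDown <- ratio >= 1 / comp
  up <- ratio < 1
  down <- ratio > 1
  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  filterSdas <- function(sdas, mib) {
    if (is.infinite(mib)) return(list())
    keep <- Filter(function(s) mib <= r[s$start] * comp, sdas)
    lapply(keep, function(s) { s$mib <- max(s$mib, mib); s })
  }
  for (si in which(steepUp | steepDown)) {
    if (si < index) next
    mib <- max(mib, max(r[index:si]))
    if (steepDown[si]) {
      sdas <- filterSdas(sdas, mib)
      dEnd <- extendRegion(steepDown, up, si, minSamples, n)
      sdas[[length(sdas) + 1L]] <- list(start = si, end = dEnd, mib = 0)
      index <- dEnd + 1L
      mib <- r[index]
    } else {
      sdas <- filterSdas(sdas, mib)
      uStart <- si
      uEnd <- extendRegion(steepUp, down, si, minSamples, n)
      index <- uEnd + 1L
      mib <- r[index]
      uClusters <- list()
      for (D in sdas) {
        cStart <- D$start
        cEnd <- uEnd
        if (r[cEnd + 1L] * comp < D$mib) next
        dMax <- r[D$start]
        if (dMax * comp >= r[cEnd + 1L]) {
          while (r[cStart + 1L] > r[cEnd + 1L] && cStart < D$end)
            cStart <- cStart + 1L
        } else if (r[cEnd + 1L] * comp >= dMax) {
          while (cEnd > uStart && r[cEnd - 1L] > dMax)
            cEnd <- cEnd - 1L
        }
        if (cEnd - cStart + 1L < minClusterSize) next
        if (cStart > D$end) next
        if (cEnd < uStart) next
        uClusters[[length(uClusters) + 1L]] <- c(cStart, cEnd)
      }
      clusters <- c(clusters, rev(uClusters))
    }
  }
  if (!length(clusters)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, clusters)
}

#' OPTICS/Xi clustering
#'
#' Density-based clustering of a numeric embedding: OPTICS reachability
#' ordering followed by Xi cluster extraction. Points in no extracted leaf
#' cluster are labeled noise (-1); cluster labels are dense integers from 0
#' in order of extraction (innermost clusters win, as leaf clusters are
#' assigned first).
#'
#' @param X numeric matrix (rows = points).
#' @param minSamples core-point neighbourhood size (default 20).
#' @param xi minimum relative steepness of a cluster boundary (default
#'   0.05).
#' @param minClusterSize minimum cluster size (defaults to `minSamples`).
#' @param maxEps maximum neighbourhood radius (default Inf).
#' @return List with `labels` (per input point, -1 = noise), `order`,
#'   `reachability` and the extracted `clusters` intervals.
#' @export
opticsXi <- function(X, minSamples = 20L, xi = 0.05,
                     minClusterSize = minSamples, maxEps = Inf) {
  og <- opticsOrdering(X, minSamples, maxEps)
  rplot <- og$reachability[og$order]
  cl <- xiClusters(rplot, xi, minSamples, minClusterSize)
  labInOrder <- rep(-1L, length(og$order))
  lab <- 0L
  if (nrow(cl)) {
    for (k in seq_len(nrow(cl))) {
      span <- cl[k, 1L]:cl[k, 2L]
      if (all(labInOrder[span] == -1L)) {
        labInOrder[span] <- lab
        lab <- lab + 1L
      }
    }
  }
  labels <- integer(length(og$order))
  labels[og$order] <- labInOrder
  list(labels = labels, order = og$order, reachability = og$reachability,
       clusters = cl)
}
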