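## From per-residue probabilities to motif calls, domain layout validation,
## LRR ladder delineation and NLR classification.

#' Call motifs from a per-residue probability vector
#'
#' A call is made at every local probability maximum strictly above the
#' threshold (the 80% rule: a probability of exactly 0.80 is not called).
#' A local maximum is a position whose probability is at least that of both
#' neighbours; on a plateau of equal values only the leftmost position is
#' called.
#'
#' @param probs numeric vector of per-residue probabilities.
#' @param seqid sequence id recorded in the calls.
#' @param motif motif name recorded in the calls.
#' @param threshold call threshold (default 0.80, strict inequality).
#' @return data.frame with columns `seqid`, `motif`, `start` (0-based),
#'   `prob`.
#' @export
callMotifs <- function(probs, seqid = "query", motif, threshold = 0.80) {
  n <- length(probs)
  if (n == 0L) return(emptyCalls())
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  left <- c(-Inf, probs[-n])
  right <- c(probs[-1L], -Inf)
  isMax <- probs >= left & probs >= right & probs > left  # leftmost on plateaus
  hit <- which(isMax & probs > threshold)
  if (!length(hit)) return(emptyCalls())
  data.frame(seqid = seqid, motif = motif, start = hit - 1L,
             prob = probs[hit], stringsAsFactors = FALSE)
}

#' Resolve satellite motif calls
#'
#' Nearby alternative calls of the same motif ("satellites") closer than
#' `window` residues are resolved: when the probability difference within a
#' conflicting pair exceeds `margin`, only the higher-probability call
#' survives; otherwise both are kept and flagged ambiguous. The operation
#' is idempotent.
#'
#' @param calls motif-call data.frame (one motif class; multiple sequences
#'   allowed, conflicts are resolved per sequence).
#' @param window conflict distance in residues (default 15).
#' @param margin probability margin that resolves a conflict (default
#'   0.20, strict: a difference of exactly 0.20 is ambiguous).
#' @return The surviving calls with an added logical column `ambiguous`.
#' @export
resolveSatellites <- function(calls, window = 15L, margin = 0.20) {
  calls <- as.data.frame(calls)
  if (!nrow(calls)) { calls$ambiguous <- logical(0); return(calls) }
  if (length(unique(calls$motif)) > 1L)
    stop("resolveSatellites expects calls of a single motif class")
  out <- lapply(split(calls, calls$seqid), function(cs) {
    cs <- cs[order(cs$start), , drop = FALSE]
    conflictPairs <- function(cs) {
      ij <- which(abs(outer(cs$start, cs$start, "-")) < window &
                    upper.tri(matrix(0, nrow(cs), nrow(cs))),
                  arr.ind = TRUE)
      ij
    }
    repeat {
      ij <- conflictPairs(cs)
      if (!nrow(ij)) break
      dp <- abs(cs$prob[ij[, 1L]] - cs$prob[ij[, 2L]])
      live <- dp > margin + 1e-12
      if (!any(live)) break
      k <- which(live)[which.max(dp[live])]
      pair <- ij[k, ]
      drop <- pair[which.min(cs$prob[pair])]
      cs <- cs[-drop, , drop = FALSE]
    }
    amb <- rep(FALSE, nrow(cs))
    ij <- conflictPairs(cs)
    if (nrow(ij)) amb[unique(as.vector(ij))] <- TRUE
    cs$ambiguous <- amb
    cs
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$seqid, res$start), , drop = FALSE]
}

#' Validate the NBS domain layout
#'
#' A sequence has a valid NBS layout when each of the nine NBS motifs is
#' called exactly once and their starts increase in the canonical order
#' VG < P-loop < RNBS-A < Walker-B < RNBS-B < RNBS-C < GLPL < RNBS-D < MHD.
#' Invalid layouts are returned with machine-readable reason codes
#' (`missing:X`, `duplicated:X`, `disordered:X|Y`).
#'
#' @param calls motif-call data.frame for one sequence (non-NBS motifs are
#'   ignored).
#' @param registry a [MotifRegistry-class].
#' @return List with `valid`, `reasons`, `calls` (the NBS calls in
#'   positional order) and `motifOrder` (the canonical order used).
#' @export
validateNbsLayout <- function(calls, registry = defaultRegistry()) {
  d <- registryTable(registry)
  nbs <- d[d$domain == "NBS", ]
  nbs <- nbs[order(nbs$order_index), ]
  calls <- as.data.frame(calls)
  calls <- calls[calls$motif %in% nbs$name, , drop = FALSE]
  tag <- function(prefix, v) if (length(v)) paste0(prefix, v) else character(0)
  counts <- table(factor(calls$motif, levels = nbs$name))
  reasons <- c(tag("missing:", names(counts)[counts == 0L]),
               tag("duplicated:", names(counts)[counts > 1L]))
  if (all(counts == 1L)) {
    starts <- calls$start[match(nbs$name, calls$motif)]
    bad <- which(diff(starts) <= 0L)
    reasons <- c(reasons,
                 tag("disordered:", paste0(nbs$name[bad], "|",
                                           nbs$name[bad + 1L])[seq_along(bad)]))
  }
  list(valid = length(reasons) == 0L, reasons = reasons,
       calls = calls[order(calls$start), , drop = FALSE],
       motifOrder = nbs$name)
}

#' Delineate the LRR repeat ladder
#'
#' Accepts a ladder of LxxLxL starts when (a) the LRR domain begins within
#' `maxLinker` residues of the end of the NBS MHD motif (linker rule,
#' applied when a valid NBS annotation is supplied), (b) every distance
#' between consecutive accepted starts lies within `[minLen, maxLen]`
#' (the last repeat is open-ended) and (c) at least `minRepeats` starts
#' remain (9 for LRR-domain analysis, 5 for the CNL interdomain analysis).
#'
#' @param calls satellite-resolved LxxLxL calls for one sequence.
#' @param nbsAnnotation result of [validateNbsLayout()], or NULL to skip
#'   the linker rule.
#' @param minRepeats minimum accepted ladder size (default 9).
#' @param maxLinker maximal NBS-to-LRR linker (default 50, strict: a
#'   linker of 50 is rejected).
#' @param minLen,maxLen accepted repeat length range (default 15-50).
#' @param registry registry supplying the MHD motif length.
#' @return List with `accepted`, `reason` (NULL when accepted), `starts`
#'   (0-based), `repeatLengths` (distances between consecutive starts) and
#'   `ladderIndex` (1..n per accepted repeat).
#' @export
delineateLrrLadder <- function(calls, nbsAnnotation = NULL, minRepeats = 9L,
                               maxLinker = 50L, minLen = 15L, maxLen = 50L,
                               registry = defaultRegistry()) {
  calls <- as.data.frame(calls)
  calls <- calls[calls$motif == "LxxLxL", , drop = FALSE]
  starts <- sort(unique(calls$start))
  reject <- function(reason) list(accepted = FALSE, reason = reason,
                                  starts = starts,
                                  repeatLengths = diff(starts),
                                  ladderIndex = integer(0))
  if (!is.null(nbsAnnotation)) {
    if (!isTRUE(nbsAnnotation$valid))
      return(reject("invalid-nbs"))
    mhd <- nbsAnnotation$calls
    mhdEnd <- mhd$start[mhd$motif == "MHD"] +
      motifDefinition(registry, "MHD")$length
    starts <- starts[starts >= mhdEnd]
    if (!length(starts)) return(reject("no-repeats-downstream"))
    linker <- starts[1L] - mhdEnd
    if (linker >= maxLinker) return(reject("linker"))
  }
  if (length(starts) < minRepeats) return(reject("too-few-repeats"))
  d <- diff(starts)
  if (any(d < minLen))
    return(reject(sprintf("short-repeat:%d", which(d < minLen)[1L])))
  if (any(d > maxLen))
    return(reject(sprintf("long-repeat:%d", which(d > maxLen)[1L])))
  list(accepted = TRUE, reason = NULL, starts = starts,
       repeatLengths = d, ladderIndex = seq_along(starts))
}

#' Classify an NLR sequence from its domain annotation
#'
#' Applies the N-terminal evidence on top of a validated NBS layout: TNL
#' when all six TIR motifs are called, in canonical order, upstream of the
#' NBS; CNL when an extended-EDVID call lies upstream of the NBS; NL when
#' only the valid NBS (with or without an LRR ladder) is present; `other`
#' otherwise. TIR evidence takes precedence when both fire (flagged
#' `both-cc-tir`); N-terminal motifs found downstream of the NBS flag the
#' layout as shuffled and demote the class to `other`. RPW8-type RNLs have
#' no dedicated predictor and are not auto-classified.
#'
#' @param calls satellite-resolved calls for one sequence (all motifs).
#' @param registry a [MotifRegistry-class].
#' @param ladder optional result of [delineateLrrLadder()], recorded as
#'   evidence.
#' @return List with `class` (one of CNL, TNL, NL, other), `evidence` and
#'   `flags`.
#' @export
classifyNlr <- function(calls, registry = defaultRegistry(), ladder = NULL) {
  calls <- as.data.frame(calls)
  nbs <- validateNbsLayout(calls, registry)
  flags <- character(0)
  evidence <- list(nbs = nbs, ladder = ladder)
  if (!nbs$valid)
    return(list(class = "other", evidence = evidence,
                flags = c(flags, "invalid-nbs")))
  nbsStart <- min(nbs$calls$start)
  tirNames <- motifNames(registry, "TIR")
  tir <- calls[calls$motif %in% tirNames, , drop = FALSE]
  tirCounts <- table(factor(tir$motif, levels = tirNames))
  tirStarts <- tir$start[match(tirNames, tir$motif)]
  tirComplete <- all(tirCounts == 1L) &&
    !is.unsorted(tirStarts, strictly = TRUE) &&
    max(tirStarts) < nbsStart
  edvid <- calls[calls$motif == "EDVID", , drop = FALSE]
  edvidUp <- nrow(edvid) > 0L && any(edvid$start < nbsStart)
  shuffled <- (nrow(edvid) > 0L && all(edvid$start >= nbsStart)) ||
    (nrow(tir) > 0L && !tirComplete && all(tirStarts >= nbsStart, na.rm = TRUE) &&
       any(!is.na(tirStarts)))
  evidence$tirComplete <- tirComplete
  evidence$edvidUpstream <- edvidUp
  if (tirComplete) {
    if (edvidUp) flags <- c(flags, "both-cc-tir")
    return(list(class = "TNL", evidence = evidence, flags = flags))
  }
  if (edvidUp)
    return(list(class = "CNL", evidence = evidence, flags = flags))
  if (shuffled)
    return(list(class = "other", evidence = evidence,
                flags = c(flags, "shuffled")))
  list(class = "NL", evidence = evidence, flags = flags)
}

#' Consensus-pattern scoring backend
#'
#' Degenerate probability backend used for rule testing and noise-free
#' pipelines: every window conforming to the motif consensus scores 1,
#' every other position 0. It exercises the identical
#' call/satellite/layout/classification path as the MLP backend.
#'
#' @param seq sequence (character or `AAString`).
#' @param def motif definition with a consensus pattern.
#' @return Numeric vector, one probability per residue.
#' @export
consensusProbabilities <- function(seq, def) {
  seq <- asResidueString(seq)
  p <- numeric(nchar(seq))
  hits <- consensusScan(seq, def)
  p[hits + 1L] <- 1
  p
}
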