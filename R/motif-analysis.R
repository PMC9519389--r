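## Downstream motif analytics: excised-motif chimeras, identity clustering,
## relative-entropy conservation profiles, the physico-chemical LRR
## embedding and its OPTICS clustering, and ladder-position distributions.

#' Excise a motif chimera from a sequence
#'
#' Extracts each requested motif with `flank` residues on both sides and
#' concatenates the segments in registry order. Flanks running past the
#' sequence ends are padded with X. Chimeras built from the same motif set
#' all share one layout (length = sum of motif lengths + 2 * flank each),
#' which makes identity comparison an ungapped column-wise match.
#'
#' @param seq sequence (character or `AAString`).
#' @param annotation motif-call or annotation data.frame for this sequence
#'   with columns `motif` and `start` (0-based); each requested motif must
#'   occur exactly once.
#' @param motifs motif names to excise, e.g. the 9 NBS motifs, 6 TIR + 9
#'   NBS, or EDVID + 9 NBS + first 5 LRR. Order is normalised to registry
#'   order (CC, TIR, NBS, then LRR by position).
#' @param flank flank width (default 5).
#' @param registry a [MotifRegistry-class].
#' @return List (class fields): `chimera` (string), `boundaries` (0-based
#'   segment starts plus final end; length = number of segments + 1) and
#'   `segments` (named per-motif strings).
#' @export
exciseChimera <- function(seq, annotation, motifs = NULL,
                          flank = 5L, registry = defaultRegistry()) {
  seq <- asResidueString(seq)
  ann <- as.data.frame(annotation)
  d <- registryTable(registry)
  if (is.null(motifs)) motifs <- unique(ann$motif)
  unknown <- setdiff(motifs, d$name)
  if (length(unknown)) stop(sprintf("unknown motifs: %s",
                                    paste(unknown, collapse = ", ")))
  ## registry order: domain blocks CC < TIR < NBS < LRR, canonical order
  ## inside TIR/NBS, LRR repeats by start position.
  ann <- ann[ann$motif %in% motifs, , drop = FALSE]
  cnt <- table(ann$motif)
  lrr <- ann[ann$motif == "LxxLxL", , drop = FALSE]
  nonLrr <- setdiff(motifs, "LxxLxL")
  if (any(!nonLrr %in% names(cnt)) || any(cnt[nonLrr] != 1L))
    stop("annotation must contain each requested non-LRR motif exactly once")
  ord <- d[match(nonLrr, d$name), ]
  ord <- ord[order(match(ord$domain, c("CC", "TIR", "NBS")),
                   ifelse(is.na(ord$order_index), 0L, ord$order_index)), ]
  rows <- ann[match(ord$name, ann$motif), , drop = FALSE]
  if ("LxxLxL" %in% motifs && nrow(lrr))
    rows <- rbind(rows, lrr[order(lrr$start), , drop = FALSE])
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  segs <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    L <- d$length[match(rows$motif[i], d$name)]
    idx <- (rows$start[i] - flank):(rows$start[i] + L + flank - 1L)
    piece <- rep("X", length(idx))
    ok <- idx >= 0L & idx < n
    piece[ok] <- chars[idx[ok] + 1L]
    segs[i] <- paste(piece, collapse = "")
  }
  segNames <- rows$motif
  if (any(duplicated(segNames)))
    segNames <- make.unique(segNames, sep = "#")
  names(segs) <- segNames
  list(chimera = paste(segs, collapse = ""),
       boundaries = c(0L, cumsum(nchar(segs))),
       segments = segs)
}

#' Cluster fixed-layout chimeras by sequence identity
#'
#' Pairwise identity between equal-length chimeras is the fraction of
#' matching columns (ungapped comparison; the fixed layout makes alignment
#' unnecessary). Sequences are connected when identity reaches the
#' threshold and clusters are the connected components of that graph, so a
#' cluster can span pairs below the threshold through intermediates.
#'
#' @param chimeras named character vector of equal-length chimera strings
#'   (or a list of [exciseChimera()] results with one shared layout).
#' @param threshold identity threshold in `[0, 1]` (edges at identity >=
#'   threshold).
#' @return List with `labels` (dense integer cluster ids from 0, named by
#'   sequence) and `identity` (the pairwise identity matrix).
#' @export
clusterByIdentity <- function(chimeras, threshold = 0.55) {
  if (is.list(chimeras) && !is.null(chimeras[[1L]]$chimera)) {
    lay <- vapply(chimeras, function(x) paste(x$boundaries, collapse = ","), "")
    if (length(unique(lay)) != 1L) stop("chimeras have mixed layouts")
    chimeras <- vapply(chimeras, `[[`, "", "chimera")
  }
  if (length(chimeras) < 2L) stop("need at least 2 chimeras")
  if (length(unique(nchar(chimeras))) != 1L)
    stop("chimeras have mixed layouts")
  m <- asAlignmentMatrix(chimeras)
  n <- nrow(m)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    idm[i, j] <- idm[j, i] <- mean(m[i, ] == m[j, ])
  adj <- idm >= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership - 1L
  ids <- names(chimeras)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  names(comp) <- ids
  dimnames(idm) <- list(ids, ids)
  list(labels = comp, identity = idm)
}

#' Per-column relative entropy of an alignment
#'
#' Conservation profile of equal-length motif windows or chimeras:
#' RE(c) = sum_a f_a(c) log2(f_a(c) / q_a) against the background q
#' (BLOSUM62 marginals). X and gaps are excluded from the column counts.
#' Always non-negative; 0 for a column matching the background exactly.
#'
#' @param seqs equal-length character vector, `AAStringSet`, or character
#'   matrix.
#' @return Numeric vector of per-column relative entropies (bits).
#' @export
columnRelativeEntropy <- function(seqs) {
  m <- asAlignmentMatrix(seqs)
  apply(m, 2L, function(col) {
    col <- col[col %in% AA20]
    if (!length(col)) return(0)
    f <- table(factor(col, levels = AA20)) / length(col)
    f <- as.numeric(f)
    keep <- f > 0
    sum(f[keep] * log2(f[keep] / BLOSUM62_BG[keep]))
  })
}

#' Sequence-logo matrix
#'
#' Per-column letter heights in bits: the residue frequency scaled by the
#' column relative entropy, the usual logo representation. Written as a
#' position x amino-acid TSV consumable by logo plotting tools.
#'
#' @param seqs equal-length sequences (as in [columnRelativeEntropy()]).
#' @param path optional TSV output path.
#' @return Numeric matrix, positions x 20 amino acids (bits).
#' @export
logoMatrix <- function(seqs, path = NULL) {
  m <- asAlignmentMatrix(seqs)
  re <- columnRelativeEntropy(m)
  heights <- t(apply(m, 2L, function(col) {
    col <- col[col %in% AA20]
    if (!length(col)) return(stats::setNames(numeric(20L), AA20))
    as.numeric(table(factor(col, levels = AA20))) / length(col)
  }))
  colnames(heights) <- AA20
  heights <- heights * re
  if (!is.null(path)) {
    out <- data.frame(position = seq_len(nrow(heights)), heights,
                      check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  heights
}

#' Physico-chemical embedding of LxxLxL motif windows
#'
#' Maps each 6-residue LRR motif window to an 18-dimensional descriptor:
#' for each of the six positions the Kyte-Doolittle hydropathy, the formal
#' side-chain charge (K/R = +1, D/E = -1, H = +0.1) and the Zamyatnin
#' residue volume. X residues receive the mean of each descriptor.
#' Features are z-scored across the dataset before clustering
#' (`standardize = TRUE`); constant features are left at 0.
#'
#' @param windows character vector of 6-mers.
#' @param standardize z-score each feature across the dataset.
#' @return Numeric matrix, rows = windows, 18 columns named
#'   `pos<i>_<hydropathy|charge|volume>`.
#' @export
lrrEmbedding <- function(windows, standardize = TRUE) {
  if (any(nchar(windows) != 6L))
    stop("LxxLxL windows must have length 6")
  m <- asAlignmentMatrix(windows)
  scales <- list(hydropathy = KYTE_DOOLITTLE, charge = AA_CHARGE,
                 volume = AA_VOLUME)
  out <- matrix(0, nrow = nrow(m), ncol = 18L)
  cn <- character(18L)
  k <- 0L
  for (pos in 1:6) {
    for (s in names(scales)) {
      k <- k + 1L
      v <- scales[[s]][m[, pos]]
      v[is.na(v)] <- mean(scales[[s]])   # X residues
      out[, k] <- v
      cn[k] <- sprintf("pos%d_%s", pos, s)
    }
  }
  colnames(out) <- cn
  rownames(out) <- names(windows)
  if (standardize) {
    mu <- colMeans(out)
    sd <- apply(out, 2L, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    out <- scale(out, center = mu, scale = sd)
    attr(out, "scaled:center") <- mu
    attr(out, "scaled:scale") <- sd
  }
  out
}

#' Cluster LRR motifs in physico-chemical space
#'
#' OPTICS with Xi extraction (Euclidean metric) over the 18-dimensional
#' embedding from [lrrEmbedding()]. Noise points are labeled -1.
#'
#' @param embeddings numeric matrix from [lrrEmbedding()] (or any numeric
#'   embedding).
#' @param minSamples OPTICS neighbourhood size (default 20).
#' @param xi Xi steepness (default 0.05).
#' @param maxEps maximum neighbourhood radius (default Inf).
#' @return List as returned by [opticsXi()].
#' @export
clusterLrrMotifs <- function(embeddings, minSamples = 20L, xi = 0.05,
                             maxEps = Inf) {
  opticsXi(as.matrix(embeddings), minSamples = minSamples, xi = xi,
           maxEps = maxEps)
}

#' Cluster occupancy along the LRR ladder
#'
#' Cross-tabulates motif cluster labels against ladder positions and
#' normalises vertically: each ladder-position column sums to 100% over
#' the clusters (noise included). Ladder positions beyond `maxPos` are
#' pooled into an `N+` column.
#'
#' @param labels integer cluster labels (-1 = noise), one per motif.
#' @param ladderPos integer ladder index (1..n) per motif.
#' @param maxPos last individual ladder position; later positions pool
#'   into `N+` (default 20).
#' @return Numeric matrix, clusters x ladder positions, percentages; every
#'   column sums to 100.
#' @export
ladderDistribution <- function(labels, ladderPos, maxPos = 20L) {
  stopifnot(length(labels) == length(ladderPos))
  if (any(is.na(ladderPos)) || any(ladderPos < 1L))
    stop("every motif needs a ladder index >= 1")
  posF <- ifelse(ladderPos > maxPos, "N+", as.character(ladderPos))
  posLevels <- c(as.character(seq_len(maxPos)), "N+")
  posLevels <- posLevels[posLevels %in% posF]
  tab <- table(factor(labels), factor(posF, levels = posLevels))
  pct <- sweep(tab, 2L, colSums(tab), "/") * 100
  as.matrix(unclass(pct))
}
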