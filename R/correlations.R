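## Column-pair coevolution analysis over concatenated motif alignments:
## Henikoff-weighted mutual information with profile-based pseudocounts,
## empirical Z-score filtering, cumulative and proximity summaries.

#' Position-based Henikoff sequence weights
#'
#' Per-sequence weights over an equal-length alignment: each column
#' contributes 1/(r * s) to the rows carrying a residue, where r is the
#' number of distinct residues in the column and s the multiplicity of the
#' row's residue; row weights are normalised to sum to 1. Redundant rows
#' are down-weighted. X and gaps contribute nothing.
#'
#' @param alignment character vector of equal-length rows, `AAStringSet`,
#'   or a character matrix.
#' @return Numeric weights summing to 1.
#' @export
henikoffWeights <- function(alignment) {
  m <- asAlignmentMatrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 alignment rows")
  henikoffWeightsMatrix(m)
}

#' Henikoff-weighted mutual information between alignment columns
#'
#' For every column pair (i, j), MI = sum_ab p_ij(a,b) ln(p_ij(a,b) /
#' (p_i(a) p_j(b))), where joint probabilities are weighted residue-pair
#' counts smoothed with profile-based pseudocounts: `pseudocountMass` units
#' distributed proportionally to the product of the columns' substitution
#' profiles g_i(a) = sum_b f_i(b) P(a|b) with P(a|b) the BLOSUM62
#' conditional. Gaps and X are excluded from counts (probabilities are
#' renormalised over rows valid at both positions). Columns with zero
#' effective counts yield MI 0 and are flagged.
#'
#' @param alignment equal-length rows (vector, `AAStringSet`, matrix).
#' @param weights per-row weights; defaults to [henikoffWeights()].
#' @param pseudocountMass total pseudocount mass per pair (default 1; 0
#'   disables smoothing).
#' @return List (`MIResult`): `mi` (symmetric matrix, diagonal NA),
#'   `weights`, `flags` (flagged columns).
#' @export
weightedMutualInformation <- function(alignment, weights = NULL,
                                      pseudocountMass = 1) {
  m <- asAlignmentMatrix(alignment)
  if (is.null(weights)) weights <- henikoffWeightsMatrix(m)
  if (length(weights) != nrow(m)) stop("one weight per alignment row needed")
  if (any(weights <= 0)) stop("weights must be positive")
  weights <- weights / sum(weights)
  n <- ncol(m)
  idx <- matrix(match(m, AA20), nrow(m), n)      # NA for X/gap
  cond <- blosum62Conditional()
  ## per-column weighted frequencies and substitution profiles
  freq <- matrix(0, 20L, n)
  for (j in seq_len(n)) {
    ok <- !is.na(idx[, j])
    if (any(ok)) {
      f <- tapply(weights[ok], idx[ok, j], sum)
      freq[as.integer(names(f)), j] <- f
    }
  }
  tot <- colSums(freq)
  flagged <- which(tot == 0)
  prof <- cond %*% sweep(freq, 2L, pmax(tot, .Machine$double.eps), "/")
  mi <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(idx[, i]) & !is.na(idx[, j])
      if (!any(ok) || i %in% flagged || j %in% flagged) {
        mi[i, j] <- mi[j, i] <- 0
        next
      }
      w <- weights[ok]
      joint <- matrix(0, 20L, 20L)
      cell <- idx[ok, i] + (idx[ok, j] - 1L) * 20L
      agg <- tapply(w, cell, sum)
      joint[as.integer(names(agg))] <- agg
      W <- sum(w)
      p <- (joint + pseudocountMass * outer(prof[, i], prof[, j])) /
        (W + pseudocountMass)
      pi <- rowSums(p)
      pj <- colSums(p)
      nz <- p > 0
      mi[i, j] <- mi[j, i] <-
        sum(p[nz] * log(p[nz] / outer(pi, pj)[nz]))
    }
  }
  list(mi = mi, weights = weights, flags = flagged)
}

#' Z-scores and significant column pairs
#'
#' Standardises the off-diagonal MI values against their empirical mean and
#' standard deviation; pairs with Z at or above the cutoff (default 3.5)
#' are significant. A degenerate (constant) MI matrix yields no significant
#' pairs and a `degenerate` flag.
#'
#' @param miResult result of [weightedMutualInformation()].
#' @param cutoff minimal Z-score (default 3.5; boundary included).
#' @return The input list extended with `z` (matrix), `pairs` (data.frame
#'   `i`, `j`, `mi`, `z` with i < j) and `degenerate`.
#' @export
miZscores <- function(miResult, cutoff = 3.5) {
  mi <- miResult$mi
  n <- nrow(mi)
  ut <- upper.tri(mi)
  vals <- mi[ut]
  s <- stats::sd(vals)
  z <- matrix(NA_real_, n, n)
  degenerate <- is.na(s) || s == 0
  if (!degenerate) {
    z[ut] <- (mi[ut] - mean(vals)) / s
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
  }
  sig <- if (degenerate) integer(0) else which(ut & z >= cutoff, arr.ind = TRUE)
  pairs <- if (length(sig))
    data.frame(i = sig[, 1L], j = sig[, 2L],
               mi = mi[sig], z = z[sig])[order(-z[sig]), ]
  else data.frame(i = integer(0), j = integer(0),
                  mi = numeric(0), z = numeric(0))
  rownames(pairs) <- NULL
  c(miResult, list(z = z, pairs = pairs, cutoff = cutoff,
                   degenerate = degenerate))
}

#' Cumulative and proximity mutual information
#'
#' Cumulative MI of a column is the sum of its significant MI values;
#' proximity MI is the mean cumulative MI over the column's 3D contact
#' neighbours (requires a contact map; omitted otherwise).
#'
#' @param miResult result of [miZscores()].
#' @param contacts optional contact data.frame with columns `i`, `j`
#'   (1-based alignment positions).
#' @return List with `cumulative` (per column) and `proximity` (per
#'   column, NULL without contacts; NA for columns without neighbours).
#' @export
cumulativeProximityMi <- function(miResult, contacts = NULL) {
  if (is.null(miResult$pairs)) stop("run miZscores() first")
  n <- nrow(miResult$mi)
  cum <- numeric(n)
  p <- miResult$pairs
  for (r in seq_len(nrow(p))) {
    cum[p$i[r]] <- cum[p$i[r]] + p$mi[r]
    cum[p$j[r]] <- cum[p$j[r]] + p$mi[r]
  }
  prox <- NULL
  if (!is.null(contacts)) {
    contacts <- as.data.frame(contacts)
    if (any(contacts$i < 1L | contacts$i > n | contacts$j < 1L |
              contacts$j > n))
      stop("contact map references positions outside the alignment")
    prox <- rep(NA_real_, n)
    for (col in seq_len(n)) {
      nb <- unique(c(contacts$j[contacts$i == col],
                     contacts$i[contacts$j == col]))
      nb <- setdiff(nb, col)
      if (length(nb)) prox[col] <- mean(cum[nb])
    }
  }
  list(cumulative = cum, proximity = prox)
}

#' Partition significant pairs by 3D support
#'
#' Labels each significant pair `supported` when it appears in the contact
#' map, `unsupported` otherwise; pairs with an endpoint missing from the
#' position map are labeled `unmapped`.
#'
#' @param pairs significant-pair data.frame (`i`, `j`).
#' @param contacts contact data.frame (`i`, `j`) in reference coordinates.
#' @param offsetMap optional data.frame mapping alignment positions to
#'   reference coordinates (columns `pos`, `ref`); identity when NULL.
#' @return The pairs with an added `support` column.
#' @export
mapPairsToContacts <- function(pairs, contacts, offsetMap = NULL) {
  pairs <- as.data.frame(pairs)
  contacts <- as.data.frame(contacts)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cset <- if (nrow(contacts)) key(contacts$i, contacts$j) else character(0)
  mapPos <- function(p) {
    if (is.null(offsetMap)) return(p)
    offsetMap$ref[match(p, offsetMap$pos)]
  }
  ri <- mapPos(pairs$i)
  rj <- mapPos(pairs$j)
  support <- ifelse(is.na(ri) | is.na(rj), "unmapped",
                    ifelse(key(ri, rj) %in% cset, "supported",
                           "unsupported"))
  pairs$support <- as.character(support)
  pairs
}

#' Read a contact map
#'
#' Plain TSV with columns `i`, `j` and optionally `distance`; rows with
#' distance above `cutoff` are dropped and self-pairs removed.
#'
#' @param path TSV path.
#' @param cutoff distance cutoff (default 5 Angstrom).
#' @return data.frame with columns `i`, `j` (and `distance` if present).
#' @export
readContactMap <- function(path, cutoff = 5) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("i", "j") %in% names(tab)))
    stop("contact map needs columns i, j")
  if ("distance" %in% names(tab)) tab <- tab[tab$distance <= cutoff, ]
  tab <- tab[tab$i != tab$j, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Contacts from residue coordinates
#'
#' Builds a contact set from a per-residue coordinate table (columns
#' `pos`, `x`, `y`, `z`, e.g. C-beta positions) with a Euclidean distance
#' cutoff (default 5 Angstrom as a proxy for all-atom proximity).
#'
#' @param coords data.frame with `pos`, `x`, `y`, `z`.
#' @param cutoff distance cutoff.
#' @return data.frame with `i`, `j`, `distance` (i < j).
#' @export
contactsFromCoords <- function(coords, cutoff = 5) {
  coords <- as.data.frame(coords)
  D <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  sel <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  data.frame(i = coords$pos[sel[, 1L]], j = coords$pos[sel[, 2L]],
             distance = D[sel])
}
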