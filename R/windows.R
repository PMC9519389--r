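## Fixed-length per-candidate feature vectors.
##
## For a motif of length L with flank f (default 5), the window of a
## candidate start position covers positions [pos - f, pos + L + f) and the
## vector holds 20 x 2 x (f + L + f) = 40 * (L + 10) features: position
## major, then iteration (1, 2), then amino acid (alphabetical). Positions
## falling outside the sequence are padded with the background block, so
## every residue of a sequence is a scoreable candidate.

## The background feature block: -ln background frequency, repeated per
## iteration (40 values for the canonical 2-iteration features).
backgroundBlock <- function(iterations = 2L) {
  rep(unname(-log(BLOSUM62_BG)), iterations)
}

#' Window vector length for a motif
#'
#' @param def motif definition from [motifDefinition()].
#' @param flank flanking positions on each side (default 5).
#' @return `20 * 2 * (flank + L + flank)`, i.e. `40 * (L + 10)` at the
#'   default flank.
#' @export
#' @examples
#' reg <- defaultRegistry()
#' windowLength(motifDefinition(reg, "LxxLxL"))  # 640
windowLength <- function(def, flank = 5L) {
  40L * (def$length + 2L * flank)
}

#' Extract one candidate window
#'
#' @param features a [ProfileFeatures-class].
#' @param pos candidate start position, 0-based, in `[0, length)`.
#' @param def motif definition.
#' @param flank flanking positions (default 5).
#' @return Numeric vector of length `windowLength(def, flank)`.
#' @export
extractWindow <- function(features, pos, def, flank = 5L) {
  f <- features@features
  n <- nrow(f)
  if (pos < 0L || pos >= n) stop("pos out of range")
  bg <- backgroundBlock(ncol(f) / 20L)
  rows <- (pos - flank):(pos + def$length + flank - 1L)
  out <- matrix(bg, nrow = length(rows), ncol = ncol(f), byrow = TRUE)
  inside <- rows >= 0L & rows < n
  out[inside, ] <- f[rows[inside] + 1L, , drop = FALSE]
  as.vector(t(out))
}

#' Window vectors for every residue of a sequence
#'
#' Every position of the sequence is a candidate motif start; border
#' windows are background-padded.
#'
#' @inheritParams extractWindow
#' @return Numeric matrix, one row per position (0-based row `i` is
#'   candidate start `i - 1`), `windowLength(def, flank)` columns.
#' @export
enumerateCandidates <- function(features, def, flank = 5L) {
  f <- features@features
  n <- nrow(f)
  W <- def$length + 2L * flank
  bg <- backgroundBlock(ncol(f) / 20L)
  pad <- function(k) matrix(bg, nrow = k, ncol = ncol(f), byrow = TRUE)
  P <- rbind(pad(flank), f, pad(def$length + flank - 1L))
  out <- matrix(0, nrow = n, ncol = ncol(f) * W)
  for (j in seq_len(W))
    out[, (j - 1L) * ncol(f) + seq_len(ncol(f))] <-
      P[j:(j + n - 1L), , drop = FALSE]
  out
}
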