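## Small shared helpers.

## Evaluate `expr` under a fixed RNG seed without touching the caller's
## global RNG state. All exported generators funnel their randomness
## through this.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  expr
}

## Convert a character string of residues to an integer vector:
## 1..20 for the standard amino acids (alphabetical), 0 for X.
aaToInt <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

## Inverse of aaToInt (0 -> "X").
intToAa <- function(idx) {
  out <- rep("X", length(idx))
  ok <- idx >= 1L & idx <= 20L
  out[ok] <- AA20[idx[ok]]
  paste(out, collapse = "")
}

## Coerce an AAString/AAStringSet element or character scalar to a plain
## upper-case character string.
asResidueString <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet"))
    x <- as.character(x)
  toupper(as.character(x)[1L])
}

## Split sequences (character vector or AAStringSet) into a character matrix
## rows = sequences, cols = positions. All must share one length.
asAlignmentMatrix <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (is.matrix(x)) return(x)
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("sequences must all have the same length")
  do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
}

## Draw n residues from the background distribution.
sampleBackground <- function(n) {
  sample(AA20, n, replace = TRUE, prob = BLOSUM62_BG)
}

## BLOSUM62 scoring matrix restricted to the 20 standard residues in
## package order, as a plain numeric matrix (cached).
blosum62Matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      m <- get("BLOSUM62", envir = environment())
      cache <<- m[AA20, AA20]
    }
    cache
  }
})

## BLOSUM62 conditional substitution profile P(a | b), derived from the
## implied target frequencies q_ab ~ p_a p_b 2^(s_ab / 2) (half-bit scores).
## Columns are the observed residue b, rows the substituted residue a.
blosum62Conditional <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- blosum62Matrix()
      q <- outer(BLOSUM62_BG, BLOSUM62_BG) * 2^(s / 2)
      cache <<- sweep(q, 2, colSums(q), "/")
    }
    cache
  }
})
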