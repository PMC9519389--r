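## The motif registry: 17 motif classes over the four canonical NLR domains.

## Registry defaults. Consensus notation: specific residues are fixed
## anchors, 'b' is the hydrophobic class, 'x' is unconstrained. The CC,
## NBS and LRR consensi are the published patterns; the six TIR element
## consensi are synthetic stand-ins (the literature pins only the catalytic
## Glu/Cys of alphaC at positions 1/4 and the Phe/Pro of betaD-alphaD1 at
## positions 4/9; the remaining anchors are plausible invented defaults and
## the lengths are configuration).
REGISTRY_DEFAULTS <- data.frame(
  name = c("EDVID",
           "betaA", "alphaA", "betaC", "alphaC", "betaD-alphaD1", "alphaD3",
           "VG", "P-loop", "RNBS-A", "Walker-B", "RNBS-B", "RNBS-C",
           "GLPL", "RNBS-D", "MHD",
           "LxxLxL"),
  domain = c("CC", rep("TIR", 6L), rep("NBS", 9L), "LRR"),
  length = c(12L, 8L, 10L, 8L, 10L, 12L, 15L,
             6L, 9L, 7L, 11L, 7L, 10L, 4L, 9L, 3L, 6L),
  consensus = c("RDbbbDbEDbbD",
                "YDVFbSFR", "GEDTRxbFTx", "VbPbFYxV", "bExxCbGbbx",
                "WxbxFxxbxPxG", "bxxAbxEAAxbSGxx",
                "bbVGxx", "GbGGbGKTT", "FbbbbWx", "KRFbbbbDDbW",
                "KbbbTTR", "LxxxExWxLF", "GLPL", "CFbYCxLFP", "MHD",
                "bxxbxb"),
  order_index = c(NA_integer_, 1:6, 1:9, NA_integer_),
  stringsAsFactors = FALSE
)

#' The default motif registry
#'
#' Returns the registry of the 17 motif classes: the extended EDVID motif of
#' the CC domain (consensus \code{RDbbbDbEDbbD}), the six conserved TIR
#' elements (betaA, alphaA, betaC, alphaC, betaD-alphaD1, alphaD3), the nine
#' NBS motifs in their canonical order (VG, P-loop, RNBS-A, Walker-B,
#' RNBS-B, RNBS-C, GLPL, RNBS-D, MHD) and the LxxLxL repeat-start motif of
#' the LRR domain. Window lengths are defaults and can be overridden with
#' the \code{lengths} argument (a model trained for one length refuses to
#' run on another).
#'
#' @param lengths optional named integer vector of per-motif length
#'   overrides. Overriding a length drops the stored consensus for that
#'   motif (the pattern no longer applies).
#' @return A [MotifRegistry-class] object.
#' @export
#' @examples
#' reg <- defaultRegistry()
#' nrow(registryTable(reg))           # 17
#' motifDefinition(reg, "P-loop")$consensus
defaultRegistry <- function(lengths = NULL) {
  d <- REGISTRY_DEFAULTS
  if (!is.null(lengths)) {
    if (is.null(names(lengths)) || !all(names(lengths) %in% d$name))
      stop("length overrides must be named by registry motif names")
    for (nm in names(lengths)) {
      i <- match(nm, d$name)
      if (as.integer(lengths[[nm]]) != d$length[i]) {
        d$length[i] <- as.integer(lengths[[nm]])
        d$consensus[i] <- NA_character_
      }
    }
  }
  methods::new("MotifRegistry", defs = d)
}

#' Registry accessors
#'
#' @param registry a [MotifRegistry-class].
#' @param name motif name.
#' @param domain optional domain filter for `motifNames`.
#' @return `registryTable` returns the definition data.frame; `motifNames`
#'   the motif names (in registry order, NBS/TIR in canonical domain order);
#'   `motifDefinition` a single definition as a list with fields `name`,
#'   `domain`, `length`, `consensus`, `order_index`.
#' @export
registryTable <- function(registry) {
  stopifnot(methods::is(registry, "MotifRegistry"))
  registry@defs
}

#' @rdname registryTable
#' @export
motifNames <- function(registry, domain = NULL) {
  d <- registryTable(registry)
  if (!is.null(domain)) d <- d[d$domain %in% domain, ]
  d <- d[order(match(d$domain, c("CC", "TIR", "NBS", "LRR")),
               ifelse(is.na(d$order_index), 0L, d$order_index)), ]
  d$name
}

#' @rdname registryTable
#' @export
motifDefinition <- function(registry, name) {
  d <- registryTable(registry)
  i <- match(name, d$name)
  if (is.na(i)) stop(sprintf("unknown motif '%s'", name))
  as.list(d[i, ])
}

#' Test a window against a motif consensus
#'
#' Position-wise match of a window against a consensus pattern: a specific
#' residue must match exactly, \code{b} accepts the hydrophobic class
#' (A,V,L,I,M,F,W,Y,C) and \code{x} accepts anything (including X).
#'
#' @param window character string, must have the definition's length.
#' @param def a motif definition list from [motifDefinition()] (or any list
#'   with `consensus` and `length`).
#' @return TRUE iff every position matches its consensus class.
#' @export
#' @examples
#' reg <- defaultRegistry()
#' matchesConsensus("GMGGLGKTT", motifDefinition(reg, "P-loop"))  # TRUE
#' matchesConsensus("LADLSL", motifDefinition(reg, "LxxLxL"))     # TRUE
matchesConsensus <- function(window, def) {
  if (is.na(def$consensus) || !nzchar(def$consensus))
    stop(sprintf("motif '%s' has no consensus pattern", def$name))
  window <- asResidueString(window)
  if (nchar(window) != def$length)
    stop(sprintf("window length %d does not match motif length %d",
                 nchar(window), def$length))
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  p <- strsplit(def$consensus, "", fixed = TRUE)[[1]]
  all(ifelse(p == "x", TRUE,
             ifelse(p == "b", w %in% HYDROPHOBIC, w == p)))
}

## Vectorised consensus scan: positions (0-based) of all windows of `seq`
## conforming to `def`. Used by the consensus scoring backend and the
## synthetic generators.
consensusScan <- function(seq, def) {
  seq <- asResidueString(seq)
  n <- nchar(seq)
  L <- def$length
  if (n < L) return(integer(0))
  if (is.na(def$consensus)) stop("no consensus pattern")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(def$consensus, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    cj <- chars[j:(n - L + j)]
    ok <- ok & switch(p[j], x = TRUE, b = cj %in% HYDROPHOBIC, cj == p[j])
  }
  which(ok) - 1L
}

#' Serialise / load a registry
#'
#' The registry round-trips through a JSON config (name, domain, length,
#' consensus, order_index per motif), so altered window lengths can be kept
#' next to the models trained with them.
#'
#' @param registry a [MotifRegistry-class].
#' @param path file path.
#' @return `readRegistry` returns a [MotifRegistry-class].
#' @export
writeRegistry <- function(registry, path) {
  jsonlite::write_json(registryTable(registry), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeRegistry
#' @export
readRegistry <- function(path) {
  d <- jsonlite::fromJSON(path)
  d$length <- as.integer(d$length)
  d$order_index <- as.integer(d$order_index)
  d$consensus <- as.character(d$consensus)
  methods::new("MotifRegistry", defs = as.data.frame(d))
}
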