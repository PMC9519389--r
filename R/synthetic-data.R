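## Seeded synthetic-data generators: labeled motif datasets, full NLR
## sequences with ground truth, focused databases with archetype families,
## planted physico-chemical LRR classes and covarying alignments.
##
## Conventions shared by all generators: background residues follow the
## BLOSUM62 marginals; consensus 'b' positions are planted from
## {L,I,V,M,F}; motif noise mu replaces each class position ('b' or 'x')
## of a planted window with a background draw, while fixed anchor residues
## stay intact; non-motif regions are scrubbed of accidental
## consensus-conforming windows so ground truth is unambiguous (noise can
## reintroduce conformers, which is the intended noisy regime).

## Plant-LRR repeat body planted at every ladder start: the LxxLxL frame
## followed by the canonical plant LRR turn (N..LSGxIP-like pattern).
LRR_REPEAT_PATTERN <- "bxxbxbxxNxLSGxbP"

## sample() without the scalar-expansion trap (sample(6, 1) == sample(1:6, 1)).
sampleRange <- function(lo, hi) {
  v <- as.integer(lo):as.integer(hi)
  v[sample.int(length(v), 1L)]
}

## Plant one consensus instance as a character vector.
plantConsensus <- function(consensus) {
  p <- strsplit(consensus, "", fixed = TRUE)[[1]]
  vapply(p, function(s) {
    if (s == "b") sample(B_PLANT_SET, 1L)
    else if (s == "x") sampleBackground(1L)
    else s
  }, "", USE.NAMES = FALSE)
}

## Apply motif noise: class positions of the window at `start` (0-based)
## are replaced by background draws with probability mu each.
applyMotifNoise <- function(chars, start, consensus, mu) {
  if (mu <= 0) return(chars)
  p <- strsplit(consensus, "", fixed = TRUE)[[1]]
  classPos <- which(p %in% c("b", "x"))
  hit <- classPos[stats::runif(length(classPos)) < mu]
  if (length(hit))
    chars[start + hit] <- sampleBackground(length(hit))
  chars
}

## Remove accidental consensus-conforming windows. `allowed` is a list
## (per definition name) of permitted 0-based starts; `immutable` marks
## positions that are constrained (non-'x') positions of planted windows
## and must not be touched. A decoy is broken by mutating one of its
## constrained positions to a non-hydrophobic (or simply different)
## residue.
scrubDecoys <- function(chars, defs, allowed = list(), immutable = NULL,
                        maxIter = 30L) {
  n <- length(chars)
  if (is.null(immutable)) immutable <- rep(FALSE, n)
  nonHydro <- setdiff(AA20, HYDROPHOBIC)
  for (iter in seq_len(maxIter)) {
    dirty <- FALSE
    for (def in defs) {
      if (is.na(def$consensus)) next
      seq <- paste(chars, collapse = "")
      decoys <- setdiff(consensusScan(seq, def),
                        allowed[[def$name]] %||% integer(0))
      for (s in decoys) {
        p <- strsplit(def$consensus, "", fixed = TRUE)[[1]]
        cand <- which(p != "x" & !immutable[s + seq_along(p)])
        if (!length(cand)) next  # fully overlaps planted anchors; leave
        j <- cand[1L]
        repl <- if (p[j] == "b") sample(nonHydro, 1L)
                else sample(setdiff(nonHydro, p[j]), 1L)
        chars[s + j] <- repl
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  chars
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labeled single-motif dataset
#'
#' Each sequence is background noise with exactly one consensus-conforming
#' motif planted at a uniform random position; motif noise `mu` then
#' replaces each non-anchor (class) position with a background draw.
#' Non-motif regions are scrubbed of accidental conforming windows before
#' noise, so the planted start is the unique noise-free true positive.
#'
#' @param def motif definition (must carry a consensus).
#' @param n number of sequences (>= 10).
#' @param mu per-position noise rate on non-anchor motif positions.
#' @param seed RNG seed (the same seed reproduces the dataset exactly).
#' @param len sequence length (default 300).
#' @return List with `sequences` (`AAStringSet`), `truth` (data.frame
#'   `seqid`, `motif`, `start`, 0-based) and `def`.
#' @export
generateMotifDataset <- function(def, n, mu = 0, seed = 1L, len = 300L) {
  if (n < 10L) stop("n must be >= 10")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  L <- def$length
  if (len <= L + 2L) stop("sequences too short for the motif")
  withSeed(seed, {
    seqs <- character(n)
    starts <- integer(n)
    for (i in seq_len(n)) {
      chars <- sampleBackground(len)
      s <- sampleRange(0L, len - L)
      chars[s + seq_len(L)] <- plantConsensus(def$consensus)
      p <- strsplit(def$consensus, "", fixed = TRUE)[[1]]
      imm <- rep(FALSE, len)
      imm[s + which(p != "x")] <- TRUE
      chars <- scrubDecoys(chars, list(def),
                           allowed = stats::setNames(list(s), def$name),
                           immutable = imm)
      chars <- applyMotifNoise(chars, s, def$consensus, mu)
      seqs[i] <- paste(chars, collapse = "")
      starts[i] <- s
    }
    ids <- sprintf("syn%04d", seq_len(n))
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- ids
    list(sequences = sequences,
         truth = data.frame(seqid = ids, motif = def$name, start = starts,
                            stringsAsFactors = FALSE),
         def = def)
  })
}

#' Generate one synthetic NLR sequence with ground truth
#'
#' Assembles a canonical NLR layout: an N-terminal region carrying the
#' extended-EDVID motif (CNL), the six TIR motifs in order (TNL) or
#' nothing (NL); the nine NBS motifs in registry order separated by
#' background spacers; a linker; and an LRR ladder whose repeats each
#' start with an LxxLxL frame extended by a plant-LRR repeat body.
#' Optional satellite decoys plant a second LxxLxL-conforming window 6-14
#' residues downstream of a true repeat start. Accidental conforming
#' windows outside the planted ones are scrubbed before noise.
#'
#' @param layout "CNL", "TNL" or "NL".
#' @param seed RNG seed.
#' @param id sequence id.
#' @param nRepeats number of LRR repeats (default drawn uniformly from
#'   `repeatCountRange`).
#' @param repeatCountRange range the repeat count is drawn from.
#' @param repeatLenRange repeat length range (default 15-40).
#' @param linker NBS-to-LRR linker length; default drawn from
#'   `linkerRange`.
#' @param linkerRange linker draw range (default 10-45).
#' @param spacerRange NBS inter-motif spacer range (default 15-40).
#' @param mu motif noise rate (non-anchor positions).
#' @param satelliteRate per-repeat probability of injecting a satellite
#'   decoy.
#' @param registry a [MotifRegistry-class].
#' @return List with `id`, `seq` (character), `truth` (list: `calls`
#'   data.frame of planted motif starts, `ladderStarts`, `satellites`,
#'   `linker`, `class`).
#' @export
generateNlr <- function(layout = c("CNL", "TNL", "NL"), seed = 1L,
                        id = "nlr1", nRepeats = NULL,
                        repeatCountRange = c(9L, 14L),
                        repeatLenRange = c(15L, 40L), linker = NULL,
                        linkerRange = c(10L, 45L), spacerRange = c(15L, 40L),
                        mu = 0, satelliteRate = 0,
                        registry = defaultRegistry()) {
  layout <- match.arg(layout)
  withSeed(seed, {
    if (is.null(nRepeats))
      nRepeats <- sampleRange(repeatCountRange[1L], repeatCountRange[2L])
    if (is.null(linker))
      linker <- sampleRange(linkerRange[1L], linkerRange[2L])
    chars <- character(0)
    plantings <- list()   # (start, consensus) of every planted window
    calls <- list()
    addBg <- function(k) chars <<- c(chars, sampleBackground(k))
    plantDef <- function(def) {
      s <- length(chars)
      chars <<- c(chars, plantConsensus(def$consensus))
      plantings[[length(plantings) + 1L]] <<-
        list(start = s, consensus = def$consensus)
      calls[[length(calls) + 1L]] <<-
        data.frame(seqid = id, motif = def$name, start = s,
                   stringsAsFactors = FALSE)
      s
    }
    plantPattern <- function(pattern) {   # unlabeled planted body
      s <- length(chars)
      chars <<- c(chars, plantConsensus(pattern))
      plantings[[length(plantings) + 1L]] <<-
        list(start = s, consensus = pattern)
      s
    }
    if (layout == "CNL") {
      addBg(40L)
      plantDef(motifDefinition(registry, "EDVID"))
      addBg(30L)
    } else if (layout == "TNL") {
      addBg(15L)
      for (nm in motifNames(registry, "TIR")) {
        plantDef(motifDefinition(registry, nm))
        addBg(sampleRange(8L, 15L))
      }
      addBg(10L)
    } else {
      addBg(25L)
    }
    nbsNames <- motifNames(registry, "NBS")
    for (k in seq_along(nbsNames)) {
      plantDef(motifDefinition(registry, nbsNames[k]))
      if (k < length(nbsNames))
        addBg(sampleRange(spacerRange[1L], spacerRange[2L]))
    }
    addBg(linker)
    lrrDef <- motifDefinition(registry, "LxxLxL")
    patL <- nchar(LRR_REPEAT_PATTERN)
    ladderStarts <- integer(0)
    satellites <- integer(0)
    for (r in seq_len(nRepeats)) {
      rl <- if (r < nRepeats)
        sampleRange(max(repeatLenRange[1L], 1L), repeatLenRange[2L])
      else patL
      s <- length(chars)
      body <- substr(LRR_REPEAT_PATTERN, 1L, min(rl, patL))
      plantPattern(body)
      if (rl > nchar(body)) addBg(rl - nchar(body))
      ladderStarts <- c(ladderStarts, s)
      calls[[length(calls) + 1L]] <-
        data.frame(seqid = id, motif = "LxxLxL", start = s,
                   stringsAsFactors = FALSE)
      if (r < nRepeats && satelliteRate > 0 &&
          stats::runif(1L) < satelliteRate && rl >= 12L) {
        off <- sampleRange(6L, min(14L, rl - 6L))
        sat <- s + off
        chars[(sat + 1L):(sat + 6L)] <- plantConsensus(lrrDef$consensus)
        plantings[[length(plantings) + 1L]] <-
          list(start = sat, consensus = lrrDef$consensus)
        satellites <- c(satellites, sat)
      }
    }
    addBg(12L)
    ## scrub accidental conformers of every motif class
    n <- length(chars)
    immutable <- rep(FALSE, n)
    for (pl in plantings) {
      p <- strsplit(pl$consensus, "", fixed = TRUE)[[1]]
      immutable[pl$start + which(p != "x")] <- TRUE
    }
    callsDf <- do.call(rbind, calls)
    allowed <- split(callsDf$start, callsDf$motif)
    allowed[["LxxLxL"]] <- c(allowed[["LxxLxL"]], satellites)
    defs <- lapply(registryTable(registry)$name,
                   function(nm) motifDefinition(registry, nm))
    chars <- scrubDecoys(chars, defs, allowed = allowed,
                         immutable = immutable)
    ## noise on every planted window
    for (pl in plantings)
      chars <- applyMotifNoise(chars, pl$start, pl$consensus, mu)
    list(id = id, seq = paste(chars, collapse = ""),
         truth = list(calls = callsDf, ladderStarts = ladderStarts,
                      satellites = satellites, linker = linker,
                      class = layout))
  })
}

#' Generate a set of synthetic NLRs
#'
#' @param n number of sequences.
#' @param layout layout passed to [generateNlr()] (recycled).
#' @param seed master seed; per-sequence seeds are derived from it.
#' @param ... further arguments to [generateNlr()].
#' @return List with `sequences` (`AAStringSet`) and `truth` (list of
#'   per-sequence truth lists, named by id).
#' @export
generateNlrSet <- function(n, layout = "NL", seed = 1L, ...) {
  layout <- rep(layout, length.out = n)
  ids <- sprintf("%s%04d", tolower(layout), seq_len(n))
  out <- lapply(seq_len(n), function(i)
    generateNlr(layout[i], seed = seed * 1000L + i, id = ids[i], ...))
  seqs <- Biostrings::AAStringSet(vapply(out, `[[`, "", "seq"))
  names(seqs) <- ids
  truth <- lapply(out, `[[`, "truth")
  names(truth) <- ids
  list(sequences = seqs, truth = truth)
}

#' Generate a synthetic focused database
#'
#' Emulates the focused profile database: NLR-like entries of at least 500
#' residues and LRR-domain-only entries of at least 200 residues, generated
#' as noisy copies of a smaller set of archetypes so that profile searches
#' find homolog families.
#'
#' @param nNlr number of NLR-like records (default 150).
#' @param nLrr number of LRR-only records (default 100).
#' @param seed RNG seed.
#' @param mu per-position divergence of each copy from its archetype
#'   (default 0.2).
#' @param copiesPerArchetype family size (default 10).
#' @return An `AAStringSet` focused database (see [buildFocusedDb()]).
#' @export
generateFocusedDb <- function(nNlr = 150L, nLrr = 100L, seed = 1L,
                              mu = 0.2, copiesPerArchetype = 10L) {
  withSeed(seed, {
    mutate <- function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(chars)) < mu)
      if (length(hit)) chars[hit] <- sampleBackground(length(hit))
      paste(chars, collapse = "")
    }
    padTo <- function(s, minLen) {
      if (nchar(s) >= minLen) s
      else paste0(s, paste(sampleBackground(minLen - nchar(s)),
                           collapse = ""))
    }
    nArchN <- ceiling(nNlr / copiesPerArchetype)
    nArchL <- ceiling(nLrr / copiesPerArchetype)
    seqs <- character(0)
    ids <- character(0)
    for (a in seq_len(nArchN)) {
      arch <- padTo(generateNlr("CNL", seed = sample.int(1e6, 1L),
                                id = "arch",
                                repeatCountRange = c(12L, 16L))$seq, 500L)
      for (cc in seq_len(copiesPerArchetype)) {
        if (length(seqs) >= nNlr) break
        seqs <- c(seqs, padTo(mutate(arch), 500L))
        ids <- c(ids, sprintf("nlrA%02d_c%02d", a, cc))
      }
    }
    nSoFar <- length(seqs)
    for (a in seq_len(nArchL)) {
      reps <- sampleRange(8L, 12L)
      body <- character(0)
      for (r in seq_len(reps)) {
        rl <- sampleRange(24L, 34L)
        pat <- plantConsensus(substr(LRR_REPEAT_PATTERN, 1L,
                                     min(rl, nchar(LRR_REPEAT_PATTERN))))
        body <- c(body, pat,
                  sampleBackground(max(0L, rl - length(pat))))
      }
      arch <- padTo(paste(c(sampleBackground(15L), body,
                            sampleBackground(15L)), collapse = ""), 200L)
      for (cc in seq_len(copiesPerArchetype)) {
        if (length(seqs) - nSoFar >= nLrr) break
        seqs <- c(seqs, padTo(mutate(arch), 200L))
        ids <- c(ids, sprintf("lrrA%02d_c%02d", a, cc))
      }
    }
    db <- Biostrings::AAStringSet(seqs)
    names(db) <- ids
    db <- buildFocusedDb(db)
    S4Vectors::metadata(db)$seed <- seed
    db
  })
}

#' Generate LxxLxL windows with planted physico-chemical classes
#'
#' Emulates the charge-class structure of LRR motif clusters: each class
#' places a charged residue at one of the solvent-exposed positions of the
#' LxxLxL frame (positions 1, 2 or 4, 0-based); the hydrophobic frame
#' positions are drawn from the aliphatic set and the remaining exposed
#' positions from small neutral residues. With probability `sigma` each
#' exposed position is jittered to a random background residue.
#'
#' @param kClasses number of classes (<= 6).
#' @param nPerClass windows per class.
#' @param sigma within-class jitter rate.
#' @param seed RNG seed.
#' @return List with `windows` (character vector of 6-mers) and `labels`
#'   (integer class per window, 1..k).
#' @export
generatePlantedLrrClasses <- function(kClasses = 3L, nPerClass = 200L,
                                      sigma = 0.02, seed = 1L) {
  if (kClasses > 6L) stop("at most 6 planted classes are defined")
  ## Charge pattern of the three exposed positions (1, 2, 4 of the frame):
  ## '+' = K/R, '-' = D/E, '0' = small neutral.
  templates <- list(c("+", "+", "+"), c("-", "-", "-"), c("0", "0", "0"),
                    c("+", "-", "+"), c("-", "+", "-"), c("+", "0", "-"))
  chargeSet <- list("+" = c("K", "R"), "-" = c("D", "E"), "0" = "S")
  withSeed(seed, {
    windows <- character(kClasses * nPerClass)
    labels <- integer(kClasses * nPerClass)
    k <- 0L
    for (cl in seq_len(kClasses)) {
      tpl <- templates[[cl]]
      for (i in seq_len(nPerClass)) {
        w <- character(6L)
        w[c(1L, 4L, 6L)] <- sample(c("L", "I", "V"), 3L, replace = TRUE)
        exposed <- c(2L, 3L, 5L)
        for (e in seq_along(exposed)) {
          set <- chargeSet[[tpl[e]]]
          w[exposed[e]] <- set[sample.int(length(set), 1L)]
        }
        for (j in exposed)
          if (stats::runif(1L) < sigma) w[j] <- sampleBackground(1L)
        k <- k + 1L
        windows[k] <- paste(w, collapse = "")
        labels[k] <- cl
      }
    }
    list(windows = windows, labels = labels)
  })
}

#' Generate an alignment with one planted covarying column pair
#'
#' All columns are i.i.d. background draws except the planted pair: column
#' i is a background draw and, with probability `coupling`, column j is a
#' deterministic one-to-one mapping (a fixed alphabet permutation) of
#' column i; otherwise column j is an independent background draw. Both
#' marginals stay at the background, so only the dependence is planted.
#'
#' @param nRows alignment depth.
#' @param nCols number of columns.
#' @param pair the covarying column pair (1-based).
#' @param coupling coupling strength in `[0, 1]`.
#' @param seed RNG seed.
#' @return List with `alignment` (character vector of rows), `pair`,
#'   `coupling`.
#' @export
generateCovaryingAlignment <- function(nRows = 500L, nCols = 20L,
                                       pair = c(3L, 11L), coupling = 0.9,
                                       seed = 1L) {
  if (any(pair < 1L | pair > nCols) || pair[1L] == pair[2L])
    stop("pair must name two distinct columns inside the alignment")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  withSeed(seed, {
    m <- matrix(sampleBackground(nRows * nCols), nRows, nCols)
    perm <- c(AA20[-1L], AA20[1L])       # fixed cyclic permutation
    names(perm) <- AA20
    coupled <- stats::runif(nRows) < coupling
    m[coupled, pair[2L]] <- perm[m[coupled, pair[1L]]]
    list(alignment = apply(m, 1L, paste, collapse = ""),
         pair = pair, coupling = coupling)
  })
}
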