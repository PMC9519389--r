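## Per-residue evolutionary features: -ln match-emission probabilities from
## two iterations of a profile search of the query against a focused
## database.
##
## The reference implementation is an internal iterative gapless-anchor
## PSSM search (no external binaries): iteration 1 scores query vs database
## with BLOSUM62, collects the best gapless local segment per subject above
## the ungapped Karlin-Altschul significance threshold, and estimates
## per-position emissions from Henikoff-weighted residue counts (query
## included, as in iterative HMM searches) plus one unit of background
## pseudocount mass; iteration 2 repeats the search using the iteration-1
## log-odds PSSM as scorer. An optional jackhmmer backend reads the same
## quantities from HMM checkpoints.

#' Build a focused profile database
#'
#' Wraps a FASTA file or `AAStringSet` as the focused homolog database used
#' for profile construction: a deliberately small, curated set of NLR and
#' LRR-domain sequences that replaces a global protein database so profile
#' features stay cheap. Records are validated for unique ids, and
#' composition statistics (counts of sequences of at least 500 aa and of at
#' least 200 aa) are attached as metadata.
#'
#' @param x FASTA path or `AAStringSet`.
#' @return An `AAStringSet` with composition stats in
#'   `S4Vectors::metadata()`.
#' @export
buildFocusedDb <- function(x) {
  db <- if (is.character(x)) readProteinFasta(x) else x
  if (!methods::is(db, "AAStringSet")) stop("x must be a FASTA path or AAStringSet")
  if (length(db) == 0L) stop("focused database is empty")
  if (is.null(names(db)) || anyDuplicated(names(db)))
    stop(sprintf("duplicate sequence id '%s' in focused database",
                 names(db)[duplicated(names(db))][1L]))
  w <- Biostrings::width(db)
  S4Vectors::metadata(db) <- c(S4Vectors::metadata(db), list(
    n = length(db), n_ge_500 = sum(w >= 500L), n_ge_200 = sum(w >= 200L)))
  db
}

## Precomputed integer/character views of the database, shared across the
## queries of one run.
dbSearchCache <- function(db) {
  chars <- as.character(db)
  list(chars = chars, ints = lapply(chars, aaToInt))
}

## Position-based Henikoff weights on a character matrix (rows = sequences,
## NA = not covered, X treated as missing). Returns weights normalised to
## sum to 1.
henikoffWeightsMatrix <- function(mat) {
  nr <- nrow(mat)
  if (nr < 1L) stop("empty alignment")
  if (nr == 1L) return(1)
  w <- numeric(nr)
  for (j in seq_len(ncol(mat))) {
    res <- mat[, j]
    ok <- !is.na(res) & res != "X" & res != "-"
    if (!any(ok)) next
    tab <- table(res[ok])
    r <- length(tab)
    w[ok] <- w[ok] + 1 / (r * as.numeric(tab[res[ok]]))
  }
  if (sum(w) == 0) w <- rep(1, nr)
  w / sum(w)
}

## Emission probabilities from one alignment iteration. `mat` holds the
## query row plus one row per accepted hit. Weighted counts are scaled so
## the total observed mass equals the number of aligned rows, then one unit
## of background pseudocount mass is added and the result normalised.
emissionsFromAlignment <- function(mat) {
  L <- ncol(mat)
  w <- henikoffWeightsMatrix(mat) * nrow(mat)
  counts <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  for (i in seq_len(nrow(mat))) {
    res <- mat[i, ]
    ok <- which(!is.na(res) & res %in% AA20)
    if (length(ok))
      counts[cbind(match(res[ok], AA20), ok)] <-
        counts[cbind(match(res[ok], AA20), ok)] + w[i]
  }
  tot <- colSums(counts)
  p <- sweep(counts, 2, tot + 1, "/") + outer(BLOSUM62_BG, 1 / (tot + 1))
  p <- pmax(p, EMISSION_FLOOR)
  p
}

#' Internal iterative PSSM search
#'
#' The dependency-free profile engine. Each iteration finds, per database
#' sequence, the best gapless local alignment segment to the query
#' (iteration 1 scored with BLOSUM62, later iterations with the log-odds
#' PSSM of the previous iteration) and keeps it when it passes the ungapped
#' Karlin-Altschul E-value threshold. Per-position emission probabilities
#' are Henikoff-weighted residue frequencies over the query and the
#' accepted hit segments, smoothed with one unit of background pseudocount
#' mass and floored at 1e-9 before taking -ln.
#'
#' The query itself is always part of the profile, so a query with no hits
#' still yields informative (query-plus-background) emissions; only its
#' coverage mask is all-FALSE. Query X residues contribute no counts and
#' fall back to pure background.
#'
#' @param query character string, `AAString`, or single-element
#'   `AAStringSet`.
#' @param db focused database from [buildFocusedDb()] (or `AAStringSet`).
#' @param iterations number of profile iterations (>= 1; the canonical
#'   feature set uses 2).
#' @param evalueCutoff hit inclusion threshold.
#' @param seqid id recorded in the result (defaults to the query's name).
#' @return A [ProfileFeatures-class] object.
#' @export
internalPssmSearch <- function(query, db, iterations = 2L,
                               evalueCutoff = 1e-5, seqid = NULL,
                               .cache = NULL) {
  if (methods::is(query, "AAStringSet")) {
    if (is.null(seqid)) seqid <- names(query)[1L]
    query <- query[[1L]]
  }
  qstr <- asResidueString(query)
  if (is.null(seqid)) seqid <- "query"
  if (!nzchar(qstr)) stop("empty query")
  if (length(db) == 0L) stop("empty database")
  if (iterations < 1L) stop("iterations must be >= 1")
  L <- nchar(qstr)
  qint <- aaToInt(qstr)
  qchars <- strsplit(qstr, "", fixed = TRUE)[[1]]
  if (is.null(.cache)) .cache <- dbSearchCache(db)
  dbchar <- .cache$chars
  dbints <- .cache$ints
  emissions <- vector("list", iterations)
  covered <- rep(FALSE, L)
  nhits <- integer(iterations)
  p_prev <- NULL
  for (it in seq_len(iterations)) {
    if (it == 1L) {
      scorer <- blosum62Matrix()
      ka <- KA_BLOSUM62
      ps <- FALSE
    } else {
      scorer <- t(log(p_prev / BLOSUM62_BG))  # L x 20 log-odds
      ka <- KA_PSSM
      ps <- TRUE
    }
    hits <- .cpp_gapless_search(qint, dbints, scorer, ps,
                                ka[["lambda"]], ka[["K"]], evalueCutoff)
    nhits[it] <- nrow(hits)
    mat <- matrix(NA_character_, nrow = 1L + nrow(hits), ncol = L)
    mat[1L, ] <- qchars
    if (nrow(hits)) {
      for (r in seq_len(nrow(hits))) {
        schars <- strsplit(dbchar[[hits$subject[r]]], "", fixed = TRUE)[[1]]
        cols <- hits$qstart[r] + seq_len(hits$len[r])       # 1-based
        mat[1L + r, cols] <- schars[hits$sstart[r] + seq_len(hits$len[r])]
      }
    }
    p_prev <- emissionsFromAlignment(mat)
    emissions[[it]] <- p_prev
    if (nrow(hits) >= 1L)
      covered <- covered | colSums(!is.na(mat[-1L, , drop = FALSE])) > 0L
  }
  if (sum(nhits) == 0L)
    warning(sprintf("no profile hits for '%s'; features carry query and background information only",
                    seqid))
  feat <- do.call(cbind, lapply(emissions, function(p) -log(t(p))))
  colnames(feat) <- paste0("it", rep(seq_len(iterations), each = 20L),
                           "_", rep(AA20, iterations))
  methods::new("ProfileFeatures", seqid = seqid, residues = qstr,
               features = feat, covered = covered, nhits = nhits)
}

#' Per-residue profile features for a query
#'
#' Front end over the profile engines. `engine = "internal"` (default, the
#' reference implementation) runs [internalPssmSearch()]; `engine =
#' "jackhmmer"` shells out to the HMMER jackhmmer binary and reads match
#' emissions from its per-iteration HMM checkpoints.
#'
#' @inheritParams internalPssmSearch
#' @param engine `"internal"` or `"jackhmmer"`.
#' @return A [ProfileFeatures-class] object.
#' @export
buildProfileFeatures <- function(query, db, iterations = 2L,
                                 evalueCutoff = 1e-5,
                                 engine = c("internal", "jackhmmer"),
                                 seqid = NULL) {
  engine <- match.arg(engine)
  if (engine == "internal")
    return(internalPssmSearch(query, db, iterations, evalueCutoff, seqid))
  jackhmmerFeatures(query, db, iterations, evalueCutoff, seqid)
}

#' @rdname buildProfileFeatures
#' @param seqs `AAStringSet` of queries.
#' @return `profileFeaturesSet` returns a named list of
#'   [ProfileFeatures-class], one per query.
#' @export
profileFeaturesSet <- function(seqs, db, iterations = 2L,
                               evalueCutoff = 1e-5,
                               engine = c("internal", "jackhmmer")) {
  engine <- match.arg(engine)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  cache <- if (engine == "internal") dbSearchCache(db)
  out <- lapply(seq_along(seqs), function(i) {
    if (engine == "internal")
      suppressWarnings(internalPssmSearch(seqs[[i]], db, iterations,
                                          evalueCutoff, ids[i],
                                          .cache = cache))
    else
      suppressWarnings(jackhmmerFeatures(seqs[[i]], db, iterations,
                                         evalueCutoff, ids[i]))
  })
  names(out) <- ids
  out
}

## jackhmmer backend: run with HMM checkpoints and read the match-state
## emission scores (HMMER stores them as -ln p, amino acids alphabetical,
## matching this package's feature order). jackhmmer keeps the model
## anchored on the query, so match state k maps to query position k.
jackhmmerFeatures <- function(query, db, iterations = 2L,
                              evalueCutoff = 1e-5, seqid = NULL) {
  bin <- Sys.which("jackhmmer")
  if (!nzchar(bin))
    stop("jackhmmer binary not found; use engine = \"internal\" (the internal PSSM search implements the same contract)")
  if (methods::is(query, "AAStringSet")) {
    if (is.null(seqid)) seqid <- names(query)[1L]
    query <- query[[1L]]
  }
  if (is.null(seqid)) seqid <- "query"
  qstr <- asResidueString(query)
  td <- tempfile("jack")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qfa <- file.path(td, "q.fa")
  dfa <- file.path(td, "db.fa")
  writeProteinFasta(stats::setNames(c(qstr), seqid), qfa)
  writeProteinFasta(db, dfa)
  chk <- file.path(td, "chk")
  dom <- file.path(td, "dom.tbl")
  status <- system2(bin, c("-N", iterations, "-E", format(evalueCutoff),
                           "--incE", format(evalueCutoff),
                           "--chkhmm", chk, "--domtblout", dom, qfa, dfa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("jackhmmer failed")
  L <- nchar(qstr)
  feats <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    f <- sprintf("%s-%d.hmm", chk, it)
    if (!file.exists(f)) f <- sprintf("%s-%d.hmm", chk, it - 1L)
    m <- parseHmmEmissions(f)
    if (nrow(m) != L)
      stop("jackhmmer model length does not match the query; use engine = \"internal\"")
    feats[[it]] <- m
  }
  covered <- rep(FALSE, L)
  if (file.exists(dom)) {
    lines <- grep("^#", readLines(dom), invert = TRUE, value = TRUE)
    for (ln in lines) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) >= 17) {
        from <- suppressWarnings(as.integer(tok[16]))
        to <- suppressWarnings(as.integer(tok[17]))
        if (!is.na(from) && !is.na(to)) covered[from:to] <- TRUE
      }
    }
  }
  feat <- do.call(cbind, feats)
  colnames(feat) <- paste0("it", rep(seq_len(iterations), each = 20L),
                           "_", rep(AA20, iterations))
  methods::new("ProfileFeatures", seqid = seqid, residues = qstr,
               features = feat, covered = covered,
               nhits = rep(NA_integer_, iterations))
}

## Parse match emissions (-ln p) from an HMMER3 .hmm file into an L x 20
## matrix in package column order (alphabetical; HMMER's order already is).
parseHmmEmissions <- function(path) {
  lines <- readLines(path)
  start <- grep("^HMM\\s", lines)[1L]
  if (is.na(start)) stop("not an HMM file")
  body <- lines[(start + 2L):length(lines)]
  rows <- list()
  i <- 1L
  if (grepl("^\\s*COMPO", body[1L])) i <- 4L  # COMPO + its insert/transition
  while (i <= length(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (identical(tok[1L], "//")) break
    node <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(node) || node != length(rows) + 1L)
      stop("unexpected HMM node structure")
    v <- suppressWarnings(as.numeric(tok[2:21]))
    v[is.na(v)] <- -log(EMISSION_FLOOR)
    rows[[length(rows) + 1L]] <- v
    i <- i + 3L  # skip insert-emission and transition lines
  }
  m <- do.call(rbind, rows)
  pmin(m, -log(EMISSION_FLOOR))
}

#' Cache profile features on disk
#'
#' Stores the feature matrix, coverage mask and residues keyed by sequence
#' id, for reuse across prediction runs.
#'
#' @param pf a [ProfileFeatures-class].
#' @param path file path.
#' @return `readProfileFeatures` returns the restored object.
#' @export
saveProfileFeatures <- function(pf, path) {
  stopifnot(methods::is(pf, "ProfileFeatures"))
  saveRDS(list(format = "NLRmotifs-profile", version = "1",
               seqid = pf@seqid, residues = pf@residues,
               features = pf@features, covered = pf@covered,
               nhits = pf@nhits), path)
  invisible(path)
}

#' @rdname saveProfileFeatures
#' @export
readProfileFeatures <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "NLRmotifs-profile"))
    stop("not a profile features file")
  methods::new("ProfileFeatures", seqid = x$seqid, residues = x$residues,
               features = x$features, covered = x$covered, nhits = x$nhits)
}
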