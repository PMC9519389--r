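## End-to-end annotation of a sequence: per-motif probabilities -> calls
## -> satellite resolution -> domain layout -> LRR ladder -> NLR class.

#' Pipeline thresholds
#'
#' The rule-stage configuration: call threshold (probability strictly
#' above 0.80), satellite window (15 aa) and margin (20%), maximal
#' NBS-to-LRR linker (50 aa), accepted repeat length range (15-50 aa) and
#' minimal ladder size (9 repeats for LRR-domain analysis; the CNL
#' interdomain analysis uses 5).
#'
#' @param call call threshold.
#' @param satelliteWindow satellite conflict distance (residues).
#' @param satelliteMargin probability margin resolving a conflict.
#' @param maxLinker maximal NBS-to-LRR linker.
#' @param repeatRange accepted repeat length range.
#' @param minRepeats minimal ladder size.
#' @return Named list.
#' @export
pipelineConfig <- function(call = 0.80, satelliteWindow = 15L,
                           satelliteMargin = 0.20, maxLinker = 50L,
                           repeatRange = c(15L, 50L), minRepeats = 9L) {
  stopifnot(call >= 0, call <= 1, satelliteMargin >= 0, satelliteMargin <= 1,
            satelliteWindow > 0, maxLinker > 0,
            repeatRange[1L] > 0, repeatRange[2L] >= repeatRange[1L])
  list(call = call, satelliteWindow = as.integer(satelliteWindow),
       satelliteMargin = satelliteMargin, maxLinker = as.integer(maxLinker),
       repeatRange = as.integer(repeatRange),
       minRepeats = as.integer(minRepeats))
}

#' Annotate one sequence end to end
#'
#' Runs the full motif pipeline on a sequence: per-residue probabilities
#' for every requested motif (from trained models, the consensus backend,
#' or precomputed vectors), motif calling at the probability threshold,
#' satellite resolution, NBS layout validation, LRR ladder delineation and
#' NLR classification.
#'
#' @param seq sequence (character or `AAString`).
#' @param seqid sequence id.
#' @param backend `"consensus"` (pattern matching, probability 1/0) or
#'   `"models"` (trained predictors over profile features).
#' @param models named list of [MotifPredictor-class] (backend
#'   `"models"`); motifs without a model are skipped.
#' @param db focused database for feature generation (backend
#'   `"models"`).
#' @param probs optional named list of precomputed per-residue probability
#'   vectors (overrides the backend).
#' @param registry a [MotifRegistry-class].
#' @param config thresholds from [pipelineConfig()].
#' @param domains domains to run (default all four).
#' @return List with `seqid`, `calls` (satellite-resolved), `nbs`,
#'   `ladder`, `class` and `flags`.
#' @export
annotateSequence <- function(seq, seqid = "query",
                             backend = c("consensus", "models"),
                             models = NULL, db = NULL, probs = NULL,
                             registry = defaultRegistry(),
                             config = pipelineConfig(),
                             domains = c("CC", "TIR", "NBS", "LRR")) {
  backend <- match.arg(backend)
  seq <- asResidueString(seq)
  wanted <- motifNames(registry, domains)
  if (is.null(probs)) {
    if (backend == "consensus") {
      probs <- lapply(wanted, function(nm)
        consensusProbabilities(seq, motifDefinition(registry, nm)))
      names(probs) <- wanted
    } else {
      if (is.null(models) || is.null(db))
        stop("backend 'models' needs `models` and `db`")
      missing <- setdiff(wanted, names(models))
      if (length(missing))
        stop(sprintf("no model for motif '%s'", missing[1L]))
      features <- internalPssmSearch(seq, db, seqid = seqid)
      probs <- lapply(wanted, function(nm)
        predictResidueProbabilities(models[[nm]], features,
                                    motifDefinition(registry, nm)))
      names(probs) <- wanted
    }
  }
  callList <- lapply(names(probs), function(nm) {
    calls <- callMotifs(probs[[nm]], seqid = seqid, motif = nm,
                        threshold = config$call)
    if (nrow(calls))
      resolveSatellites(calls, window = config$satelliteWindow,
                        margin = config$satelliteMargin)
    else cbind(calls, ambiguous = logical(0))
  })
  calls <- do.call(rbind, callList)
  nbs <- validateNbsLayout(calls, registry)
  ladder <- delineateLrrLadder(calls,
                               nbsAnnotation = if (nbs$valid) nbs else NULL,
                               minRepeats = config$minRepeats,
                               maxLinker = config$maxLinker,
                               minLen = config$repeatRange[1L],
                               maxLen = config$repeatRange[2L],
                               registry = registry)
  cls <- classifyNlr(calls, registry, ladder)
  list(seqid = seqid, calls = calls, nbs = nbs, ladder = ladder,
       class = cls$class, flags = cls$flags, evidence = cls$evidence)
}
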