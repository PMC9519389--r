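#' @import methods
NULL

#' MotifRegistry: the catalogue of NLR motif classes
#'
#' Holds the definitions of the motif classes the package predicts: name,
#' domain (CC, TIR, NBS or LRR), window length, consensus pattern and, for
#' NBS and TIR motifs, the canonical order of the motif within its domain.
#' Consensus patterns are strings over specific residues plus the class
#' symbols \code{b} (hydrophobic: A,V,L,I,M,F,W,Y,C) and \code{x} (any).
#'
#' @slot defs data.frame with columns \code{name}, \code{domain},
#'   \code{length}, \code{consensus}, \code{order_index}.
#' @seealso [defaultRegistry()], [motifDefinition()], [matchesConsensus()]
#' @export
setClass("MotifRegistry", representation(defs = "data.frame"))

setValidity("MotifRegistry", function(object) {
  d <- object@defs
  need <- c("name", "domain", "length", "consensus", "order_index")
  if (!all(need %in% names(d)))
    return(paste("defs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$name)) return("duplicate motif names")
  if (!all(d$domain %in% c("CC", "TIR", "NBS", "LRR")))
    return("domain must be one of CC, TIR, NBS, LRR")
  if (any(d$length < 1L)) return("motif lengths must be positive")
  has <- !is.na(d$consensus) & nzchar(d$consensus)
  if (any(nchar(d$consensus[has]) != d$length[has]))
    return("consensus length must equal motif length")
  bad <- setdiff(unique(strsplit(paste(d$consensus[has], collapse = ""),
                                 "")[[1]]), c(AA20, "b", "x"))
  if (length(bad))
    return(paste("illegal consensus symbols:", paste(bad, collapse = "")))
  nbs <- d[d$domain == "NBS", ]
  if (nrow(nbs) && !identical(sort(nbs$order_index), seq_len(nrow(nbs))))
    return("NBS order_index must rank the NBS motifs 1..n")
  TRUE
})

#' ProfileFeatures: per-residue evolutionary features for one sequence
#'
#' The feature container consumed by the window extractor and the MLP
#' predictors. For each residue it stores the negative natural log of the
#' profile match-emission probability of each of the 20 amino acids, for
#' two iterations of the profile search (40 values per residue). Columns
#' 1-20 are iteration 1 and 21-40 iteration 2, amino acids alphabetical.
#'
#' @slot seqid sequence identifier.
#' @slot residues the query residues (upper case, X allowed).
#' @slot features numeric matrix, rows = positions, 20 x iterations columns.
#' @slot covered logical per position: TRUE where at least one profile hit
#'   column covers the position; FALSE positions carry query-plus-background
#'   emissions only.
#' @slot nhits integer, number of accepted hits per iteration.
#' @export
setClass("ProfileFeatures", representation(
  seqid = "character", residues = "character", features = "matrix",
  covered = "logical", nhits = "integer"))

setValidity("ProfileFeatures", function(object) {
  f <- object@features
  L <- nchar(object@residues)
  if (nrow(f) != L) return("feature rows must match sequence length")
  if (ncol(f) %% 20L != 0L) return("feature columns must be a multiple of 20")
  if (length(object@covered) != L) return("covered mask length mismatch")
  if (any(!is.finite(f)) || any(f < 0))
    return("features must be finite and >= 0")
  nit <- ncol(f) / 20L
  for (it in seq_len(nit)) {
    s <- rowSums(exp(-f[, (it - 1L) * 20L + 1:20, drop = FALSE]))
    if (any(s < 0.999 | s > 1.001))
      return("emission probabilities must sum to 1 within 1e-3 per position")
  }
  TRUE
})

#' SplitPlan: the 5-group training split
#'
#' Partition of a dataset into five near-equal groups: groups 1-4 drive the
#' fourfold cross-validation used for tuning, group 5 is the held-out test
#' set and is never touched during training.
#'
#' @slot groups integer vector, group id (1-5) per item.
#' @slot seed the seed the plan was drawn with.
#' @seealso [makeSplit()]
#' @export
setClass("SplitPlan", representation(groups = "integer", seed = "integer"))

setValidity("SplitPlan", function(object) {
  g <- object@groups
  if (!all(g %in% 1:5)) return("group ids must be in 1..5")
  sz <- tabulate(g, 5L)
  if (diff(range(sz)) > 1L) return("group sizes must differ by at most 1")
  TRUE
})

#' MetricsReport: binary classification metrics
#'
#' Confusion counts and the derived metrics used to evaluate the motif
#' predictors: precision, recall (sensitivity), specificity, F1 and the
#' G score, here the geometric mean sqrt(precision x recall).
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot precision,recall,specificity,f1,g derived metrics in [0, 1].
#' @slot flags character, degenerate-case annotations (e.g. no positive
#'   predictions, in which case precision is reported as 0).
#' @seealso [evaluatePredictions()]
#' @export
setClass("MetricsReport", representation(
  tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric",
  precision = "numeric", recall = "numeric", specificity = "numeric",
  f1 = "numeric", g = "numeric", flags = "character"))

setValidity("MetricsReport", function(object) {
  v <- c(object@precision, object@recall, object@specificity,
         object@f1, object@g)
  if (any(v < 0 | v > 1)) return("metrics must lie in [0, 1]")
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0))
    return("confusion counts must be non-negative")
  TRUE
})

#' MotifPredictor: a trained per-motif MLP classifier
#'
#' One of the per-motif multilayer perceptrons: three hidden layers
#' (250, 125, 100 by default), ReLU activations, logistic output, trained
#' with Adam and L2 regularisation on sliding-window profile features.
#'
#' @slot motif motif name (must exist in the registry used at predict time).
#' @slot motifLength the motif window length L the model was trained for;
#'   the input dimensionality is 40 x (L + 10).
#' @slot weights list of weight matrices and bias vectors.
#' @slot hyperparams the hyperparameter list used for training.
#' @slot negSamplingRate fraction of negative (non-start) windows that was
#'   kept when assembling the training set; predictions are prior-corrected
#'   with this rate so per-residue probabilities refer to the full sequence.
#' @slot meta training metadata (dataset fingerprint, reports).
#' @slot version model format version.
#' @slot featureOrder tag describing the window feature ordering.
#' @export
setClass("MotifPredictor", representation(
  motif = "character", motifLength = "integer", weights = "list",
  hyperparams = "list", negSamplingRate = "numeric", meta = "list",
  version = "character", featureOrder = "character"))

setValidity("MotifPredictor", function(object) {
  if (length(object@weights) == 0L) return("empty weights")
  d <- nrow(object@weights[[1L]]$W)
  if (d != 40L * (object@motifLength + 10L))
    return("input dimensionality must equal 40 * (L + 10)")
  if (object@negSamplingRate <= 0 || object@negSamplingRate > 1)
    return("negSamplingRate must be in (0, 1]")
  TRUE
})

setMethod("show", "MotifRegistry", function(object) {
  d <- object@defs
  cat(sprintf("MotifRegistry with %d motif definitions\n", nrow(d)))
  for (dom in c("CC", "TIR", "NBS", "LRR")) {
    sub <- d[d$domain == dom, ]
    if (!nrow(sub)) next
    sub <- sub[order(ifelse(is.na(sub$order_index), 0L, sub$order_index)), ]
    cat(sprintf("  %s: %s\n", dom, paste(sub$name, collapse = ", ")))
  }
})

setMethod("show", "ProfileFeatures", function(object) {
  cat(sprintf(
    "ProfileFeatures for '%s': %d positions, %d iterations, %.1f%% covered (hits: %s)\n",
    object@seqid, nrow(object@features), ncol(object@features) / 20L,
    100 * mean(object@covered), paste(object@nhits, collapse = "/")))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: n = %d, group sizes %s (seed %d)\n",
              length(object@groups),
              paste(tabulate(object@groups, 5L), collapse = "/"),
              object@seed))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: TP=%g FP=%g TN=%g FN=%g | precision %.4f recall %.4f specificity %.4f F1 %.4f G %.4f%s\n",
    object@tp, object@fp, object@tn, object@fn, object@precision,
    object@recall, object@specificity, object@f1, object@g,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
    else ""))
})

setMethod("show", "MotifPredictor", function(object) {
  hid <- paste(object@hyperparams$hidden, collapse = "/")
  cat(sprintf(
    "MotifPredictor '%s' (L=%d, input dim %d, hidden %s, neg sampling %.3g)\n",
    object@motif, object@motifLength, 40L * (object@motifLength + 10L), hid,
    object@negSamplingRate))
})
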