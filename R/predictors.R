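## Training, evaluation and application of the per-motif MLP classifiers.

#' MLP hyperparameters
#'
#' The network is the architecture shared by all 17 motif predictors:
#' three hidden layers of 250, 125 and 100 neurons, ReLU activations,
#' logistic output, Adam with a constant learning rate of 0.001 and L2
#' penalty (alpha tunable per motif). Training stops early when the
#' validation loss has not improved by `tol` for `patience` epochs.
#'
#' @param hidden hidden layer sizes.
#' @param learningRate constant Adam learning rate.
#' @param l2Alpha L2 penalty weight.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch cap.
#' @param patience early-stopping patience (epochs).
#' @param tol minimal validation-loss improvement counted as progress.
#' @param seed RNG seed for weight initialisation and batch shuffling.
#' @return Named list of hyperparameters.
#' @export
mlpHyperparams <- function(hidden = c(250L, 125L, 100L),
                           learningRate = 0.001, l2Alpha = 1e-4,
                           batchSize = 200L, maxEpochs = 100L,
                           patience = 10L, tol = 1e-3, seed = 1L) {
  stopifnot(all(hidden > 0L), learningRate > 0, l2Alpha >= 0)
  list(hidden = as.integer(hidden), learningRate = learningRate,
       l2Alpha = l2Alpha, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       tol = tol, seed = as.integer(seed))
}

#' Draw the 5-group training split
#'
#' Partitions `n` items into five near-equal groups (sizes differ by at
#' most one). Groups 1-4 feed the fourfold cross-validation used for
#' tuning; group 5 is the held-out test set.
#'
#' @param n number of items (>= 5).
#' @param seed RNG seed; the same seed always yields the same plan.
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(n, seed = 1L) {
  if (n < 5L) stop("need at least 5 items to form 5 groups")
  g <- withSeed(seed, sample(rep(1:5, length.out = n)))
  methods::new("SplitPlan", groups = as.integer(g), seed = as.integer(seed))
}

#' @rdname makeSplit
#' @param plan a [SplitPlan-class].
#' @return `splitGroups` returns the integer group vector.
#' @export
splitGroups <- function(plan) {
  stopifnot(methods::is(plan, "SplitPlan"))
  plan@groups
}

## Confusion counts -> MetricsReport. Precision is reported as 0 (with a
## flag) when nothing is predicted positive; G = sqrt(precision * recall).
metricsFromCounts <- function(tp, fp, tn, fn) {
  flags <- character(0)
  if (tp + fp == 0) {
    precision <- 0
    flags <- c(flags, "no-positive-predictions")
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) { flags <- c(flags, "no-positives"); 0 }
            else tp / (tp + fn)
  specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  g <- sqrt(precision * recall)
  methods::new("MetricsReport", tp = tp, fp = fp, tn = tn, fn = fn,
               precision = precision, recall = recall,
               specificity = specificity, f1 = f1, g = g, flags = flags)
}

#' Position-level evaluation of motif-start predictions
#'
#' Scores per-residue probabilities against true start positions: a
#' position is predicted positive when its probability reaches `threshold`;
#' a predicted position counts as a true positive when a true start lies
#' within `tolerance` residues (default 0: exact-position scoring).
#'
#' @param probs numeric vector of per-residue probabilities, or a list of
#'   such vectors (one per sequence).
#' @param trueStarts integer vector of 0-based true starts (or a list
#'   parallel to `probs`).
#' @param threshold call threshold (default 0.5).
#' @param tolerance positional slack in residues (default 0).
#' @return A [MetricsReport-class].
#' @export
evaluatePredictions <- function(probs, trueStarts, threshold = 0.5,
                                tolerance = 0L) {
  if (!is.list(probs)) { probs <- list(probs); trueStarts <- list(trueStarts) }
  if (length(probs) != length(trueStarts))
    stop("probs and trueStarts must have the same length")
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(probs)) {
    p <- probs[[i]]
    true <- as.integer(trueStarts[[i]])
    pred <- which(p >= threshold) - 1L
    if (tolerance == 0L) {
      tpi <- length(intersect(pred, true))
      fpi <- length(setdiff(pred, true))
      fni <- length(setdiff(true, pred))
    } else {
      near <- function(a, b) length(b) > 0 &&
        vapply(a, function(x) any(abs(b - x) <= tolerance), logical(1))
      hit <- if (length(pred)) near(pred, true) else logical(0)
      tpi <- sum(hit)
      fpi <- sum(!hit)
      fni <- sum(if (length(true)) !near(true, pred) else logical(0))
    }
    tp <- tp + tpi; fp <- fp + fpi; fn <- fn + fni
    tn <- tn + length(p) - tpi - fpi - fni
  }
  metricsFromCounts(tp, fp, tn, fn)
}

#' Assemble a labeled window training set
#'
#' Builds the window-vector design matrix for one motif from per-sequence
#' profile features and true start positions. All true-start windows are
#' positives; negatives are a seeded random subsample of the non-start
#' positions (`negPerPos` negatives per positive, per sequence). The
#' realised negative sampling fraction is recorded so that per-residue
#' probabilities can be prior-corrected at predict time.
#'
#' @param features list of [ProfileFeatures-class], one per sequence.
#' @param starts list of 0-based integer vectors of true starts, parallel
#'   to `features`.
#' @param def motif definition.
#' @param negPerPos negatives sampled per positive (default 12); `Inf`
#'   keeps every non-start position.
#' @param flank window flank (default 5).
#' @param seed RNG seed for the subsample.
#' @return List with `X` (matrix), `y` (0/1 vector), `seqIndex` (sequence
#'   of origin per row), `pos` (0-based candidate position per row) and
#'   `negSamplingRate`.
#' @export
buildTrainingSet <- function(features, starts, def, negPerPos = 12,
                             flank = 5L, seed = 1L) {
  stopifnot(length(features) == length(starts))
  rowsX <- vector("list", length(features))
  rowsY <- vector("list", length(features))
  rowsS <- vector("list", length(features))
  rowsP <- vector("list", length(features))
  negTotal <- 0; negKept <- 0
  withSeed(seed, {
    for (i in seq_along(features)) {
      Xi <- enumerateCandidates(features[[i]], def, flank)
      n <- nrow(Xi)
      pos <- intersect(as.integer(starts[[i]]), 0:(n - 1L))
      neg <- setdiff(0:(n - 1L), pos)
      k <- if (is.finite(negPerPos))
        min(length(neg), ceiling(negPerPos * max(1L, length(pos))))
      else length(neg)
      negSel <- if (k < length(neg)) sort(sample(neg, k)) else neg
      negTotal <- negTotal + length(neg)
      negKept <- negKept + length(negSel)
      sel <- c(pos, negSel)
      rowsX[[i]] <- Xi[sel + 1L, , drop = FALSE]
      rowsY[[i]] <- c(rep(1, length(pos)), rep(0, length(negSel)))
      rowsS[[i]] <- rep(i, length(sel))
      rowsP[[i]] <- sel
    }
  })
  list(X = do.call(rbind, rowsX), y = unlist(rowsY),
       seqIndex = unlist(rowsS), pos = unlist(rowsP),
       negSamplingRate = if (negTotal > 0) negKept / negTotal else 1)
}

#' Train a per-motif MLP predictor
#'
#' Trains the motif classifier under the 5-group protocol: a fourfold
#' cross-validation over groups 1-4 (each fold trains on three groups and
#' is scored on the fourth), then a final fit on all four training groups;
#' group 5 is scored exactly once as the held-out test report. Training is
#' deterministic given the hyperparameter seed.
#'
#' @param x window matrix (rows = examples) or the list returned by
#'   [buildTrainingSet()] (in which case `y` and `negSamplingRate` are
#'   taken from it).
#' @param y binary labels (1 = true motif start).
#' @param def motif definition; the window dimensionality must equal
#'   `windowLength(def)`.
#' @param hp hyperparameters from [mlpHyperparams()].
#' @param split a [SplitPlan-class] over sequences or examples: if its
#'   length matches the number of examples it is used directly, otherwise
#'   it is mapped through the training set's `seqIndex`.
#' @param negSamplingRate negative sampling fraction stored in the model.
#' @param flank window flank the matrix was built with.
#' @param cv run the fourfold cross-validation over groups 1-4 (default).
#'   Disabling it skips only the per-fold reports; the final fit and the
#'   held-out test report are unchanged.
#' @return List with `model` ([MotifPredictor-class]), `cv` (list of 4
#'   [MetricsReport-class], NULL when `cv = FALSE`) and `test`
#'   ([MetricsReport-class]).
#' @export
trainPredictor <- function(x, y = NULL, def, hp = mlpHyperparams(),
                           split, negSamplingRate = 1, flank = 5L,
                           cv = TRUE) {
  if (is.list(x) && !is.null(x$X)) {
    ts <- x
    x <- ts$X
    if (is.null(y)) y <- ts$y
    negSamplingRate <- ts$negSamplingRate
    seqIndex <- ts$seqIndex
  } else seqIndex <- NULL
  n <- nrow(x)
  if (length(y) != n) stop("labels and window matrix disagree in length")
  if (ncol(x) != windowLength(def, flank))
    stop(sprintf("window dimensionality %d does not match 40*(L+10) = %d for motif '%s'",
                 ncol(x), windowLength(def, flank), def$name))
  g <- splitGroups(split)
  if (length(g) != n) {
    if (is.null(seqIndex) || length(g) < max(seqIndex))
      stop("split length matches neither examples nor sequences")
    g <- g[seqIndex]
  }
  for (k in 1:5) {
    yk <- y[g == k]
    if (length(unique(yk)) < 2L)
      stop(sprintf("group %d contains a single class", k))
  }
  runFit <- function(trIdx, valIdx, seed) {
    .cpp_mlp_train(x[trIdx, , drop = FALSE], y[trIdx],
                   x[valIdx, , drop = FALSE], y[valIdx],
                   hp$hidden, hp$learningRate, hp$l2Alpha, hp$batchSize,
                   hp$maxEpochs, hp$patience, hp$tol, seed)
  }
  windowMetrics <- function(w, idx) {
    p <- as.numeric(.cpp_mlp_predict(w, x[idx, , drop = FALSE]))
    pred <- p >= 0.5
    metricsFromCounts(sum(pred & y[idx] == 1), sum(pred & y[idx] == 0),
                      sum(!pred & y[idx] == 0), sum(!pred & y[idx] == 1))
  }
  cvReports <- NULL
  if (cv) {
    cvReports <- vector("list", 4L)
    for (f in 1:4) {
      fit <- runFit(which(g %in% setdiff(1:4, f)), which(g == f),
                    hp$seed * 10L + f)
      cvReports[[f]] <- windowMetrics(fit$weights, which(g == f))
    }
  }
  trainIdx <- which(g %in% 1:4)
  innerVal <- withSeed(hp$seed,
                       sample(trainIdx, max(1L, round(0.1 * length(trainIdx)))))
  fit <- runFit(setdiff(trainIdx, innerVal), innerVal, hp$seed)
  test <- windowMetrics(fit$weights, which(g == 5))
  model <- methods::new(
    "MotifPredictor", motif = def$name,
    motifLength = as.integer(def$length), weights = fit$weights,
    hyperparams = hp, negSamplingRate = negSamplingRate,
    meta = list(n = n, positives = sum(y == 1),
                bestEpoch = fit$bestEpoch, epochsRun = fit$epochsRun,
                trainedAt = format(Sys.time(), "%Y-%m-%d")),
    version = "1", featureOrder = "position-major;iteration;aa-alpha")
  list(model = model, cv = cvReports, test = test)
}

#' Per-residue motif-start probabilities
#'
#' Applies a trained predictor to every residue of a sequence. When the
#' model was trained with subsampled negatives the raw MLP output is
#' calibrated back to the full-sequence prevalence with the standard
#' case-control intercept correction (logit shifted by the log of the
#' negative sampling fraction).
#'
#' @param model a [MotifPredictor-class].
#' @param features [ProfileFeatures-class] of the query.
#' @param def motif definition; must name the model's motif and carry the
#'   length the model was trained for.
#' @param flank window flank (default 5).
#' @return Numeric vector, one probability in `[0, 1]` per residue.
#' @export
predictResidueProbabilities <- function(model, features, def, flank = 5L) {
  stopifnot(methods::is(model, "MotifPredictor"))
  if (!identical(model@motif, def$name))
    stop(sprintf("model is for motif '%s', definition is '%s'",
                 model@motif, def$name))
  if (model@motifLength != def$length)
    stop(sprintf("model was trained for length %d but definition has length %d",
                 model@motifLength, def$length))
  X <- enumerateCandidates(features, def, flank)
  p <- as.numeric(.cpp_mlp_predict(model@weights, X))
  s <- model@negSamplingRate
  if (s < 1) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    p <- stats::plogis(stats::qlogis(p) + log(s))
  }
  p
}

#' Persist / restore a trained predictor
#'
#' Models round-trip bit-identically (same weights, hyperparameters,
#' sampling rate and feature-order tag). Loading rejects files that are
#' not model archives or carry an unknown format version.
#'
#' @param model a [MotifPredictor-class].
#' @param path file path.
#' @return `loadModel` returns the [MotifPredictor-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(methods::is(model, "MotifPredictor"))
  saveRDS(list(format = "NLRmotifs-model", version = model@version,
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read model archive '%s': %s", path,
                 conditionMessage(e))))
  if (!is.list(x) || !identical(x$format, "NLRmotifs-model"))
    stop("not a model archive")
  if (!identical(x$version, "1"))
    stop(sprintf("unsupported model format version '%s'", x$version))
  x$model
}
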