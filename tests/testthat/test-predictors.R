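reg <- defaultRegistry()

test_that("the 5-group split is balanced and deterministic", {
  expect_equal(sort(tabulate(splitGroups(makeSplit(10, 1)), 5)),
               rep(2L, 5))
  expect_equal(sort(tabulate(splitGroups(makeSplit(13, 3)), 5)),
               c(2L, 2L, 3L, 3L, 3L))
  expect_identical(makeSplit(57, 9)@groups, makeSplit(57, 9)@groups)
  expect_false(identical(makeSplit(57, 9)@groups, makeSplit(57, 10)@groups))
  expect_error(makeSplit(4, 1), "at least 5")
})

test_that("backpropagation gradients match finite differences", {
  set.seed(9)
  X <- matrix(rnorm(80), 16, 5)
  y <- rep(c(0, 1), 8)
  w <- NLRmotifs:::.cpp_mlp_train(X, y, X, y, c(4L, 3L), 0.01, 0.001, 8L,
                                  2L, 2L, 1e-9, 7L)$weights
  lg <- NLRmotifs:::.cpp_mlp_loss_grad(w, X, y, 0.001)
  eps <- 1e-6
  for (l in seq_along(w)) {
    for (k in sample(seq_along(w[[l]]$W), min(4, length(w[[l]]$W)))) {
      wp <- w; wp[[l]]$W[k] <- wp[[l]]$W[k] + eps
      wm <- w; wm[[l]]$W[k] <- wm[[l]]$W[k] - eps
      num <- (NLRmotifs:::.cpp_mlp_loss_grad(wp, X, y, 0.001)$loss -
                NLRmotifs:::.cpp_mlp_loss_grad(wm, X, y, 0.001)$loss) /
        (2 * eps)
      expect_equal(lg$grad[[l]]$W[k], num, tolerance = 1e-5)
    }
  }
})

test_that("a separable toy problem is solved perfectly; shuffled labels are not", {
  toy <- separableToy(200)
  def <- motifDefinition(reg, "LxxLxL")
  plan <- makeSplit(200, seed = 2)
  hp <- mlpHyperparams(hidden = c(64L, 32L, 16L), batchSize = 32L,
                       maxEpochs = 60L, seed = 3L)
  fit <- trainPredictor(toy$X, toy$y, def, hp, plan)
  expect_equal(fit$test@f1, 1.0)
  expect_length(fit$cv, 4L)
  ## seeded label shuffle destroys the association: F1 near prevalence
  yShuf <- withr::with_seed(8L, sample(toy$y))
  fitS <- trainPredictor(toy$X, yShuf, def, hp, plan)
  expect_lt(fitS$test@f1, 0.85)
  ## determinism: identical weights on retrain
  fit2 <- trainPredictor(toy$X, toy$y, def, hp, plan)
  expect_identical(fit$model@weights, fit2$model@weights)
})

test_that("training rejects malformed inputs", {
  toy <- separableToy(50)
  def <- motifDefinition(reg, "LxxLxL")
  plan <- makeSplit(50, seed = 1)
  expect_error(trainPredictor(toy$X[, 1:100], toy$y, def,
                              mlpHyperparams(), plan), "40\\*\\(L\\+10\\)")
  oneClass <- rep(1, 50)
  oneClass[splitGroups(plan) == 2] <- 1
  expect_error(trainPredictor(toy$X, oneClass, def, mlpHyperparams(), plan),
               "single class")
})

test_that("a trained predictor recovers planted motif starts per residue", {
  fx <- trainedPloop()
  g <- splitGroups(fx$plan)
  testIdx <- which(g == 5)
  probs <- lapply(testIdx, function(i)
    predictResidueProbabilities(fx$fit$model, fx$feats[[i]], fx$def))
  expect_true(all(vapply(probs, function(p) all(p >= 0 & p <= 1),
                         logical(1))))
  m <- evaluatePredictions(probs, fx$starts[testIdx])
  expect_gte(m@f1, 0.95)
  ## argmax sits at the planted start
  hits <- vapply(seq_along(testIdx), function(k)
    which.max(probs[[k]]) - 1L == fx$starts[[testIdx[k]]], logical(1))
  expect_true(all(hits))
})

test_that("model application is guarded by motif and dimensionality", {
  fx <- trainedPloop()
  lrr <- motifDefinition(reg, "LxxLxL")
  expect_error(predictResidueProbabilities(fx$fit$model, fx$feats[[1]], lrr),
               "motif")
  ## registry length override changes the expected input dimension
  reg2 <- defaultRegistry(lengths = c("P-loop" = 12L))
  expect_error(predictResidueProbabilities(fx$fit$model, fx$feats[[1]],
                                           motifDefinition(reg2, "P-loop")),
               "length")
})

test_that("model archives round-trip bit-identically", {
  fx <- trainedPloop()
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(fx$fit$model, f)
  back <- loadModel(f)
  p1 <- predictResidueProbabilities(fx$fit$model, fx$feats[[1]], fx$def)
  p2 <- predictResidueProbabilities(back, fx$feats[[1]], fx$def)
  expect_identical(p1, p2)
  corrupt <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", corrupt)
  expect_error(loadModel(corrupt), "model archive")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "NLRmotifs-model", version = "99",
               model = fx$fit$model), other)
  expect_error(loadModel(other), "version")
})

test_that("metric reports satisfy their closed-form identities", {
  m <- NLRmotifs:::metricsFromCounts(8, 2, 88, 2)
  expect_equal(m@precision, 0.8)
  expect_equal(m@recall, 0.8)
  expect_equal(m@f1, 0.8)
  expect_equal(m@specificity, 88 / 90, tolerance = 1e-4)
  expect_equal(m@g, 0.8)
  ## identities over random confusion tables
  withr::with_seed(31L, {
    for (r in 1:50) {
      cts <- sample(0:40, 4, replace = TRUE)
      mm <- NLRmotifs:::metricsFromCounts(cts[1], cts[2], cts[3], cts[4])
      expect_equal(mm@g^2, mm@precision * mm@recall, tolerance = 1e-12)
      if (mm@precision + mm@recall > 0)
        expect_equal(mm@f1, 2 * mm@precision * mm@recall /
                       (mm@precision + mm@recall), tolerance = 1e-12)
    }
  })
  ## degenerate: nothing predicted positive
  m0 <- evaluatePredictions(rep(0.1, 20), integer(0), threshold = 0.5)
  expect_equal(m0@precision, 0)
  expect_true("no-positive-predictions" %in% m0@flags)
})

test_that("raising the threshold trades recall for precision monotonically", {
  withr::with_seed(13L, {
    p <- runif(400)
    true <- sort(sample(0:399, 40))
  })
  prev <- NULL
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    m <- evaluatePredictions(p, true, threshold = thr)
    if (!is.null(prev)) {
      expect_lte(m@recall, prev@recall + 1e-12)  # recall never increases
      expect_lte(m@fp, prev@fp)                  # false calls never increase
      expect_lte(m@tp, prev@tp)
    }
    prev <- m
  }
})

test_that("positional tolerance relaxes exact-position scoring", {
  p <- rep(0, 30); p[11] <- 0.9       # predicted start at 0-based 10
  expect_equal(evaluatePredictions(p, 11L)@tp, 0)
  expect_equal(evaluatePredictions(p, 11L, tolerance = 1L)@tp, 1)
})
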