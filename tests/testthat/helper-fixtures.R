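## Shared fixtures, built in code and cached for the session.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, builder(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

## A small focused database with archetype families.
tinyDb <- function() fixture("tinyDb", function() {
  generateFocusedDb(nNlr = 30L, nLrr = 20L, seed = 7L,
                    copiesPerArchetype = 10L)
})

## Exact-copy profile fixture: a query with 10 identical homologs plus
## unrelated sequences in the database.
copyFixture <- function() fixture("copyFixture", function() {
  q <- withr::with_seed(11L, paste(sample(NLRmotifs:::AA20, 60,
                                          replace = TRUE), collapse = ""))
  extra <- withr::with_seed(12L, replicate(5, paste(
    sample(NLRmotifs:::AA20, 80, replace = TRUE), collapse = "")))
  db <- Biostrings::AAStringSet(c(rep(q, 10), extra))
  names(db) <- sprintf("s%02d", seq_along(db))
  list(query = q, db = db)
})

## A trained P-loop predictor on a small labeled dataset, with per-sequence
## features and the split kept for evaluation.
trainedPloop <- function() fixture("trainedPloop", function() {
  reg <- defaultRegistry()
  def <- motifDefinition(reg, "P-loop")
  ds <- generateMotifDataset(def, n = 80, mu = 0.10, seed = 42, len = 150)
  feats <- profileFeaturesSet(ds$sequences, tinyDb())
  starts <- as.list(ds$truth$start)
  ts <- buildTrainingSet(feats, starts, def, negPerPos = 12, seed = 1)
  plan <- makeSplit(length(feats), seed = 1)
  fit <- trainPredictor(ts, def = def,
                        hp = mlpHyperparams(maxEpochs = 60L, seed = 1L),
                        split = plan)
  list(def = def, ds = ds, feats = feats, starts = starts, ts = ts,
       plan = plan, fit = fit)
})

## Separable toy window set at LxxLxL dimensionality (640): two shifted
## Gaussian clouds, labels by cloud.
separableToy <- function(n = 200L, shift = 4) {
  withr::with_seed(5L, {
    d <- 640L
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(stats::rnorm(n * d, sd = 1), n, d)
    X[y == 1, 1:20] <- X[y == 1, 1:20] + shift
    list(X = X, y = y)
  })
}
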