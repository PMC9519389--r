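reg <- defaultRegistry()

test_that("noise-free motif datasets plant exactly one conforming window", {
  def <- motifDefinition(reg, "EDVID")
  ds <- generateMotifDataset(def, n = 15, mu = 0, seed = 4, len = 200)
  expect_length(ds$sequences, 15L)
  for (i in seq_len(15)) {
    seq <- as.character(ds$sequences[[i]])
    hits <- NLRmotifs:::consensusScan(seq, def)
    expect_equal(hits, ds$truth$start[i])   # unique, at the planted start
  }
  ## determinism
  ds2 <- generateMotifDataset(def, n = 15, mu = 0, seed = 4, len = 200)
  expect_identical(as.character(ds$sequences), as.character(ds2$sequences))
  expect_error(generateMotifDataset(def, n = 5, seed = 1), ">= 10")
})

test_that("heavy noise erodes consensus conformance of planted windows", {
  def <- motifDefinition(reg, "LxxLxL")
  conformance <- function(mu) {
    ds <- generateMotifDataset(def, n = 60, mu = mu, seed = 8, len = 80)
    mean(vapply(seq_len(60), function(i) {
      w <- substr(as.character(ds$sequences[[i]]), ds$truth$start[i] + 1,
                  ds$truth$start[i] + 6)
      matchesConsensus(w, def)
    }, logical(1)))
  }
  expect_equal(conformance(0), 1)
  full <- conformance(1)
  ## with every position resampled, conformance drops to the background
  ## rate of an unconstrained 6-mer (hydrophobic^3 ~ 0.1)
  expect_lt(full, 0.35)
})

test_that("synthetic NLRs carry consistent ground truth", {
  for (lay in c("CNL", "TNL", "NL")) {
    nlr <- generateNlr(lay, seed = 31, id = "t")
    truth <- nlr$truth
    expect_equal(truth$class, lay)
    ## every planted labeled window conforms at mu = 0
    for (r in seq_len(nrow(truth$calls))) {
      def <- motifDefinition(reg, truth$calls$motif[r])
      w <- substr(nlr$seq, truth$calls$start[r] + 1,
                  truth$calls$start[r] + def$length)
      expect_true(matchesConsensus(w, def),
                  label = paste(lay, truth$calls$motif[r]))
    }
    ## the LxxLxL scan finds the ladder (plus injected satellites); the
    ## only other conforming windows sit inside planted motifs whose own
    ## anchors are hydrophobic (LxxLxL is that degenerate by design)
    hits <- NLRmotifs:::consensusScan(nlr$seq,
                                      motifDefinition(reg, "LxxLxL"))
    expect_true(all(c(truth$ladderStarts, truth$satellites) %in% hits))
    extras <- setdiff(hits, c(truth$ladderStarts, truth$satellites))
    insidePlanted <- vapply(extras, function(s) {
      any(vapply(seq_len(nrow(truth$calls)), function(r) {
        L <- motifDefinition(reg, truth$calls$motif[r])$length
        s >= truth$calls$start[r] - 5L & s < truth$calls$start[r] + L
      }, logical(1)))
    }, logical(1))
    expect_true(all(insidePlanted))
  }
  ## deterministic under seed
  a <- generateNlr("CNL", seed = 9, id = "a")
  b <- generateNlr("CNL", seed = 9, id = "a")
  expect_identical(a$seq, b$seq)
})

test_that("generator knobs drive the downstream rules", {
  ## an oversized linker is rejected by ladder delineation
  long <- generateNlr("NL", seed = 12, id = "l", linker = 60L)
  annL <- annotateSequence(long$seq, "l", backend = "consensus")
  expect_false(annL$ladder$accepted)
  expect_equal(annL$ladder$reason, "linker")
  ## satellite decoys appear within 6-14 residues of a true start
  sat <- generateNlr("NL", seed = 13, id = "s", satelliteRate = 1,
                     repeatLenRange = c(24L, 36L))
  expect_gt(length(sat$truth$satellites), 0)
  d <- vapply(sat$truth$satellites, function(s)
    min(s - sat$truth$ladderStarts[sat$truth$ladderStarts < s]), numeric(1))
  expect_true(all(d >= 6 & d <= 14))
})

test_that("the focused database mirrors the curated-set shape", {
  db <- tinyDb()
  expect_equal(length(db), 50L)
  w <- Biostrings::width(db)
  isNlr <- grepl("^nlrA", names(db))
  expect_true(all(w[isNlr] >= 500))
  expect_true(all(w[!isNlr] >= 200))
  ## two copies of one archetype stay recognisably homologous at mu = 0.2
  fam <- which(names(db) %in% c("nlrA01_c01", "nlrA01_c02"))
  a <- strsplit(as.character(db[[fam[1]]]), "")[[1]]
  b <- strsplit(as.character(db[[fam[2]]]), "")[[1]]
  n <- min(length(a), length(b))
  expect_gte(mean(a[1:n] == b[1:n]), 0.60)
  ## determinism
  db2 <- generateFocusedDb(nNlr = 30L, nLrr = 20L, seed = 7L,
                           copiesPerArchetype = 10L)
  expect_identical(names(db2), names(db))
  expect_identical(as.character(db2), as.character(db))
})

test_that("planted LRR classes and covarying alignments are reproducible", {
  a <- generatePlantedLrrClasses(3, 50, seed = 6)
  b <- generatePlantedLrrClasses(3, 50, seed = 6)
  expect_identical(a, b)
  expect_equal(unique(nchar(a$windows)), 6L)
  expect_equal(sort(unique(a$labels)), 1:3)
  expect_error(generatePlantedLrrClasses(7, 10, seed = 1), "at most 6")
  x <- generateCovaryingAlignment(50, 10, pair = c(2L, 9L), coupling = 1,
                                  seed = 2)
  y <- generateCovaryingAlignment(50, 10, pair = c(2L, 9L), coupling = 1,
                                  seed = 2)
  expect_identical(x, y)
  ## at full coupling the planted pair is deterministic: maximal MI
  mi <- weightedMutualInformation(x$alignment,
                                  weights = rep(1 / 50, 50),
                                  pseudocountMass = 0)
  ut <- which(upper.tri(mi$mi), arr.ind = TRUE)
  best <- ut[which.max(mi$mi[upper.tri(mi$mi)]), ]
  expect_equal(unname(best), c(2L, 9L))
  expect_error(generateCovaryingAlignment(10, 5, pair = c(1L, 7L)),
               "inside")
})
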