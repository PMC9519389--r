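test_that("Henikoff weights down-weight redundant rows", {
  expect_equal(henikoffWeights(c("AAAA", "AAAA", "AAAA")), rep(1 / 3, 3))
  ## hand-computed 2-column toy: rows AA, AA, CC
  ## each column: 2 distinct residues; A carried by 2 rows -> 1/(2*2);
  ## C by one row -> 1/2. Row sums (0.5, 0.5, 1) normalise to (.25,.25,.5).
  w <- henikoffWeights(c("AA", "AA", "CC"))
  expect_equal(w, c(0.25, 0.25, 0.5))
  expect_gt(w[3], w[1])
  expect_equal(sum(w), 1)
  expect_error(henikoffWeights("AA"), "at least 2")
})

test_that("mutual information finds dependence and respects symmetry", {
  ## two perfectly covarying binary columns at zero pseudocount: MI = ln 2
  rows <- c(rep("AC", 25), rep("CD", 25))
  mi0 <- weightedMutualInformation(rows, weights = rep(1 / 50, 50),
                                   pseudocountMass = 0)
  expect_equal(mi0$mi[1, 2], log(2), tolerance = 1e-12)
  expect_equal(mi0$mi[1, 2], mi0$mi[2, 1])
  ## independent background columns: MI near zero at large n
  al <- generateCovaryingAlignment(600, 6, pair = c(1L, 2L), coupling = 0,
                                   seed = 3)
  mi <- weightedMutualInformation(al$alignment)
  off <- mi$mi[upper.tri(mi$mi)]
  expect_lt(max(off), 0.35)        # sampling bias only
  expect_true(all(off >= 0 | abs(off) < 1e-9))
  ## row permutation invariance
  perm <- withr::with_seed(5L, sample(length(al$alignment)))
  miP <- weightedMutualInformation(al$alignment[perm])
  expect_equal(miP$mi, mi$mi, tolerance = 1e-9)
})

test_that("pseudocount mass shrinks sparse-column MI toward zero", {
  rows <- c(rep("AC", 4), rep("CD", 4))
  w <- rep(1 / 8, 8)
  vals <- vapply(c(0, 0.5, 1, 2, 4), function(pc)
    weightedMutualInformation(rows, w, pseudocountMass = pc)$mi[1, 2],
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_gt(vals[1], vals[5])
})

test_that("Z-scores single out the planted pair; boundary is inclusive", {
  al <- generateCovaryingAlignment(500, 20, pair = c(3L, 11L),
                                   coupling = 0.9, seed = 5)
  mi <- miZscores(weightedMutualInformation(al$alignment))
  expect_equal(c(mi$pairs$i[1], mi$pairs$j[1]), c(3L, 11L))
  expect_gte(mi$pairs$z[1], 3.5)
  ## boundary: a pair with Z exactly at the cutoff is significant
  zmax <- max(mi$z, na.rm = TRUE)
  miB <- miZscores(list(mi = mi$mi), cutoff = zmax)
  expect_equal(nrow(miB$pairs), 1L)
  ## degenerate constant matrix: no significant pairs, flagged
  const <- list(mi = matrix(0.5, 4, 4))
  md <- miZscores(const)
  expect_true(md$degenerate)
  expect_equal(nrow(md$pairs), 0L)
})

test_that("cumulative and proximity MI summarise significant pairs", {
  mi <- matrix(0, 5, 5)
  mi[2, 4] <- mi[4, 2] <- 0.8
  fake <- list(mi = mi,
               pairs = data.frame(i = 2L, j = 4L, mi = 0.8, z = 5))
  cp <- cumulativeProximityMi(fake)
  expect_equal(cp$cumulative, c(0, 0.8, 0, 0.8, 0))
  expect_null(cp$proximity)
  contacts <- data.frame(i = c(1L, 2L), j = c(2L, 4L))
  cp2 <- cumulativeProximityMi(fake, contacts)
  expect_equal(cp2$proximity[1], 0.8)      # singleton neighbour set {2}
  expect_equal(cp2$proximity[2], mean(c(0, 0.8)))
  expect_error(cumulativeProximityMi(fake, data.frame(i = 1L, j = 9L)),
               "outside")
  ## no significant pairs: cumulative identically zero
  none <- list(mi = mi, pairs = data.frame(i = integer(0), j = integer(0),
                                           mi = numeric(0), z = numeric(0)))
  expect_equal(cumulativeProximityMi(none)$cumulative, rep(0, 5))
})

test_that("significant pairs are partitioned by 3D support", {
  pairs <- data.frame(i = c(1L, 2L, 3L), j = c(5L, 6L, 7L))
  empty <- data.frame(i = integer(0), j = integer(0))
  expect_equal(mapPairsToContacts(pairs, empty)$support,
               rep("unsupported", 3))
  contacts <- data.frame(i = 2L, j = 6L)
  expect_equal(mapPairsToContacts(pairs, contacts)$support,
               c("unsupported", "supported", "unsupported"))
  off <- data.frame(pos = c(1L, 2L, 5L, 6L), ref = c(11L, 12L, 15L, 16L))
  m <- mapPairsToContacts(pairs, data.frame(i = 12L, j = 16L),
                          offsetMap = off)
  expect_equal(m$support, c("unsupported", "supported", "unmapped"))
})

test_that("contact maps load from TSV and from coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("i\tj\tdistance", "1\t5\t4.2", "2\t6\t7.0", "3\t3\t1.0"), f)
  cm <- readContactMap(f)
  expect_equal(nrow(cm), 1L)       # distance filter and self-pair removal
  expect_equal(c(cm$i, cm$j), c(1L, 5L))
  coords <- data.frame(pos = 1:3, x = c(0, 3, 40), y = 0, z = 0)
  cc <- contactsFromCoords(coords, cutoff = 5)
  expect_equal(nrow(cc), 1L)
  expect_equal(c(cc$i, cc$j), c(1L, 2L))
})
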