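reg <- defaultRegistry()

nbsChimeraFixture <- function(n = 6, seed = 50) {
  out <- lapply(seq_len(n), function(i) {
    nlr <- generateNlr("NL", seed = seed + i, id = sprintf("n%02d", i))
    exciseChimera(nlr$seq, nlr$truth$calls, motifs = motifNames(reg, "NBS"),
                  registry = reg)
  })
  names(out) <- sprintf("n%02d", seq_len(n))
  out
}

test_that("chimeras concatenate flanked motifs in registry order", {
  chims <- nbsChimeraFixture(2)
  lens <- registryTable(reg)
  nbsLen <- sum(lens$length[lens$domain == "NBS"])
  for (ch in chims) {
    expect_equal(nchar(ch$chimera), nbsLen + 9 * 10)     # sum(L_i) + 90
    expect_length(ch$boundaries, 10L)                    # 9 segments + 1
    expect_equal(names(ch$segments), motifNames(reg, "NBS"))
  }
  ## a motif at the sequence start gets an X left flank
  ann <- data.frame(seqid = "s", motif = "P-loop", start = 0L)
  ch <- exciseChimera("GMGGLGKTTAAAA", ann, motifs = "P-loop",
                      registry = reg)
  expect_equal(substr(ch$chimera, 1, 5), "XXXXX")
  ## CNL chimera: EDVID + 9 NBS + first 5 LRR = 15 segments
  cnl <- generateNlr("CNL", seed = 123, id = "c", nRepeats = 9)
  calls <- cnl$truth$calls
  lrr5 <- calls[calls$motif == "LxxLxL", ][1:5, ]
  ann15 <- rbind(calls[calls$motif != "LxxLxL", ], lrr5)
  ch15 <- exciseChimera(cnl$seq, ann15,
                        motifs = c("EDVID", motifNames(reg, "NBS"), "LxxLxL"),
                        registry = reg)
  expect_length(ch15$boundaries, 16L)
  expect_error(exciseChimera(cnl$seq, calls[calls$motif != "P-loop", ],
                             motifs = motifNames(reg, "NBS"),
                             registry = reg), "exactly once")
})

test_that("identity clustering uses connected components", {
  ## two identical chimeras always cluster at any threshold
  cc <- clusterByIdentity(c(a = "AAAAAAA", b = "AAAAAAA"), threshold = 0.55)
  expect_equal(unname(cc$labels), c(0L, 0L))
  ## transitivity: A~B and B~C at 60%, A~C only 30%: one component
  a <- "AAAAAAAAAA"
  b <- "AAAAAABBBB"   # 60% to a
  c_ <- "AAAAABBBBB"  # 90% to b, 50% to a
  cc2 <- clusterByIdentity(c(A = a, B = b, C = c_), threshold = 0.55)
  expect_equal(length(unique(cc2$labels)), 1L)
  expect_lt(cc2$identity["A", "C"], 0.55)
  ## mixed layouts refuse to compare
  expect_error(clusterByIdentity(c("AAAA", "AAAAA")), "mixed layouts")
})

test_that("threshold 1.0 reduces to exact-string grouping", {
  withr::with_seed(61L, {
    pool <- replicate(4, paste(sample(NLRmotifs:::AA20, 30, replace = TRUE),
                               collapse = ""))
    strings <- sample(pool, 12, replace = TRUE)
  })
  names(strings) <- sprintf("s%02d", 1:12)
  cc <- clusterByIdentity(strings, threshold = 1.0)
  oracle <- as.integer(factor(strings, levels = unique(strings))) - 1L
  ## same partition (labels may permute)
  expect_equal(length(unique(cc$labels)), length(unique(oracle)))
  expect_true(all(tapply(cc$labels, oracle,
                         function(v) length(unique(v))) == 1L))
})

test_that("relative entropy measures divergence from background in bits", {
  expect_equal(columnRelativeEntropy(c("G", "G", "G"))[1],
               -log2(backgroundFrequencies()[["G"]]), tolerance = 1e-9)
  ## never negative, and shuffled background columns tend to 0
  withr::with_seed(41L, {
    col <- NLRmotifs:::sampleBackground(3000)
    re <- columnRelativeEntropy(matrix(col, ncol = 1))
  })
  expect_gte(re, 0)
  expect_lt(re, 0.02)
  withr::with_seed(42L, {
    m <- matrix(NLRmotifs:::sampleBackground(50 * 8), 50, 8)
    expect_true(all(columnRelativeEntropy(m) >= 0))
  })
  ## logo matrix heights sum to the column relative entropy
  lm <- logoMatrix(c("GGA", "GGC", "GGA"))
  expect_equal(rowSums(lm), columnRelativeEntropy(c("GGA", "GGC", "GGA")),
               tolerance = 1e-9)
})

test_that("the physico-chemical embedding maps windows to 18 descriptors", {
  emb <- lrrEmbedding(c("LADLSL", "KADLSL", "RADLSL"), standardize = FALSE)
  expect_equal(dim(emb), c(3L, 18L))
  charge <- emb[, grep("charge", colnames(emb))]
  expect_equal(unname(charge[1, ]), c(0, 0, -1, 0, 0, 0))  # D at position 2
  expect_equal(charge[2, 1], charge[3, 1])   # K and R share +1 at position 0
  expect_equal(emb[2, -(1:3)], emb[3, -(1:3)])
  expect_identical(lrrEmbedding(c("LADLSL"), standardize = FALSE),
                   lrrEmbedding(c("LADLSL"), standardize = FALSE))
  expect_error(lrrEmbedding("LADLS"), "length 6")
  ## X residues take the descriptor means
  xe <- lrrEmbedding(c("XADLSL"), standardize = FALSE)
  expect_equal(unname(xe[1, 1]), mean(aaHydropathy()))
})

test_that("OPTICS/Xi recovers planted charge classes and respects blobs", {
  cl <- generatePlantedLrrClasses(3, 150, seed = 2)
  res <- clusterLrrMotifs(lrrEmbedding(cl$windows), minSamples = 20)
  expect_equal(length(setdiff(unique(res$labels), -1L)), 3L)
  expect_gte(mclust::adjustedRandIndex(res$labels, cl$labels), 0.9)
  ## a single Gaussian blob yields at most one cluster
  blob <- withr::with_seed(3L, matrix(rnorm(300 * 6), 300, 6))
  rb <- opticsXi(blob, minSamples = 20, xi = 0.05)
  expect_lte(length(setdiff(unique(rb$labels), -1L)), 1L)
  ## single planted class: never more than one non-noise cluster
  one <- generatePlantedLrrClasses(1, 200, seed = 4)
  r1 <- clusterLrrMotifs(lrrEmbedding(one$windows), minSamples = 20)
  expect_lte(length(setdiff(unique(r1$labels), -1L)), 1L)
  ## determinism on identical input
  res2 <- clusterLrrMotifs(lrrEmbedding(cl$windows), minSamples = 20)
  expect_identical(res$labels, res2$labels)
  expect_error(opticsXi(blob[1:5, ], minSamples = 20), "minSamples")
})

test_that("ladder distributions normalise vertically to 100%", {
  labels <- c(0L, 0L, 1L, 1L, 0L, 1L, -1L, 0L)
  ladder <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 25L)
  d <- ladderDistribution(labels, ladder, maxPos = 20L)
  expect_true(all(abs(colSums(d) - 100) < 1e-9))
  expect_true("N+" %in% colnames(d))
  expect_equal(d["0", "N+"], 100)
  ## all repeats in one cluster: that row is 100 everywhere
  d1 <- ladderDistribution(rep(0L, 6), rep(1:3, 2))
  expect_true(all(d1["0", ] == 100))
  ## 50/50 split at position 1
  d2 <- ladderDistribution(c(0L, 1L), c(1L, 1L))
  expect_equal(unname(d2[, "1"]), c(50, 50))
  expect_error(ladderDistribution(labels, c(ladder[-1], NA)), "ladder index")
})
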