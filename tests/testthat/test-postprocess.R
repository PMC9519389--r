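reg <- defaultRegistry()

test_that("motif calling fires at local maxima strictly above 80%", {
  p <- rep(0.1, 30); p[15] <- 0.95
  calls <- callMotifs(p, "s", "P-loop")
  expect_equal(calls$start, 14L)
  expect_equal(calls$prob, 0.95)
  ## a peak of exactly 0.80 is not called (strict inequality)
  p80 <- rep(0.1, 30); p80[15] <- 0.80
  expect_equal(nrow(callMotifs(p80, "s", "P-loop")), 0L)
  expect_equal(nrow(callMotifs(p80, "s", "P-loop", threshold = 0.79)), 1L)
})

test_that("plateaus are called once, at their leftmost position", {
  for (width in 1:4) {
    for (at in c(1L, 5L, 26L)) {
      p <- rep(0.2, 30)
      span <- at:min(30L, at + width - 1L)
      p[span] <- 0.9
      calls <- callMotifs(p, "s", "LxxLxL")
      expect_equal(calls$start, at - 1L,
                   label = sprintf("width %d at %d", width, at))
    }
  }
})

test_that("satellite resolution follows the 15 aa / 20% rule", {
  mk <- function(starts, probs)
    data.frame(seqid = "s", motif = "LxxLxL", start = starts, prob = probs)
  ## clear margin: keep only the stronger call
  r1 <- resolveSatellites(mk(c(100L, 108L), c(0.95, 0.70)))
  expect_equal(r1$start, 100L)
  ## within margin: both kept, flagged ambiguous
  r2 <- resolveSatellites(mk(c(100L, 108L), c(0.90, 0.85)))
  expect_equal(r2$start, c(100L, 108L))
  expect_true(all(r2$ambiguous))
  ## a difference of exactly 20% stays ambiguous ("surpasses 20%")
  r2b <- resolveSatellites(mk(c(100L, 108L), c(0.90, 0.70)))
  expect_equal(nrow(r2b), 2L)
  ## outside the window: untouched and unflagged
  r3 <- resolveSatellites(mk(c(100L, 120L), c(0.95, 0.70)))
  expect_equal(r3$start, c(100L, 120L))
  expect_false(any(r3$ambiguous))
  ## idempotent
  expect_equal(resolveSatellites(r2[names(r2) != "ambiguous"]), r2)
  ## chains collapse onto the strongest call
  r4 <- resolveSatellites(mk(c(100L, 108L, 116L), c(0.95, 0.60, 0.85)))
  expect_equal(r4$start, c(100L, 116L))
})

test_that("NBS layout validation demands all nine motifs once, in order", {
  nbs <- motifNames(reg, "NBS")
  mk <- function(motifs, starts)
    data.frame(seqid = "s", motif = motifs, start = starts,
               prob = 0.9)
  good <- mk(nbs, seq(0, by = 40, length.out = 9))
  v <- validateNbsLayout(good, reg)
  expect_true(v$valid)
  expect_length(v$reasons, 0L)
  ## MHD before GLPL
  sw <- good
  sw$start[sw$motif == "MHD"] <- 200L
  sw$start[sw$motif == "GLPL"] <- 320L
  v2 <- validateNbsLayout(sw, reg)
  expect_false(v2$valid)
  expect_true("disordered:GLPL|RNBS-D" %in% v2$reasons ||
                "disordered:RNBS-D|MHD" %in% v2$reasons ||
                "disordered:GLPL|MHD" %in% v2$reasons)
  ## duplicated P-loop
  dup <- rbind(good, mk("P-loop", 500L))
  v3 <- validateNbsLayout(dup, reg)
  expect_false(v3$valid)
  expect_true("duplicated:P-loop" %in% v3$reasons)
  ## missing motif
  v4 <- validateNbsLayout(good[good$motif != "VG", ], reg)
  expect_true("missing:VG" %in% v4$reasons)
})

test_that("only the identity ordering of the nine starts validates", {
  nbs <- motifNames(reg, "NBS")
  starts <- seq(10, by = 35, length.out = 9)
  withr::with_seed(17L, {
    perms <- c(list(1:9), lapply(1:40, function(i) sample(9)))
  })
  ## plus all adjacent transpositions
  for (i in 1:8) {
    p <- 1:9; p[c(i, i + 1)] <- p[c(i + 1, i)]
    perms[[length(perms) + 1]] <- p
  }
  for (p in perms) {
    calls <- data.frame(seqid = "s", motif = nbs[p], start = starts,
                        prob = 0.9)
    v <- validateNbsLayout(calls, reg)
    expect_equal(v$valid, all(p == sort(p)),
                 label = paste(p, collapse = ","))
  }
})

test_that("LRR ladder delineation enforces linker, spacing and count rules", {
  nbs <- motifNames(reg, "NBS")
  nbsCalls <- data.frame(seqid = "s", motif = nbs,
                         start = seq(0, by = 40, length.out = 9), prob = 0.9)
  ann <- validateNbsLayout(nbsCalls, reg)
  mhdEnd <- 320 + 3
  mkLadder <- function(starts)
    data.frame(seqid = "s", motif = "LxxLxL", start = starts, prob = 0.9)
  ## 10 starts spaced 24 aa, linker 30: accepted
  starts <- mhdEnd + 30 + 24 * (0:9)
  lad <- delineateLrrLadder(mkLadder(starts), ann)
  expect_true(lad$accepted)
  expect_equal(lad$ladderIndex, 1:10)
  expect_equal(lad$repeatLengths, rep(24L, 9L))
  ## 12 aa between repeats 3 and 4
  bad <- starts; bad[4:10] <- bad[4:10] - 12L
  lad2 <- delineateLrrLadder(mkLadder(bad), ann)
  expect_false(lad2$accepted)
  expect_equal(lad2$reason, "short-repeat:3")
  ## linker of 60 (>= 50) is rejected
  lad3 <- delineateLrrLadder(mkLadder(starts + 30), ann)
  expect_false(lad3$accepted)
  expect_equal(lad3$reason, "linker")
  ## too few repeats under the 9-repeat rule, fine under the CNL 5-rule
  five <- mkLadder(mhdEnd + 20 + 24 * (0:4))
  expect_false(delineateLrrLadder(five, ann)$accepted)
  expect_true(delineateLrrLadder(five, ann, minRepeats = 5L)$accepted)
  ## spacing outside [15, 50] is never accepted
  wide <- mkLadder(mhdEnd + 20 + c(0, 24, 80, 104, 128, 152, 176, 200, 224))
  expect_false(delineateLrrLadder(wide, ann)$accepted)
  expect_match(delineateLrrLadder(wide, ann)$reason, "long-repeat")
})

test_that("NLR classification integrates N-terminal and NBS evidence", {
  nbs <- motifNames(reg, "NBS")
  base <- data.frame(seqid = "s", motif = nbs,
                     start = seq(100, by = 40, length.out = 9), prob = 0.9)
  expect_equal(classifyNlr(base, reg)$class, "NL")
  cnl <- rbind(data.frame(seqid = "s", motif = "EDVID", start = 20L,
                          prob = 0.95), base)
  expect_equal(classifyNlr(cnl, reg)$class, "CNL")
  tir <- rbind(data.frame(seqid = "s", motif = motifNames(reg, "TIR"),
                          start = seq(5, by = 15, length.out = 6),
                          prob = 0.9), base)
  expect_equal(classifyNlr(tir, reg)$class, "TNL")
  ## TIR precedence over CC, flagged
  both <- rbind(tir, data.frame(seqid = "s", motif = "EDVID", start = 95L,
                                prob = 0.9))
  cb <- classifyNlr(both, reg)
  expect_equal(cb$class, "TNL")
  expect_true("both-cc-tir" %in% cb$flags)
  ## EDVID downstream of the NBS: shuffled layout
  shuf <- rbind(base, data.frame(seqid = "s", motif = "EDVID", start = 600L,
                                 prob = 0.9))
  cs <- classifyNlr(shuf, reg)
  expect_equal(cs$class, "other")
  expect_true("shuffled" %in% cs$flags)
  ## invalid NBS: other
  expect_equal(classifyNlr(base[-1, ], reg)$class, "other")
})

test_that("consensus scoring exercises the whole pipeline faithfully", {
  nlr <- generateNlr("CNL", seed = 77, id = "c1")
  ann <- annotateSequence(nlr$seq, "c1", backend = "consensus")
  expect_equal(ann$class, "CNL")
  expect_true(ann$nbs$valid)
  truthNbs <- nlr$truth$calls[nlr$truth$calls$motif %in%
                                motifNames(reg, "NBS"), ]
  got <- ann$nbs$calls
  expect_equal(got$start[match(truthNbs$motif, got$motif)], truthNbs$start)
  expect_equal(ann$ladder$starts, nlr$truth$ladderStarts)
})
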