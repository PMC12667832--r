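test_that("homopolymer masking matches an independent run-length scan", {
  expect_true(maskHomopolymer(2L, "GAAAAAG", runLen = 4))
  expect_false(maskHomopolymer(2L, "ACGTACG", runLen = 4))
  expect_error(maskHomopolymer(10L, "ACGT"), "outside")
  set.seed(201)
  s <- randomSeq(2000)
  pos <- 0:(nchar(s) - 1L)
  got <- maskHomopolymer(pos, s, runLen = 4)
  # independent scan with rle
  r <- rle(strsplit(s, "")[[1]])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  want <- rep(FALSE, nchar(s))
  for (u in which(r$lengths >= 4)) {
    lo <- max(1L, starts[u] - 1L); hi <- min(nchar(s), ends[u] + 1L)
    want[lo:hi] <- TRUE
  }
  expect_equal(got, want[pos + 1L])
})

test_that("strand-bias predicate matches exhaustive enumeration", {
  expect_true(maskStrandBias(strandBiasTable(c(0, 0, 1, 1, 1),
                                             c("+", "+", "-", "-", "-"))))
  expect_false(maskStrandBias(strandBiasTable(c(0, 0, 1, 1),
                                              c("+", "-", "-", "-"))))
  # exhaustive truth table over all phase/strand assignments of <= 6 reads
  for (K in 2:6) {
    grid_ph <- expand.grid(rep(list(c(0L, 1L)), K))
    grid_st <- expand.grid(rep(list(c("+", "-")), K), stringsAsFactors = FALSE)
    set.seed(202 + K)
    # full truth table for K <= 4; random subsample above
    idx <- if (K <= 4) seq_len(nrow(grid_ph) * nrow(grid_st)) else
      sample(nrow(grid_ph) * nrow(grid_st), 400)
    for (u in idx) {
      i <- (u - 1L) %% nrow(grid_ph) + 1L
      j <- (u - 1L) %/% nrow(grid_ph) + 1L
      ph <- as.integer(grid_ph[i, ]); st <- as.character(grid_st[j, ])
      want <- {
        s0 <- st[ph == 0L]; s1 <- st[ph == 1L]
        length(s0) > 0 && length(s1) > 0 &&
          ((all(s0 == "+") && all(s1 == "-")) ||
           (all(s0 == "-") && all(s1 == "+")))
      }
      expect_identical(maskStrandBias(strandBiasTable(ph, st)), want)
    }
  }
})

test_that("low-quality bases are reassigned to * and exhausted sites dropped", {
  pt <- fig1cTable()
  pt@quals[2, 4] <- 5L   # z's first carrier
  out <- maskLowQuality(pt)
  expect_equal(sitePhases(out)[2, 4], NA_integer_)
  expect_equal(length(sitePositions(out)), 6L)
  # drop the only phase-1 read of site t -> site disappears
  pt2 <- fig1cTable()
  pt2@quals[4, 6] <- 3L
  out2 <- maskLowQuality(pt2)
  expect_equal(length(sitePositions(out2)), 5L)
  expect_false(40L %in% sitePositions(out2))
  # unchanged when all qualities pass
  out3 <- maskLowQuality(fig1cTable())
  expect_equal(sitePhases(out3), sitePhases(fig1cTable()))
  # re-count oracle on simulated data: dropped sites equal an independent scan
  fx <- smallSim()
  reads <- simReads(fx$sim)
  ovl <- findReadOverlaps(reads)
  pil <- phasingTable(buildPileup(ovl, 2, reads = reads), minAlt = 1L)
  out4 <- maskLowQuality(pil, 10L)
  ph <- sitePhases(pil); q <- pil@quals
  ph[!is.na(q) & q < 10L & !is.na(ph)] <- NA_integer_
  keep <- rowSums(ph == 1L, na.rm = TRUE) > 0L
  expect_equal(sitePositions(out4), sitePositions(pil)[keep])
})

test_that("site compatibility follows its definition on hand-built vectors", {
  expect_true(sitesCompatible(c(0L, 1L, NA), c(0L, 1L, 0L)))
  expect_false(sitesCompatible(c(0L, 1L, 1L), c(1L, 1L, 1L), maxConflict = 0L))
  expect_true(sitesCompatible(c(0L, NA, NA), c(NA, NA, 1L), 0L, 0L))
  expect_false(sitesCompatible(c(0L, NA, NA), c(NA, NA, 1L), 1L, 0L))
  expect_error(sitesCompatible(c(0L, 1L), c(0L, 1L, 1L)), "equal length")
})

test_that("the LCG recurrence solves the worked diploid example", {
  pt <- fig1cTable()
  dp <- computeLCG(pt, minShared = 2L, minShared1 = 1L, maxConflict = 0L)
  expect_equal(lcgScores(dp), c(1L, 1L, 2L, 1L, 3L, 4L))
  expect_equal(lcgPred(dp), c(NA, NA, 1L, NA, 3L, 5L))
  expect_equal(which.max(lcgScores(dp)), 6L)  # the chain ends at site n
  dp <- tracebackGroups(dp, pt)
  expect_equal(siteClusters(dp), list(c(1L, 3L, 5L, 6L)))
  # N = 1 and N = 0 degenerate cases
  one <- .subsetSitesForTest(pt, 1L)
  d1 <- computeLCG(one, 0L, 0L)
  expect_equal(lcgScores(d1), 1L)
  expect_equal(lcgPred(d1), NA_integer_)
  empty <- .subsetSitesForTest(pt, integer())
  expect_equal(length(lcgScores(computeLCG(empty))), 0L)
})

test_that("traceback separates the three-haplotype clusters", {
  pt <- fig1dTable()
  dp <- tracebackGroups(figPhase(pt), pt)
  expect_equal(siteClusters(dp), list(c(2L, 4L), c(1L, 3L)))
  # all sites mutually incompatible -> no clusters
  inc <- fig1dTable()
  inc@phases <- rbind(c(1L, 0L, 1L, 0L, 1L, 0L),
                      c(0L, 1L, 0L, 1L, 0L, 1L),
                      c(1L, 1L, 0L, 0L, 1L, 1L),
                      c(0L, 0L, 1L, 1L, 0L, 0L))
  dp2 <- tracebackGroups(computeLCG(inc, 2L, 1L, 0L), inc)
  expect_equal(length(siteClusters(dp2)), 0L)
})

test_that("classification reproduces the worked example and its boundary", {
  pt <- fig1cTable()
  dp <- tracebackGroups(figPhase(pt), pt)
  dp <- classifySites(pt, dp, isoSupportThreshold = 5L)
  expect_equal(siteClass(dp),
               c("informative", "error", "informative", "error",
                 "informative", "informative"))
  # masked sites stay masked
  ptm <- fig1cTable()
  ptm@mask[1] <- "homopolymer"
  dpm <- tracebackGroups(figPhase(ptm), ptm)
  dpm <- classifySites(ptm, dpm, isoSupportThreshold = 5L)
  expect_equal(siteClass(dpm)[1], "masked")
  # isolated site with support exactly at the threshold is informative
  iso <- strandBiasTable(c(1, 1, 0, 0), c("+", "-", "+", "-"))
  d <- classifySites(iso, tracebackGroups(computeLCG(iso, 0L, 0L)),
                     isoSupportThreshold = 2L)
  expect_equal(siteClass(d), "informative")
  d2 <- classifySites(iso, tracebackGroups(computeLCG(iso, 0L, 0L)),
                      isoSupportThreshold = 3L)
  expect_equal(siteClass(d2), "error")
})

test_that("DP and literal traceback agree with the exhaustive chain oracle", {
  set.seed(203)
  for (rep in 1:200) {
    N <- sample(1:10, 1)
    K <- sample(2:8, 1)
    pt <- randomPhaseTable(N, K)
    ms <- sample(0:2, 1); ms1 <- sample(0:1, 1); mc <- sample(0:1, 1)
    dp <- computeLCG(pt, ms, ms1, mc)
    want <- oracleLCG(sitePhases(pt), ms, ms1, mc)
    expect_equal(lcgScores(dp), want)
    tb <- tracebackGroups(dp, pt, mergeBranches = FALSE)
    if (max(want) > 1L) {
      expect_equal(length(siteClusters(tb)[[1]]), max(want))
    } else {
      expect_equal(length(siteClusters(tb)), 0L)
    }
  }
})

test_that("phasing is invariant under a consistent permutation of reads", {
  pt <- fig1cTable()
  set.seed(204)
  perm <- sample(6)
  pt2 <- pt
  pt2@phases <- pt@phases[, perm]
  pt2@quals <- pt@quals[, perm]
  pt2@strands <- pt@strands[perm]
  pt2@readIds <- pt@readIds[perm]
  d1 <- classifySites(pt, tracebackGroups(figPhase(pt), pt),
                      isoSupportThreshold = 5L)
  d2 <- classifySites(pt2, tracebackGroups(figPhase(pt2), pt2),
                      isoSupportThreshold = 5L)
  expect_equal(lcgScores(d1), lcgScores(d2))
  expect_equal(siteClusters(d1), siteClusters(d2))
  expect_equal(siteClass(d1), siteClass(d2))
})

test_that("pairwise compatibility checks are quadratic and storage linear", {
  pt <- randomPhaseTable(12L, 6L)
  dp <- computeLCG(pt, 0L, 0L, 0L)
  # score and predecessor storage are one value per site
  expect_length(lcgScores(dp), 12L)
  expect_length(lcgPred(dp), 12L)
})
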