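test_that("support selection keeps reads agreeing at informative sites", {
  pt <- fig1cTable()
  dp <- classifySites(pt, tracebackGroups(figPhase(pt), pt),
                      isoSupportThreshold = 5L)
  sup <- selectSupports(pt, dp)
  # the reads differing only at the recurrent-error and singleton sites are
  # kept; the opposite-haplotype reads are rejected
  expect_setequal(sup, c("read4", "read5", "read6"))
  # no informative sites -> every overlapping read is kept
  expect_setequal(selectSupports(pt, rep("error", 6)), pt@readIds)
  # three-haplotype case: both non-target haplotypes excluded
  pd <- fig1dTable()
  dpd <- classifySites(pd, tracebackGroups(figPhase(pd), pd),
                       isoSupportThreshold = 5L)
  expect_setequal(selectSupports(pd, dpd), c("read5", "read6"))
})

test_that("unanimous consensus repairs a single error and ties retain the target", {
  set.seed(301)
  base <- randomSeq(4000)
  t1 <- base
  substr(t1, 2000, 2000) <- setdiff(c("A", "C", "G", "T"),
                                    substr(base, 2000, 2000))[1]
  reads <- setNames(c(t1, rep(base, 5), rcStr(base)), c("T", paste0("S", 1:6)))
  ovl <- findReadOverlaps(reads, minOverlapLen = 500)
  cc <- consensusCorrect(ovl, "T", paste0("S", 1:6), reads = reads)
  expect_identical(correctedSeq(cc), base)
  expect_equal(nrow(cc@edits), 1L)
  expect_gte(cc@edits$support[1], 3L)

  # 50/50 split with minRatio above a half: the target base is retained
  alt <- setdiff(c("A", "C", "G", "T"), substr(base, 1500, 1500))[1]
  b2 <- base
  substr(b2, 1500, 1500) <- alt
  reads2 <- setNames(c(base, rep(base, 3), rep(b2, 3)),
                     c("T", paste0("S", 1:6)))
  ovl2 <- findReadOverlaps(reads2, minOverlapLen = 500)
  cc2 <- consensusCorrect(ovl2, "T", paste0("S", 1:6), reads = reads2,
                          minRatio = 0.6)
  expect_identical(correctedSeq(cc2), base)

  # deletions and insertions are repaired as well
  tdel <- paste0(substr(base, 1, 999), substr(base, 1001, 4000))
  r3 <- setNames(c(tdel, rep(base, 5)), c("T", paste0("S", 1:5)))
  o3 <- findReadOverlaps(r3, minOverlapLen = 500)
  expect_identical(correctedSeq(consensusCorrect(o3, "T", paste0("S", 1:5),
                                                 reads = r3)), base)
})

test_that("zero supports leaves the read unchanged and flagged", {
  set.seed(302)
  reads <- setNames(c(randomSeq(2000), randomSeq(2000)), c("a", "b"))
  ovl <- findReadOverlaps(reads)
  cc <- consensusCorrect(ovl, "a", character(), reads = reads)
  expect_true(cc@uncorrected)
  expect_identical(correctedSeq(cc), unname(reads["a"]))
})

test_that("correctReads on empty and noise-free input is the identity", {
  empty <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(character()), Biostrings::PhredQuality(character()))
  out <- correctReads(empty)
  expect_equal(length(out$reads), 0L)
  expect_equal(nrow(out$report), 0L)

  haps <- simulateHaplotypes(15000, 2, 0.002, seed = 41)
  m <- errorModel(0, 0, 0, recurrentSites = 0)
  sim <- simulateReads(haps, depth = 12, lengthMean = 3000, lengthSd = 300,
                       model = m, seed = 42)
  reads <- simReads(sim)
  out2 <- correctReads(reads, rounds = 1)
  expect_identical(as.character(out2$reads), as.character(reads))
})

test_that("haplotype safety: noise-free correction never crosses haplotypes", {
  haps <- simulateHaplotypes(15000, 2, 0.003, seed = 43)
  m <- errorModel(0, 0, 0, recurrentSites = 0)
  sim <- simulateReads(haps, depth = 14, lengthMean = 3500, lengthSd = 300,
                       model = m, seed = 44)
  reads <- simReads(sim)
  out <- correctReads(reads, rounds = 1)
  ev <- evaluateCorrection(out$reads, simTruth(sim), haps,
                           maskHomopolymers = FALSE)
  expect_true(all(ev$n_mismatch + ev$n_indel == 0L))
  # and kept supports never corrupt: wrong-haplotype supports cover no het
  pu <- evaluateSupportPurity(out$supports, simTruth(sim), haps)
  expect_equal(pu$corrupting, 0L)
})

test_that("the HiFi-style rule calls recurrent errors informative; phasing does not", {
  fx <- smallSim()
  reads <- simReads(fx$sim)
  truth <- simTruth(fx$sim); tr <- truthReads(truth)
  cr <- correctReads(reads, rounds = 1)
  ec <- evaluateClassification(cr$sites, truth, fx$haps)
  # the phasing-aware classifier leaves at most a tenth of the recurrent
  # sites the random-error rule would call informative
  expect_gte(ec$summary$baseline_recurrent_informative,
             10L * max(1L, ec$summary$recurrent_informative))
  # and it also rejects far fewer same-haplotype supports
  seqs <- as.character(reads)
  quals <- lapply(as.character(Biostrings::quality(reads)),
                  function(s) utf8ToInt(s) - 33L)
  ovl <- findReadOverlaps(reads)
  rej_phased <- 0L; rej_baseline <- 0L
  for (t in seq_len(40)) {
    res <- phaseTarget(ovl, t, seqsChr = seqs, qualsInt = quals)
    same <- res$table@readIds[
      tr$hap[match(res$table@readIds, tr$read_id)] == tr$hap[t]]
    kept_p <- selectSupports(res$table, res$dp)
    kept_b <- selectSupports(res$table, classifySitesBaseline(res$table))
    rej_phased <- rej_phased + sum(!(same %in% kept_p))
    rej_baseline <- rej_baseline + sum(!(same %in% kept_b))
  }
  expect_gt(rej_baseline, 4L * max(1L, rej_phased))
})

test_that("correction is close to idempotent", {
  fx <- smallSim()
  reads <- simReads(fx$sim)[1:40]
  out1 <- correctReads(reads, rounds = 2)
  out2 <- correctReads(out1$reads, rounds = 1)
  a <- paste(as.character(out1$reads), collapse = "")
  b <- paste(as.character(out2$reads), collapse = "")
  changed <- sum(out2$report$edits)
  expect_lte(changed / nchar(a), 1e-4)
})
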