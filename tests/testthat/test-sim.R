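test_that("zero heterozygosity yields identical haplotypes and no variants", {
  haps <- simulateHaplotypes(2000, ploidy = 2, hetRate = 0, seed = 42)
  expect_equal(nrow(variants(haps)), 0L)
  expect_equal(as.character(haplotypes(haps)[[1]]),
               as.character(haplotypes(haps)[[2]]))
  expect_equal(as.character(haplotypes(haps)[[1]]), haps@reference)
})

test_that("variant counts follow the binomial model", {
  counts <- vapply(1:50, function(s) {
    haps <- simulateHaplotypes(100000, ploidy = 2, hetRate = 0.001, seed = s)
    v <- variants(haps)
    sum(v$hap == 1L)
  }, numeric(1))
  mu <- 100000 * 0.001
  sigma <- sqrt(100000 * 0.001 * 0.999)
  expect_true(all(abs(counts - mu) < 3 * sigma))
  # mean of 50 draws is much tighter
  expect_lt(abs(mean(counts) - mu), 3 * sigma / sqrt(50))
})

test_that("polyploid simulation draws variants independently per haplotype", {
  haps <- simulateHaplotypes(5000, ploidy = 3, hetRate = 0.01, seed = 7)
  expect_equal(length(haplotypes(haps)), 3L)
  v <- variants(haps)
  expect_setequal(unique(v$hap), 1:3)
  # independent draws almost surely give three distinct position sets
  expect_gt(length(unique(lapply(split(v$pos, v$hap), identity))), 1L)
  expect_error(simulateHaplotypes(100, 2, 0.001), "refLength")
  expect_error(simulateHaplotypes(2000, 2, 0.5), "hetRate")
})

test_that("noise-free reads are exact substrings of their origin haplotype", {
  haps <- simulateHaplotypes(10000, 2, 0.002, seed = 3)
  m <- errorModel(0, 0, 0, recurrentSites = 0)
  sim <- simulateReads(haps, depth = 5, lengthMean = 2000, lengthSd = 300,
                       model = m, seed = 4)
  tr <- truthReads(simTruth(sim))
  hs <- as.character(haplotypes(haps))
  for (i in seq_len(nrow(tr))) {
    s <- as.character(simReads(sim)[[i]])
    if (tr$strand[i] == "-") s <- rcStr(s)
    expect_identical(s, substring(hs[tr$hap[i]], tr$start[i] + 1L, tr$end[i]))
  }
})

test_that("recurrent sites are carried with probability rho and share one allele", {
  haps <- simulateHaplotypes(30000, 2, 0, seed = 5)
  m <- errorModel(0, 0, 0, recurrentSites = 20, rho = 0.5)
  sim <- simulateReads(haps, depth = 30, lengthMean = 3000, lengthSd = 300,
                       model = m, seed = 6)
  truth <- simTruth(sim)
  tr <- truthReads(truth)
  rec <- recurrentSites(truth)
  hs <- as.character(haplotypes(haps))
  for (s in seq_len(nrow(rec))) {
    covering <- which(tr$start <= rec$pos[s] & tr$end > rec$pos[s])
    carriers <- truth@recurrentReads[[s]]
    n <- length(covering)
    # binomial(cov, 0.5) within 3 sigma
    expect_true(abs(length(carriers) - n / 2) <= 3 * sqrt(n * 0.25) + 1)
    # every carrier has the identical wrong allele at the site
    for (i in carriers) {
      m2 <- truth@originMap[[i]]
      p <- which(m2 == rec$pos[s])
      b <- substring(as.character(simReads(sim)[[i]]), p, p)
      if (tr$strand[i] == "-") b <- chartr("ACGT", "TGCA", b)
      expect_identical(b, rec$alt[s])
    }
  }
})

test_that("simulation is reproducible and the ledger is conserved", {
  haps <- simulateHaplotypes(10000, 2, 0.002, seed = 11)
  a <- simulateReads(haps, depth = 8, lengthMean = 2000, lengthSd = 300, seed = 12)
  b <- simulateReads(haps, depth = 8, lengthMean = 2000, lengthSd = 300, seed = 12)
  expect_identical(as.character(simReads(a)), as.character(simReads(b)))
  expect_identical(as.character(Biostrings::quality(simReads(a))),
                   as.character(Biostrings::quality(simReads(b))))
  expect_identical(simTruth(a)@randomErrors, simTruth(b)@randomErrors)
  # every read id in the ledger exists in the read set and vice versa
  expect_identical(names(simReads(a)), truthReads(simTruth(a))$read_id)
  # conservation: per-read ledger totals match across representations
  tot_random <- sum(vapply(simTruth(a)@randomErrors,
                           function(d) sum(d$kind != "R"), numeric(1)))
  tot_rec <- sum(lengths(simTruth(a)@recurrentReads))
  rec_marks <- sum(vapply(simTruth(a)@randomErrors,
                          function(d) sum(d$kind == "R"), numeric(1)))
  expect_gt(tot_random, 0)
  expect_equal(tot_rec, rec_marks)
})

test_that("the origin map reproduces every read base from its haplotype", {
  fx <- smallSim()
  truth <- simTruth(fx$sim); tr <- truthReads(truth)
  hs <- as.character(haplotypes(fx$haps))
  for (i in seq_len(10)) {
    s <- as.character(simReads(fx$sim)[[i]])
    b <- strsplit(s, "")[[1]]
    map <- truth@originMap[[i]]
    hb <- strsplit(hs[tr$hap[i]], "")[[1]][map + 1L]
    if (tr$strand[i] == "-") hb <- chartr("ACGT", "TGCA", hb)
    err <- truth@randomErrors[[i]]
    unexplained <- setdiff(which(b != hb) - 1L, err$pos)
    # the remaining positions are planted recurrent alleles ('R' records)
    expect_true(all(unexplained %in% err$pos[err$kind == "R"] |
                    length(unexplained) == 0L))
  }
})

test_that("evaluateCorrection counts residuals and honours the homopolymer mask", {
  haps <- simulateHaplotypes(5000, 1, 0, seed = 21)
  m <- errorModel(0, 0, 0, recurrentSites = 0)
  sim <- simulateReads(haps, depth = 2, lengthMean = 2000, lengthSd = 100,
                       model = m, seed = 22)
  truth <- simTruth(sim)
  ev <- evaluateCorrection(simReads(sim), truth, haps)
  expect_true(all(ev$zero_error))
  expect_true(all(ev$n_mismatch + ev$n_indel == 0L))

  # plant one error inside a known homopolymer and one outside
  tr <- truthReads(truth)
  hs <- as.character(haplotypes(haps)[[1]])
  i <- which(tr$strand == "+")[1]
  s <- as.character(simReads(sim)[[i]])
  origin <- substring(hs, tr$start[i] + 1, tr$end[i])
  hp <- which(phasecor:::.pc_hp_mask(origin, 4L, TRUE))
  nohp <- setdiff(seq(10, nchar(origin) - 10), hp)
  p <- nohp[100]
  substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  mod <- setNames(s, tr$read_id[i])
  ev2 <- evaluateCorrection(mod, truth, haps)
  expect_equal(ev2$n_mismatch, 1L)
  # error inside a homopolymer run is excluded when masking is on
  run <- hp[hp > 10 & hp < nchar(origin) - 10][5]
  s2 <- as.character(simReads(sim)[[i]])
  base <- substr(s2, run, run)
  substr(s2, run, run) <- setdiff(c("A", "C", "G", "T"), base)[1]
  ev3 <- evaluateCorrection(setNames(s2, tr$read_id[i]), truth, haps,
                            maskHomopolymers = TRUE)
  expect_equal(ev3$n_mismatch + ev3$n_indel, 0L)
  expect_gt(ev3$n_masked, 0L)
  expect_error(evaluateCorrection(setNames(s2, "nonsense"), truth, haps),
               "unknown read")
})

test_that("error model rejects invalid parameters", {
  expect_error(errorModel(subRate = 1.5), "rates")
  expect_error(errorModel(rho = 0), "rho")
  expect_error(errorModel(hpMultiplier = 0.5), "hpMultiplier")
  expect_error(simulateReads(simulateHaplotypes(2000, 1, 0, seed = 1),
                             lengthMean = 99999), "exceeds")
})
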