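test_that("identical reads produce one full-length forward overlap", {
  set.seed(101)
  s <- randomSeq(3000)
  reads <- setNames(c(s, s), c("a", "b"))
  ovl <- findReadOverlaps(reads, minOverlapLen = 500)
  o <- overlapTable(ovl)
  prim <- o[o$target == 2 & o$query == 1, ]
  expect_equal(nrow(prim), 1L)
  expect_equal(prim$strand, "+")
  expect_equal(c(prim$tstart, prim$tend), c(0L, 3000L))
  expect_equal(nrow(overlapDiffs(ovl)), 0L)
})

test_that("reads from disjoint intervals do not overlap", {
  set.seed(102)
  g <- randomSeq(10000)
  reads <- setNames(c(substr(g, 1, 3000), substr(g, 6000, 9000)), c("a", "b"))
  ovl <- findReadOverlaps(reads, minOverlapLen = 500)
  expect_equal(nrow(overlapTable(ovl)), 0L)
  expect_equal(nrow(overlapTable(findReadOverlaps(character()))), 0L)
})

test_that("reverse-complement reads overlap on the minus strand", {
  set.seed(103)
  s <- randomSeq(3000)
  reads <- setNames(c(s, rcStr(s)), c("a", "b"))
  ovl <- findReadOverlaps(reads, minOverlapLen = 500)
  o <- overlapTable(ovl)
  expect_true(all(o$strand == "-"))
  expect_equal(nrow(overlapDiffs(ovl)), 0L)
})

test_that("alignPair matches a full-matrix edit-distance oracle", {
  expect_equal(alignPair("ACGTACGTAC", "ACGTACGTAC")$cost, 0L)
  r <- alignPair("ACGTACGTAC", "ACGAACGTAC")
  expect_equal(r$cost, 1L)
  expect_equal(r$diffs$tpos, 3L)
  expect_equal(r$diffs$kind, "S")
  set.seed(104)
  for (rep in 1:25) {
    n <- sample(50:300, 1)
    a <- randomSeq(n)
    b <- a
    # mutate a few positions / indels
    for (k in seq_len(sample(0:8, 1))) {
      p <- sample(nchar(b), 1)
      op <- sample(3, 1)
      if (op == 1) substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      else if (op == 2) b <- paste0(substr(b, 1, p), sample(c("A","C","G","T"), 1),
                                    substr(b, p + 1, nchar(b)))
      else if (nchar(b) > 10) b <- paste0(substr(b, 1, p - 1),
                                          substr(b, p + 1, nchar(b)))
    }
    expect_equal(alignPair(a, b, band = 64)$cost, oracleEditDist(a, b))
  }
})

test_that("the pileup reproduces the diploid worked-example phase vectors", {
  # construct reads realizing the six-site example on a concrete sequence
  set.seed(105)
  g <- randomSeq(4000)
  pos <- c(x = 500L, z = 1000L, y = 1500L, t = 2000L, m = 2500L, n = 3000L)
  mut <- function(s, p, to) { substr(s, p + 1, p + 1) <- to; s }
  other <- function(s, p) setdiff(c("A", "C", "G", "T"),
                                  substr(s, p + 1, p + 1))[1]
  hap2 <- g
  for (p in pos[c("x", "y", "m", "n")]) hap2 <- mut(hap2, p, other(g, p))
  zalt <- other(g, pos["z"]); talt <- other(g, pos["t"])
  reads <- c(R = g,
             b1 = hap2, b2 = hap2, b3 = rcStr(hap2),
             o1 = mut(g, pos["z"], zalt), o2 = rcStr(mut(g, pos["z"], zalt)),
             o3 = mut(g, pos["t"], talt))
  ovl <- findReadOverlaps(reads, minOverlapLen = 500)
  pil <- buildPileup(ovl, "R", reads = reads)
  pt <- phasingTable(pil, minAlt = 1L)
  expect_equal(sitePositions(pt), unname(sort(pos)))
  ph <- sitePhases(pt)
  colnames(ph) <- pt@readIds
  # blue reads phase 1 at x,y,m,n and 0 at z,t; orange o1/o2 only at z; o3 at t
  for (b in c("b1", "b2", "b3")) {
    expect_equal(unname(ph[match(pos[c("x","y","m","n")], sitePositions(pt)), b]),
                 rep(1L, 4))
    expect_equal(unname(ph[match(pos[c("z","t")], sitePositions(pt)), b]),
                 rep(0L, 2))
  }
  expect_equal(unname(ph[match(pos["z"], sitePositions(pt)), c("o1", "o2")]),
               c(1L, 1L))
  expect_equal(unname(ph[match(pos["t"], sitePositions(pt)), "o3"]), 1L)
  sup <- siteSupport(pt)
  expect_equal(sup$n1, c(3L, 2L, 3L, 1L, 3L, 3L))
})

test_that("the pileup is invariant to overlap input order and strand flips", {
  fx <- smallSim()
  reads <- simReads(fx$sim)
  ovl <- findReadOverlaps(reads)
  p1 <- buildPileup(ovl, 3, reads = reads)

  # permute overlap rows (and remap diff references accordingly)
  o <- ovl@overlaps
  set.seed(106)
  perm <- sample(nrow(o))
  ovl2 <- ovl
  ovl2@overlaps <- o[perm, , drop = FALSE]
  rownames(ovl2@overlaps) <- NULL
  d <- ovl@diffs
  d$ovl <- match(d$ovl, perm)
  d <- d[order(d$ovl, d$tpos), , drop = FALSE]
  rownames(d) <- NULL
  ovl2@diffs <- d
  p2 <- buildPileup(ovl2, 3, reads = reads)
  expect_equal(sitePositions(p1), sitePositions(p2))
  expect_equal(siteSupport(p1), siteSupport(p2))
  # same phases after aligning column order
  co <- match(p1@readIds, p2@readIds)
  expect_equal(unname(p1@phases), unname(p2@phases[, co, drop = FALSE]))
})

test_that("noise-free diploid pileup sites sit on true heterozygous positions", {
  haps <- simulateHaplotypes(20000, 2, 0.002, seed = 31)
  m <- errorModel(0, 0, 0, recurrentSites = 0)
  sim <- simulateReads(haps, depth = 15, lengthMean = 4000, lengthSd = 500,
                       model = m, seed = 32)
  reads <- simReads(sim)
  truth <- simTruth(sim)
  ovl <- findReadOverlaps(reads)
  het <- hetPositions(haps)
  for (t in 1:5) {
    pt <- phasingTable(buildPileup(ovl, t, reads = reads), minAlt = 1L)
    g <- truth@originMap[[t]][sitePositions(pt) + 1L]
    expect_true(all(g %in% het))
  }
})

test_that("detection recovers nearly all truth overlaps at default noise", {
  fx <- smallSim()
  reads <- simReads(fx$sim)
  truth <- simTruth(fx$sim)
  det <- findReadOverlaps(reads)
  o <- overlapTable(det)
  found <- unique(paste(pmin(o$target, o$query), pmax(o$target, o$query)))
  tr <- truthReads(truth)
  n <- nrow(tr)
  want <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- min(tr$end[i], tr$end[j]) - max(tr$start[i], tr$start[j])
    if (inter >= 1500) want <- c(want, paste(i, j))
  }
  expect_gte(mean(want %in% found), 0.95)
})

test_that("PAF round-trips losslessly through write and read", {
  fx <- smallSim()
  reads <- simReads(fx$sim)[1:25]
  ovl <- findReadOverlaps(reads)
  path <- tempfile(fileext = ".paf")
  n <- writePAF(ovl, path)
  expect_gt(n, 0)
  back <- readPAF(path, reads)
  keyize <- function(x) {
    o <- overlapTable(x)
    o <- o[order(o$target, o$query, o$tstart), c("target", "query", "strand",
                                                 "tstart", "tend", "qstart",
                                                 "qend", "cost")]
    rownames(o) <- NULL
    o
  }
  expect_equal(keyize(back), keyize(ovl))
  # the edit paths are equivalent: replaying each overlap's differences on
  # its target window reconstructs the identical aligned query segment
  replay <- function(x, i) {
    o <- overlapTable(x)[i, ]
    d <- overlapDiffs(x)
    d <- d[d$ovl == i, , drop = FALSE]
    d <- d[order(d$tpos, d$kind != "I"), , drop = FALSE]
    tseq <- as.character(reads)[[o$target]]
    out <- ""
    tp <- o$tstart
    for (u in seq_len(nrow(d))) {
      out <- paste0(out, substring(tseq, tp + 1, d$tpos[u]))
      if (d$kind[u] == "S") { out <- paste0(out, d$qseq[u]); tp <- d$tpos[u] + 1L }
      else if (d$kind[u] == "I") { out <- paste0(out, d$qseq[u]); tp <- d$tpos[u] }
      else tp <- d$tpos[u] + d$len[u]
    }
    paste0(out, substring(tseq, tp + 1, o$tend))
  }
  o1 <- keyize(ovl)
  for (i in seq_len(min(40, nrow(o1)))) {
    # locate the matching record in each set (same order after keyize sort)
    m1 <- order(overlapTable(ovl)$target, overlapTable(ovl)$query,
                overlapTable(ovl)$tstart)[i]
    m2 <- order(overlapTable(back)$target, overlapTable(back)$query,
                overlapTable(back)$tstart)[i]
    expect_identical(replay(ovl, m1), replay(back, m2))
  }
  unlink(path)
})
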