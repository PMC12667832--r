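test_that("telomere detection finds tandem arrays on either strand", {
  arr <- strrep("TTAGGG", 200)
  hit <- detectTelomere(arr)
  expect_gt(nrow(hit), 0L)
  expect_true(all(hit$density >= 0.4))
  # reverse-complement array is detected too
  expect_gt(nrow(detectTelomere(strrep("CCCTAA", 200))), 0L)
  # one telomeric end on a longer contig
  set.seed(401)
  ctg <- paste0(strrep("TTAGGG", 300), randomSeq(5000))
  h2 <- detectTelomere(ctg)
  expect_equal(h2$end, "start")
  expect_error(detectTelomere(ctg, motif = ""), "non-empty")
})

test_that("random sequence stays below the telomere density threshold", {
  # expected motif coverage of random DNA: occurrences ~ Binomial with
  # p = (1/4)^6 per start for each of the two motif orientations, so the
  # covered fraction is about 2 * 6 / 4^6 ~ 0.3%, far below 0.4
  set.seed(402)
  for (r in 1:10) expect_equal(nrow(detectTelomere(randomSeq(3000))), 0L)
})

test_that("tip cleaning removes spurs but preserves telomeric tips", {
  set.seed(403)
  chain <- data.frame(id = c("u1", "u2", "u3"),
                      seq = c(randomSeq(5000), randomSeq(5000), randomSeq(5000)),
                      cov = 30, telomere = FALSE, stringsAsFactors = FALSE)
  spur <- data.frame(id = "tip1", seq = randomSeq(500), cov = 2,
                     telomere = FALSE, stringsAsFactors = FALSE)
  telo <- data.frame(id = "tip2", seq = paste0(strrep("TTAGGG", 150),
                                               randomSeq(200)),
                     cov = 2, telomere = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("u1", "u2", "u2", "u2"), fromOrient = "+",
    to = c("u2", "u3", "tip1", "tip2"), toOrient = "+",
    stringsAsFactors = FALSE)
  g <- flagTelomeres(unitigGraph(rbind(chain, spur, telo), edges))
  expect_equal(graphNodes(g)$telomere, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  cleaned <- cleanTips(g, maxTipLen = 2000, minCov = 10)
  expect_setequal(graphNodes(cleaned)$id, c("u1", "u2", "u3", "tip2"))
  # a graph without removable tips is a fixpoint
  again <- cleanTips(cleaned, maxTipLen = 2000, minCov = 10)
  expect_equal(graphNodes(again), graphNodes(cleaned))
})

test_that("telomere-flagged tips survive cleaning on random graphs", {
  set.seed(404)
  for (r in 1:50) {
    g <- randomGraph(nchain = sample(2:5, 1), nspur = sample(1:4, 1))
    g <- flagTelomeres(g)
    cleaned <- cleanTips(g, maxTipLen = 2000, minCov = 10)
    flagged <- graphNodes(g)$id[graphNodes(g)$telomere]
    expect_true(all(flagged %in% graphNodes(cleaned)$id))
    # every removed node was a short low-coverage non-telomeric dead end
    removed <- setdiff(graphNodes(g)$id, graphNodes(cleaned)$id)
    if (length(removed)) {
      info <- graphNodes(g)[match(removed, graphNodes(g)$id), ]
      expect_true(all(!info$telomere & info$cov < 10 &
                      nchar(info$seq) <= 2000))
    }
  }
})

test_that("GFA round-trips losslessly", {
  set.seed(405)
  g <- flagTelomeres(randomGraph())
  path <- tempfile(fileext = ".gfa")
  writeGFA(g, path)
  back <- readGFA(path)
  expect_equal(graphNodes(back), graphNodes(g))
  expect_equal(graphEdges(back), graphEdges(g))
  unlink(path)
})

test_that("dual-scaffolding recovers a planted gap from the other haplotype", {
  set.seed(406)
  genome <- randomSeq(150000)
  # haplotype 2 is complete; haplotype 1 is broken with a 50 kb gap
  brk <- 60000; gap <- 50000
  h1 <- c(ctgA = substr(genome, 1, brk),
          ctgB = substr(genome, brk + gap + 1, 150000))
  h2 <- c(full = genome)
  plans <- dualScaffold(h1, h2, minAnchor = 10000)
  cmp <- scaffoldComponents(plans$hap1)
  gaps <- cmp[cmp$type == "N", ]
  expect_equal(nrow(gaps), 1L)
  expect_lt(abs(gaps$gap_len - gap) / gap, 0.05)
  # contig order follows the anchor coordinates
  ws <- cmp[cmp$type == "W", ]
  expect_equal(ws$comp_id, c("ctgA", "ctgB"))
  expect_true(all(diff(ws$comp_beg) > 0))

  # the companion broken across the same region: no join
  h2b <- c(left = substr(genome, 1, brk + 2000),
           right = substr(genome, brk + gap - 2000, 150000))
  plans2 <- dualScaffold(h1, h2b, minAnchor = 10000)
  cmp2 <- scaffoldComponents(plans2$hap1)
  expect_equal(sum(cmp2$type == "N"), 0L)
  expect_equal(length(unique(cmp2$object)), 2L)

  # single-contig input is returned unchanged
  plans3 <- dualScaffold(h2, h2, minAnchor = 10000)
  cmp3 <- scaffoldComponents(plans3$hap1)
  expect_equal(nrow(cmp3), 1L)
  expect_equal(cmp3$type, "W")
  expect_error(dualScaffold(character(), h2), "non-empty")
})

test_that("AGP round-trips losslessly", {
  set.seed(407)
  genome <- randomSeq(120000)
  h1 <- c(a = substr(genome, 1, 50000), b = substr(genome, 90001, 120000))
  plans <- dualScaffold(h1, c(full = genome), minAnchor = 10000)
  path <- tempfile(fileext = ".agp")
  writeAGP(plans$hap1, path)
  back <- readAGP(path)
  expect_equal(scaffoldComponents(back), scaffoldComponents(plans$hap1))
  unlink(path)
})
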