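# Shared fixtures and independent oracles for the test suite.
# Fixtures are built in code; nothing is read from disk.

# ---- worked-example site tables --------------------------------------------

# Diploid worked example: target read with six candidate sites in positional
# order x, z, y, t, m, n. Reads 1-3 are from the opposite haplotype (differ
# at the four true het sites x, y, m, n); reads 4-5 carry a shared recurrent
# error at z; read 6 carries a singleton error at t.
fig1cTable <- function() {
  phases <- rbind(
    x = c(1L, 1L, 1L, 0L, 0L, 0L),
    z = c(0L, 0L, 0L, 1L, 1L, 0L),
    y = c(1L, 1L, 1L, 0L, 0L, 0L),
    t = c(0L, 0L, 0L, 0L, 0L, 1L),
    m = c(1L, 1L, 1L, 0L, 0L, 0L),
    n = c(1L, 1L, 1L, 0L, 0L, 0L))
  positions <- c(10L, 20L, 30L, 40L, 50L, 60L)
  new("PhasingTable",
      targetId = "R", readIds = paste0("read", 1:6),
      positions = positions,
      targetAllele = rep("A", 6),
      phases = unname(phases),
      quals = matrix(25L, 6, 6),
      strands = c("+", "-", "+", "-", "+", "-"),
      targetQual = rep(25L, 6),
      altSupport = as.integer(rowSums(phases == 1L)),
      mask = rep("none", 6))
}

# Three-haplotype worked example: reads 1-2 from copy 2 (differ at x, m),
# reads 3-4 from copy 3 (differ at y, n), reads 5-6 from the target's copy.
fig1dTable <- function() {
  phases <- rbind(
    x = c(1L, 1L, 0L, 0L, 0L, 0L),
    y = c(0L, 0L, 1L, 1L, 0L, 0L),
    m = c(1L, 1L, 0L, 0L, 0L, 0L),
    n = c(0L, 0L, 1L, 1L, 0L, 0L))
  new("PhasingTable",
      targetId = "R", readIds = paste0("read", 1:6),
      positions = c(10L, 20L, 30L, 40L),
      targetAllele = rep("A", 4),
      phases = unname(phases),
      quals = matrix(25L, 4, 6),
      strands = c("+", "-", "+", "-", "+", "-"),
      targetQual = rep(25L, 4),
      altSupport = as.integer(rowSums(phases == 1L)),
      mask = rep("none", 4))
}

# fixture-scale phasing parameters (six reads; the literal strict
# predicate, with the shared-read guards scaled to the tiny read count)
figPhase <- function(pt, mergeBranches = TRUE) {
  dp <- computeLCG(pt, minShared = 2L, minShared1 = 1L, maxConflict = 0L)
  tracebackGroups(dp, pt, mergeBranches = mergeBranches)
}

# ---- small cached simulation ------------------------------------------------

.sim_cache <- new.env(parent = emptyenv())

smallSim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    haps <- simulateHaplotypes(20000, ploidy = 2, hetRate = 0.002, seed = seed)
    sim <- simulateReads(haps, depth = 20, lengthMean = 4000, lengthSd = 800,
                         seed = seed + 1000L)
    .sim_cache[[key]] <- list(haps = haps, sim = sim)
  }
  .sim_cache[[key]]
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

rcStr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# ---- independent oracles ----------------------------------------------------

# pure-R pairwise compatibility, written against the predicate definition
# (not calling the package implementation)
oracleCompat <- function(a, b, minShared, minShared1, maxConflict) {
  both <- which(!is.na(a) & !is.na(b))
  conflict <- sum(a[both] != b[both])
  shared1 <- sum(a[both] == 1L & b[both] == 1L)
  length(both) >= minShared && conflict <= maxConflict &&
    shared1 >= minShared1 && shared1 >= 5L * conflict
}

# Exhaustive chain search: for each site i, the length of the longest
# subsequence ending at i whose adjacent pairs are compatible, found by
# enumerating all subsets (subset-incremental validity, not the package's
# recurrence).
oracleLCG <- function(phases, minShared, minShared1, maxConflict) {
  N <- nrow(phases)
  if (N == 0L) return(integer())
  comp <- matrix(FALSE, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    comp[i, j] <- oracleCompat(phases[i, ], phases[j, ],
                               minShared, minShared1, maxConflict)
  nmask <- bitwShiftL(1L, N) - 1L
  valid <- logical(nmask + 1L)
  len <- integer(nmask + 1L)
  top <- integer(nmask + 1L)
  best <- rep(1L, N)
  valid[1L] <- TRUE   # empty set (mask 0 stored at index 1)
  for (mask in seq_len(nmask)) {
    t <- floor(log2(mask))            # highest set bit (0-based site index)
    rest <- mask - bitwShiftL(1L, t)
    if (rest == 0L) {
      valid[mask + 1L] <- TRUE; len[mask + 1L] <- 1L; top[mask + 1L] <- t
    } else if (valid[rest + 1L]) {
      prev <- top[rest + 1L]
      if (comp[prev + 1L, t + 1L]) {
        valid[mask + 1L] <- TRUE
        len[mask + 1L] <- len[rest + 1L] + 1L
        top[mask + 1L] <- t
      }
    }
    if (valid[mask + 1L] && len[mask + 1L] > best[t + 1L])
      best[t + 1L] <- len[mask + 1L]
  }
  best
}

# random phasing instance: N sites x K reads with phases 0/1/* at the given
# proportions
randomPhaseTable <- function(N, K, pNA = 0.3) {
  ph <- matrix(sample(c(0L, 1L, NA_integer_), N * K, TRUE,
                      prob = c((1 - pNA) / 2, (1 - pNA) / 2, pNA)), N, K)
  new("PhasingTable",
      targetId = "R", readIds = paste0("r", seq_len(K)),
      positions = as.integer(seq_len(N) * 10L),
      targetAllele = rep("A", N),
      phases = ph, quals = matrix(25L, N, K),
      strands = rep(c("+", "-"), length.out = K),
      targetQual = rep(25L, N),
      altSupport = pmax(1L, as.integer(rowSums(ph == 1L, na.rm = TRUE))),
      mask = rep("none", N))
}

# full-matrix edit distance (unbanded, O(nm)) for short sequences
oracleEditDist <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (x[i] != y[j]),
                         prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# single-site table for the strand-bias truth table
strandBiasTable <- function(phases, strands) {
  K <- length(phases)
  new("PhasingTable",
      targetId = "R", readIds = paste0("r", seq_len(K)),
      positions = 5L, targetAllele = "A",
      phases = matrix(as.integer(phases), 1L, K),
      quals = matrix(25L, 1L, K),
      strands = strands, targetQual = 25L,
      altSupport = max(1L, sum(phases == 1L, na.rm = TRUE)),
      mask = "none")
}

# random unitig graph: a backbone chain plus random spurs, some telomeric
randomGraph <- function(nchain = 4L, nspur = 3L, telomereProb = 0.3) {
  telo <- strrep("TTAGGG", 120)
  nodes <- data.frame(
    id = sprintf("chain%02d", seq_len(nchain)),
    seq = vapply(seq_len(nchain), function(i) randomSeq(2000), ""),
    cov = 30, telomere = FALSE, stringsAsFactors = FALSE)
  edges <- if (nchain > 1L)
    data.frame(from = nodes$id[-nchain], fromOrient = "+",
               to = nodes$id[-1L], toOrient = "+", stringsAsFactors = FALSE)
  else data.frame(from = character(), fromOrient = character(),
                  to = character(), toOrient = character(),
                  stringsAsFactors = FALSE)
  for (s in seq_len(nspur)) {
    id <- sprintf("spur%02d", s)
    telomeric <- runif(1) < telomereProb
    nodes <- rbind(nodes, data.frame(
      id = id,
      seq = if (telomeric) paste0(telo, randomSeq(300)) else randomSeq(800),
      cov = 3, telomere = telomeric, stringsAsFactors = FALSE))
    at <- sample(nchain, 1L)
    edges <- rbind(edges, data.frame(
      from = nodes$id[at], fromOrient = "+", to = id, toOrient = "+",
      stringsAsFactors = FALSE))
  }
  unitigGraph(nodes, edges)
}

.subsetSitesForTest <- function(pt, idx) phasecor:::.subsetSites(pt, idx)
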