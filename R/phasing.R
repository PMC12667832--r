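#' Candidate-site table from a raw pileup
#'
#' Restricts a raw pileup to candidate informative sites: positions where at
#' least `minAlt` overlapping reads carry the \emph{identical} alternative
#' allele. A mismatch is a candidate variant only when several reads support
#' the same alternative; differences seen in a single read, or coincident
#' but conflicting differences (e.g. one read substituting, another
#' deleting), are overwhelmingly random sequencing errors and are dropped
#' before phasing. This also keeps the quadratic compatibility stage small.
#'
#' @param pileup A [PhasingTable] from [buildPileup()].
#' @param minAlt Minimum number of phase-1 reads sharing one alternative
#'   allele.
#' @return A filtered [PhasingTable].
#' @export
phasingTable <- function(pileup, minAlt = 2L) {
  stopifnot(is(pileup, "PhasingTable"))
  supp <- if (length(pileup@altSupport)) pileup@altSupport
          else rowSums(pileup@phases == 1L, na.rm = TRUE)
  .subsetSites(pileup, which(supp >= minAlt))
}

.subsetSites <- function(pt, idx) {
  new("PhasingTable", targetId = pt@targetId, readIds = pt@readIds,
      positions = pt@positions[idx],
      targetAllele = pt@targetAllele[idx],
      phases = pt@phases[idx, , drop = FALSE],
      quals = pt@quals[idx, , drop = FALSE],
      strands = pt@strands,
      targetQual = pt@targetQual[idx],
      altSupport = if (length(pt@altSupport)) pt@altSupport[idx] else integer(),
      mask = pt@mask[idx])
}

#' Homopolymer mask for candidate sites
#'
#' A site is masked when it lies inside, or immediately adjacent to, a run of
#' at least `runLen` identical bases on the target read: nanopore error rates
#' inside homopolymers are high enough that such candidate sites are more
#' likely homopolymer artifacts than variants, and they are discarded.
#'
#' @param positions Integer vector of 0-based site positions (or a
#'   [PhasingTable]).
#' @param targetSeq Target read sequence.
#' @param runLen Minimum homopolymer run length.
#' @return Logical vector: `TRUE` = masked.
#' @examples
#' maskHomopolymer(2L, "GAAAAAG", runLen = 4)   # inside the run
#' maskHomopolymer(2L, "ACGTACG", runLen = 4)   # FALSE
#' @export
maskHomopolymer <- function(positions, targetSeq, runLen = 4L) {
  if (is(positions, "PhasingTable")) positions <- positions@positions
  if (!length(positions)) return(logical())
  if (any(positions < 0L | positions >= nchar(targetSeq)))
    stop("site position outside the target")
  hp <- .pc_hp_mask(targetSeq, as.integer(runLen), TRUE)
  hp[positions + 1L]
}

#' Strand-bias mask for candidate sites
#'
#' A site is masked when the phase split aligns perfectly with sequencing
#' strand: every phase-0 read comes from one strand and every phase-1 read
#' from the other. Such perfect separation indicates a strand-specific
#' sequencing artifact rather than a variant. Sites with fewer than one read
#' in either phase are not maskable by this rule.
#'
#' @param pt A [PhasingTable].
#' @return Logical vector per site: `TRUE` = masked.
#' @export
maskStrandBias <- function(pt) {
  stopifnot(is(pt, "PhasingTable"))
  ph <- pt@phases
  if (!nrow(ph)) return(logical())
  plus <- pt@strands == "+"
  vapply(seq_len(nrow(ph)), function(i) {
    p <- ph[i, ]
    s0 <- plus[!is.na(p) & p == 0L]
    s1 <- plus[!is.na(p) & p == 1L]
    if (!length(s0) || !length(s1)) return(FALSE)
    (all(s0) && all(!s1)) || (all(!s0) && all(s1))
  }, logical(1))
}

#' Base-quality filter for candidate sites
#'
#' Bases with quality below `qThreshold` are treated as potential sequencing
#' errors and removed from the site computation: covering reads whose base at
#' the site falls below the threshold are reassigned to `*` (not covering).
#' Sites that lose all phase-1 reads are dropped; sites where the target's
#' own base is below the threshold are flagged (the target allele is still
#' trusted for phasing, since phases are defined relative to the target).
#'
#' @param pt A [PhasingTable].
#' @param qThreshold Phred threshold (default 10).
#' @return A modified [PhasingTable]; the flag of target-low-quality sites is
#'   available via `attr(x, "targetLowQual")` mapped to the retained sites.
#' @export
maskLowQuality <- function(pt, qThreshold = 10L) {
  stopifnot(is(pt, "PhasingTable"))
  if (!length(pt@positions)) return(pt)
  ph <- pt@phases
  q <- pt@quals
  drop <- !is.na(q) & q < qThreshold & !is.na(ph)
  ph[drop] <- NA_integer_
  pt@phases <- ph
  n1 <- rowSums(ph == 1L, na.rm = TRUE)
  keep <- which(n1 > 0L)
  out <- .subsetSites(pt, keep)
  attr(out, "targetLowQual") <- out@targetQual < qThreshold
  out
}

#' Compatibility of two phased sites
#'
#' Two sites are compatible if and only if every read phased (0 or 1) at both
#' sites has the identical phase at both, and at least `minShared` reads are
#' phased at both. With `minShared = 0` the predicate is vacuously true for
#' sites with disjoint coverage, the literal definition; the default of 2
#' guards against spurious chains between coverage-disjoint sites.
#'
#' In addition, `minShared1` of the agreeing reads must be phase 1 at both
#' sites: linkage between two candidate variants is evidenced by reads that
#' carry the alternative allele at both, while agreement consisting solely
#' of phase-0 reads is vacuous (two unrelated error sites whose carrier
#' reads do not see each other's position would otherwise be "compatible").
#' `minShared = 0, minShared1 = 0` reproduces the literal predicate.
#'
#' @param a,b Integer phase vectors over the same reads (0/1/`NA`), or
#'   single-row selections from the same [PhasingTable].
#' @param minShared Minimum number of co-phased reads.
#' @param minShared1 Minimum number of co-phased reads in phase 1 at both
#'   sites.
#' @param maxConflict Maximum number of co-phased reads allowed to disagree
#'   (0 = the strict predicate; the default 1 absorbs a single sequencing
#'   error landing on a variant position).
#' @return Logical scalar.
#' @examples
#' sitesCompatible(c(0L, 1L, NA), c(0L, 1L, 0L))                # TRUE
#' sitesCompatible(c(0L, 1L, 1L), c(1L, 1L, 1L), maxConflict = 0)  # FALSE
#' sitesCompatible(c(0L, NA, NA), c(NA, NA, 1L), 0L, 0L)        # vacuously TRUE
#' @export
sitesCompatible <- function(a, b, minShared = 2L, minShared1 = 1L,
                            maxConflict = 1L) {
  if (length(a) != length(b)) stop("phase vectors must have equal length")
  both <- !is.na(a) & !is.na(b)
  conflict <- sum(a[both] != b[both])
  shared1 <- sum(a[both] == 1L & b[both] == 1L)
  # each tolerated conflict needs five agreeing phase-1 reads as evidence
  sum(both) >= minShared && conflict <= maxConflict &&
    shared1 >= minShared1 && shared1 >= 5L * conflict
}

#' Largest-compatible-group dynamic program
#'
#' For the ordered site list `S`, computes `LCG[i]`, the size of the largest
#' chain of sites ending at `i` in which every site is compatible with its
#' predecessor in the chain:
#' `LCG(i) = max over j < i with S[j] ~ S[i] of LCG(j) + 1`.
#' Predecessor ties are broken toward the largest `j`. Masked sites are
#' excluded from the chain; `siteIndex` maps DP rows back to table rows.
#' Pairwise checks are quadratic in the number of sites and storage is
#' linear.
#'
#' @param pt A [PhasingTable] (after filtering).
#' @param minShared,minShared1,maxConflict Passed to the compatibility
#'   predicate ([sitesCompatible()]).
#' @return A [DPResult] with `lcg`, `pred` and `siteIndex` filled
#'   (clusters/classification empty until [tracebackGroups()] /
#'   [classifySites()]).
#' @export
computeLCG <- function(pt, minShared = 2L, minShared1 = 1L,
                       maxConflict = 1L) {
  stopifnot(is(pt, "PhasingTable"))
  idx <- which(pt@mask == "none")
  if (!length(idx))
    return(new("DPResult", lcg = integer(), pred = integer(),
               siteIndex = integer(), clusters = list(),
               classification = character()))
  ph <- pt@phases[idx, , drop = FALSE]
  r <- .pc_lcg(ph, as.integer(minShared), as.integer(minShared1),
               as.integer(maxConflict))
  pred <- r$pred + 1L
  pred[pred == 0L] <- NA_integer_
  new("DPResult", lcg = r$lcg, pred = pred, siteIndex = idx,
      clusters = list(), classification = character())
}

#' Traceback clustering of compatible sites
#'
#' Visits sites in decreasing LCG order (ties: larger index first). Each
#' unassigned site with `LCG > 1` opens a new cluster and its predecessor
#' chain is followed, adding every not-yet-assigned site on the path.
#' Clusters of final size >= 2 are kept.
#'
#' With `strict = TRUE`, each cluster is re-verified for all-pairs
#' compatibility after traceback: members incompatible with an earlier
#' member (in cluster order) are demoted out of the cluster. The chain
#' recurrence only guarantees compatibility with the predecessor, so a
#' cluster is a chain, not necessarily a clique; strict mode enforces the
#' clique reading.
#'
#' @param dp A [DPResult] from [computeLCG()].
#' @param pt The [PhasingTable] the DP was computed on (required for
#'   `strict` and branch merging).
#' @param strict Verify all-pairs compatibility within clusters.
#' @param minShared,minShared1,maxConflict Compatibility parameters for
#'   strict mode.
#' @param mergeBranches Merge a site whose predecessor chain runs into an
#'   existing cluster into that cluster (when it agrees with the cluster's
#'   phase profile). With `FALSE`, such branch sites form their own
#'   (usually singleton, hence discarded) clusters — the literal traceback.
#' @return The [DPResult] with `clusters` filled (clusters contain table row
#'   indices, i.e. values of `siteIndex`).
#' @export
tracebackGroups <- function(dp, pt = NULL, strict = FALSE, minShared = 2L,
                            minShared1 = 1L, maxConflict = 1L,
                            mergeBranches = TRUE) {
  stopifnot(is(dp, "DPResult"))
  n <- length(dp@lcg)
  if (!n) { dp@clusters <- list(); return(dp) }
  ord <- order(-dp@lcg, -seq_len(n))
  assigned <- logical(n)
  cluster_of <- rep(NA_integer_, n)
  clusters <- list()
  for (i in ord) {
    if (assigned[i] || dp@lcg[i] <= 1L) next
    path <- integer()
    j <- i
    hit <- NA_integer_
    while (!is.na(j)) {
      if (assigned[j]) {
        # the predecessor chain runs into an existing cluster: this site is
        # a branch of that group, not an isolated singleton
        hit <- cluster_of[j]
        break
      }
      path <- c(path, j); assigned[j] <- TRUE
      j <- dp@pred[j]
    }
    if (!is.na(hit) && mergeBranches) {
      # admit the branch only if its sites agree with the phase profile of
      # the group they run into (majority phase per read over its sites);
      # an unrelated chain that merely touches the group must not dilute it
      okmerge <- TRUE
      if (!is.null(pt)) {
        ph <- pt@phases[clusters[[hit]], , drop = FALSE]
        ones <- colSums(ph == 1L, na.rm = TRUE)
        zeros <- colSums(ph == 0L, na.rm = TRUE)
        profile <- ifelse(ones + zeros == 0L, NA_integer_,
                          as.integer(ones > zeros))
        okmerge <- all(vapply(dp@siteIndex[path], function(u) {
          p <- pt@phases[u, ]
          use <- !is.na(p) & !is.na(profile)
          sum(p[use] != profile[use]) <= max(1L, floor(0.1 * sum(use)))
        }, logical(1)))
      }
      if (okmerge) {
        clusters[[hit]] <- sort(c(clusters[[hit]], dp@siteIndex[path]))
        cluster_of[path] <- hit
      } else if (length(path) >= 2L) {
        clusters[[length(clusters) + 1L]] <- sort(dp@siteIndex[path])
        cluster_of[path] <- length(clusters)
      }
    } else if (length(path) >= 2L) {
      clusters[[length(clusters) + 1L]] <- sort(dp@siteIndex[path])
      cluster_of[path] <- length(clusters)
    }
  }
  if (strict && length(clusters)) {
    stopifnot(is(pt, "PhasingTable"))
    clusters <- lapply(clusters, function(cl) {
      kept <- cl[1L]
      for (s in cl[-1L]) {
        ok <- all(vapply(kept, function(u)
          sitesCompatible(pt@phases[u, ], pt@phases[s, ], minShared,
                          minShared1, maxConflict), logical(1)))
        if (ok) kept <- c(kept, s)
      }
      kept
    })
    clusters <- clusters[lengths(clusters) >= 2L]
  }
  dp@clusters <- clusters
  dp
}

#' Classify candidate sites as informative or error
#'
#' Site support is `min(n0, n1)` (phase-0 reads excluding the target, which
#' is never stored, against phase-1 reads). Grouped sites (member of any
#' cluster) supported by at least `groupedSupportThreshold` reads are
#' informative; isolated sites need `isoSupportThreshold` supporting reads; a
#' recurrent sequencing error shared by a large fraction of the covering
#' reads can reach substantial support while remaining isolated, so this
#' threshold is deliberately strict. Everything else is an error; masked
#' sites stay masked.
#'
#' Because the chain recurrence only requires each site to be compatible
#' with its predecessor, a cluster can pick up sites that conflict with the
#' phasing as a whole (a conflicting read may simply not cover the
#' predecessor). Each cluster therefore defines a phase profile — the
#' majority phase of every read across the cluster's sites — and member
#' sites whose phased reads disagree with the profile beyond a small
#' tolerance (`clusterTol`, a fraction of the site's phased reads, at least
#' one read) are demoted to isolated before classification.
#'
#' @param pt The filtered [PhasingTable].
#' @param dp A [DPResult] with clusters (see [tracebackGroups()]).
#' @param isoSupportThreshold Minimum support for isolated sites. An
#'   isolated site is inherently suspect: a recurrent error carried by the
#'   target itself splits the covering reads roughly in half, exactly like
#'   a heterozygous site, but stays isolated because its carrier set is
#'   random. The default (28) sits above the support such a site can reach
#'   at the 30x design coverage, so isolated candidates pass only with
#'   exceptional read support; true variants are recovered through
#'   clustering instead.
#' @param groupedSupportThreshold Minimum support for grouped sites.
#' @param clusterTol Tolerated fraction of profile-disagreeing reads per
#'   grouped site (`NA` disables the consistency check).
#' @param minorFrac Minimum fraction of the phased reads on the minor side
#'   of the site. A genuine variant splits the covering reads into
#'   haplotype groups, so its minor side holds roughly `1 / ploidy` of
#'   them; a site whose minor side is a tiny sliver of the coverage (for
#'   example the target's own sequencing error matched by chance by one or
#'   two reads) is never informative.
#' @return The [DPResult] with per-site `classification` filled
#'   (`"informative"`, `"error"`, `"masked"`), one entry per table site, and
#'   `clusters` updated if sites were demoted.
#' @export
classifySites <- function(pt, dp, isoSupportThreshold = 28L,
                          groupedSupportThreshold = 2L, clusterTol = 0.05,
                          minorFrac = 0.1) {
  stopifnot(is(pt, "PhasingTable"), is(dp, "DPResult"))
  n <- length(pt@positions)
  cls <- rep("error", n)
  cls[pt@mask != "none"] <- "masked"
  if (!is.na(clusterTol) && length(dp@clusters)) {
    clusters <- lapply(dp@clusters, function(cl) {
      ph <- pt@phases[cl, , drop = FALSE]
      ones <- colSums(ph == 1L, na.rm = TRUE)
      zeros <- colSums(ph == 0L, na.rm = TRUE)
      profile <- ifelse(ones + zeros == 0L, NA_integer_,
                        as.integer(ones > zeros))
      # a group whose profile assigns (almost) every read to phase 1 is a
      # chain of the target's own errors, not linked variants: a variant
      # partitions the reads, so each side of the profile must hold at
      # least the minor fraction
      pr <- profile[!is.na(profile)]
      if (length(pr) &&
          (mean(pr == 0L) < minorFrac || mean(pr == 1L) < minorFrac))
        return(integer())
      keep <- vapply(seq_along(cl), function(u) {
        p <- ph[u, ]
        use <- !is.na(p) & !is.na(profile)
        dis <- sum(p[use] != profile[use])
        dis <= max(1L, floor(clusterTol * sum(use)))
      }, logical(1))
      cl[keep]
    })
    dp@clusters <- clusters[lengths(clusters) >= 2L]
  }
  sup <- siteSupport(pt)
  support <- pmin(sup$n0, sup$n1)
  balanced <- support >= minorFrac * (sup$n0 + sup$n1)
  grouped <- logical(n)
  for (cl in dp@clusters) grouped[cl] <- TRUE
  cls[grouped & balanced & support >= groupedSupportThreshold &
        pt@mask == "none"] <- "informative"
  iso <- !grouped & pt@mask == "none"
  cls[iso & balanced & support >= isoSupportThreshold] <- "informative"
  dp@classification <- cls
  dp
}

#' HiFi-style baseline site classifier
#'
#' The classical random-error rule used for accurate (HiFi-like) reads: any
#' unmasked site whose differing allele is supported by at least `minSupport`
#' overlapping reads is informative. Recurrent errors shared by several
#' reads satisfy this rule, which is exactly the failure mode the
#' phasing-aware classifier avoids; the baseline is bundled for contrast.
#'
#' @param pt A filtered [PhasingTable].
#' @param minSupport Minimum phase-1 count.
#' @return Character vector of per-site classes (`"informative"`, `"error"`,
#'   `"masked"`).
#' @export
classifySitesBaseline <- function(pt, minSupport = 2L) {
  stopifnot(is(pt, "PhasingTable"))
  n1 <- rowSums(pt@phases == 1L, na.rm = TRUE)
  cls <- ifelse(n1 >= minSupport, "informative", "error")
  cls[pt@mask != "none"] <- "masked"
  cls
}

#' Phase one target read
#'
#' Full per-target phasing stage: raw pileup, candidate filtering, the
#' base-quality / homopolymer / strand-bias filters, the LCG dynamic
#' program, traceback clustering and site classification.
#'
#' @param ovl An [OverlapSet].
#' @param target Target read id or index.
#' @param reads Read set (for sequences and base qualities).
#' @param minAlt,qThreshold,runLen,minShared,isoSupportThreshold,groupedSupportThreshold
#'   Stage parameters, see the individual functions.
#' @param seqsChr,qualsInt Optional precomputed sequence/quality caches.
#' @param selRows,diffRows Optional precomputed per-target row indices.
#' @return A list with `table` (the filtered [PhasingTable], `mask` filled)
#'   and `dp` (the [DPResult] with clusters and classification).
#' @export
phaseTarget <- function(ovl, target, reads = NULL, minAlt = 2L,
                        qThreshold = 10L, runLen = 4L, minShared = 8L,
                        minShared1 = 2L, maxConflict = 1L, strict = FALSE,
                        isoSupportThreshold = 28L,
                        groupedSupportThreshold = 2L,
                        seqsChr = NULL, qualsInt = NULL,
                        selRows = NULL, diffRows = NULL) {
  pileup <- buildPileup(ovl, target, reads, seqsChr = seqsChr,
                        qualsInt = qualsInt, selRows = selRows,
                        diffRows = diffRows)
  pt <- phasingTable(pileup, minAlt = minAlt)
  pt <- maskLowQuality(pt, qThreshold = qThreshold)
  tidx <- if (is.character(target)) match(target, ovl@readIds) else as.integer(target)
  tseq <- if (!is.null(seqsChr)) seqsChr[[tidx]]
          else if (!is.null(reads)) as.character(reads)[[tidx]]
          else NULL
  mask <- pt@mask
  if (!is.null(tseq) && length(pt@positions))
    mask[maskHomopolymer(pt@positions, tseq, runLen)] <- "homopolymer"
  sb <- maskStrandBias(pt)
  mask[sb & mask == "none"] <- "strand"
  pt@mask <- mask
  dp <- computeLCG(pt, minShared = minShared, minShared1 = minShared1,
                   maxConflict = maxConflict)
  dp <- tracebackGroups(dp, pt, strict = strict, minShared = minShared,
                        minShared1 = minShared1, maxConflict = maxConflict)
  dp <- classifySites(pt, dp, isoSupportThreshold = isoSupportThreshold,
                      groupedSupportThreshold = groupedSupportThreshold)
  list(table = pt, dp = dp)
}
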