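#' Find candidate overlaps among reads
#'
#' Detects pairwise read overlaps by minimizer sketching (k-mer `k`, window
#' `window`) and diagonal chaining, then verifies each candidate with a
#' banded edit-distance alignment ([alignOverlaps()] is called internally).
#' Alternatively, when a [SimTruth] ledger is supplied via `truth`, candidate
#' placements are derived from the true origin intervals (any two reads whose
#' origin intervals intersect by at least `minOverlapLen` bp), which isolates
#' downstream stages from detection noise.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet], `DNAStringSet` or
#'   named character vector of reads.
#' @param k Minimizer k-mer size (11--21).
#' @param window Minimizer window size.
#' @param minOverlapLen Minimum overlap length to keep.
#' @param maxDiv Maximum alignment divergence; candidates above are dropped.
#' @param band Alignment band width.
#' @param maxIndel Indels longer than this split an overlap in two.
#' @param truth Optional [SimTruth] for truth-mode candidates.
#' @param minHits,minSpan,diagTol,maxOcc Chaining thresholds (shared
#'   minimizer count, chained span, diagonal tolerance, repeat filter).
#' @return An [OverlapSet]. Both reads of every aligned pair appear as
#'   target: each pairwise alignment is stored in both orientations.
#' @export
findReadOverlaps <- function(reads, k = 15L, window = 10L,
                             minOverlapLen = 1000L, maxDiv = 0.15,
                             band = 48L, maxIndel = 10L, truth = NULL,
                             minHits = 4L, minSpan = 500L, diagTol = 64L,
                             maxOcc = 500L) {
  ids <- names(reads)
  seqs <- as.character(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(seqs))
  names(seqs) <- ids
  if (length(seqs) == 0L)
    return(.emptyOverlapSet(ids, integer()))
  if (k < 11L || k > 21L) stop("k must lie in [11, 21]")
  lens <- nchar(seqs)

  if (is.null(truth)) {
    cand <- .pc_overlap_candidates(unname(seqs), unname(seqs), k, window,
                                   maxOcc, minHits, minSpan, diagTol, TRUE)
  } else {
    cand <- .truthCandidates(truth, lens, minOverlapLen)
  }
  if (!nrow(cand)) return(.emptyOverlapSet(ids, lens))
  keep <- (cand$tend - cand$tstart) >= minOverlapLen
  cand <- cand[keep, , drop = FALSE]
  alignOverlaps(seqs, cand, ids = ids, band = band, maxDiv = maxDiv,
                maxIndel = maxIndel, minLen = minOverlapLen)
}

.emptyOverlapSet <- function(ids, lens) {
  new("OverlapSet",
      overlaps = data.frame(target = integer(), query = integer(),
                            strand = character(), tstart = integer(),
                            tend = integer(), qstart = integer(),
                            qend = integer(), cost = integer(),
                            stringsAsFactors = FALSE),
      diffs = data.frame(ovl = integer(), tpos = integer(), kind = character(),
                         len = integer(), tseq = character(),
                         qseq = character(), qpos = integer(),
                         stringsAsFactors = FALSE),
      readIds = as.character(ids), readLengths = as.integer(lens))
}

# Candidate placements from the simulation truth: reads whose origin
# intervals intersect (haplotypes share the reference coordinate system).
.truthCandidates <- function(truth, lens, minOverlapLen) {
  tr <- truth@reads
  n <- nrow(tr)
  ord <- order(tr$start)
  t_id <- integer(); q_id <- integer(); strand <- character()
  ts <- te <- qs <- qe <- integer()
  for (u in seq_len(n)) {
    i <- ord[u]
    v <- u + 1L
    while (v <= n && tr$start[ord[v]] < tr$end[i]) {
      j <- ord[v]; v <- v + 1L
      a <- max(tr$start[i], tr$start[j]); b <- min(tr$end[i], tr$end[j])
      if (b - a < minOverlapLen) next
      # project the genomic intersection onto each read's emitted frame
      rel <- if (tr$strand[i] == tr$strand[j]) "+" else "-"
      if (tr$strand[i] == "+") {
        tcoord <- c(a - tr$start[i], b - tr$start[i])
        qcoord <- c(a - tr$start[j], b - tr$start[j])
      } else {
        tcoord <- c(tr$end[i] - b, tr$end[i] - a)
        qcoord <- c(tr$end[j] - b, tr$end[j] - a)
      }
      t_id <- c(t_id, i); q_id <- c(q_id, j); strand <- c(strand, rel)
      ts <- c(ts, tcoord[1L]); te <- c(te, tcoord[2L])
      qs <- c(qs, qcoord[1L]); qe <- c(qe, qcoord[2L])
    }
  }
  # clamp to emitted read bounds (indels shift lengths slightly)
  data.frame(target = t_id, query = q_id, strand = strand,
             tstart = pmax(0L, ts), tend = pmin(lens[t_id], te),
             qstart = pmax(0L, qs), qend = pmin(lens[q_id], qe),
             nhits = NA_integer_, stringsAsFactors = FALSE)
}

#' Align candidate overlaps
#'
#' Runs banded global edit-distance alignment over each candidate placement,
#' extracts a left-aligned difference list (substitutions and small indels;
#' indels longer than `maxIndel` split the overlap), drops candidates above
#' `maxDiv` divergence and mirrors every alignment so both reads act as
#' target.
#'
#' @param seqs Named character vector of read sequences.
#' @param candidates `data.frame` with columns `target`, `query`, `strand`,
#'   `tstart`, `tend`, `qstart`, `qend` (query coordinates in the
#'   reverse-complemented frame for `-` candidates).
#' @param ids Read identifiers (defaults to `names(seqs)`).
#' @param band,maxDiv,maxIndel,minLen See [findReadOverlaps()].
#' @return An [OverlapSet].
#' @export
alignOverlaps <- function(seqs, candidates, ids = names(seqs), band = 64L,
                          maxDiv = 0.15, maxIndel = 10L, minLen = 1000L) {
  seqs <- as.character(seqs)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(seqs))
  res <- .pc_align_batch(unname(seqs), candidates$target, candidates$query,
                         candidates$strand, candidates$tstart, candidates$tend,
                         candidates$qstart, candidates$qend,
                         band, maxDiv, maxIndel, minLen)
  ovl <- res$overlaps; dif <- res$diffs
  lens <- as.integer(nchar(seqs))
  if (nrow(ovl)) {
    flip <- .pc_flip_overlaps(ovl$target, ovl$query, ovl$strand,
                              ovl$tstart, ovl$tend, ovl$qstart, ovl$qend,
                              ovl$cost, dif$ovl, dif$tpos, dif$kind, dif$len,
                              dif$tseq, dif$qseq, dif$qpos, unname(seqs))
    fovl <- flip$overlaps; fdif <- flip$diffs
    fdif$ovl <- fdif$ovl + nrow(ovl)
    ovl <- rbind(ovl, fovl)
    dif <- rbind(dif, fdif)
    o <- order(dif$ovl, dif$tpos)
    dif <- dif[o, , drop = FALSE]
    rownames(ovl) <- rownames(dif) <- NULL
  }
  new("OverlapSet", overlaps = ovl, diffs = dif,
      readIds = as.character(ids), readLengths = lens)
}

#' Align one read pair
#'
#' Banded global edit-distance alignment of two sequences with deterministic
#' traceback (diagonal preferred over indels) and left-aligned indel
#' extraction.
#'
#' @param target,query Character scalars.
#' @param strand `"+"` or `"-"`; for `"-"` the query is reverse-complemented
#'   before alignment.
#' @param band Band width (>= 50 recommended for noisy reads).
#' @return A list with `cost` (edit cost) and `diffs` (`data.frame` of
#'   differences: `tpos`, `kind`, `len`, `tseq`, `qseq`, `qpos`).
#' @examples
#' alignPair("ACGTACGTAC", "ACGTACGTAC")$cost  # 0
#' @export
alignPair <- function(target, query, strand = "+", band = 64L) {
  if (strand == "-") query <- .pc_revcomp(query)
  .pc_align_pair(target, query, band)
}

#' Build the site pileup for a target read
#'
#' Collects, over all overlaps of the target, every target position at which
#' at least one covering read differs (substitution or indel anchored at
#' that position), and assigns each overlapping read a phase: 1 if it
#' differs there, 0 if it covers the site and matches, `*` (`NA`) otherwise.
#' The target read itself is implicitly phase 0 and never stored.
#'
#' @param ovl An [OverlapSet].
#' @param target Read id (or 1-based index) of the target.
#' @param reads The read set the overlaps were computed from (used for
#'   base qualities; a [Biostrings::QualityScaledDNAStringSet] or `NULL`
#'   for quality-less input, in which case all qualities are set to 40).
#' @param seqsChr,qualsInt Optional precomputed `as.character(reads)` and
#'   per-read integer quality list (used by the pipeline to avoid repeated
#'   conversion).
#' @param endTrim Bases trimmed from each end of every overlap before sites
#'   are called. Global alignment of a projected overlap region is least
#'   reliable at its boundaries (the projection is exact only up to the
#'   indel drift of the chained minimizers), and boundary wobble produces
#'   correlated artefact differences across reads; the trimmed margin keeps
#'   them out of the pileup.
#' @param flank A read with a difference within `flank` bases of a site (but
#'   not anchored at it) is assigned `*` rather than phase 0 there: indel
#'   placement wobbles between equivalent alignments, so such a "match" is
#'   not reliable evidence that the read agrees with the target.
#' @param selRows,diffRows Optional precomputed row indices of the target's
#'   overlaps and diffs (pipeline fast path).
#' @return A [PhasingTable] containing every difference site (`mask` all
#'   `"none"`); see [phasingTable()] for candidate filtering.
#' @export
buildPileup <- function(ovl, target, reads = NULL, seqsChr = NULL,
                        qualsInt = NULL, endTrim = 15L, flank = 3L,
                        selRows = NULL, diffRows = NULL) {
  stopifnot(is(ovl, "OverlapSet"))
  tidx <- if (is.character(target)) match(target, ovl@readIds) else as.integer(target)
  if (is.na(tidx) || tidx < 1L || tidx > length(ovl@readIds))
    stop("unknown target read: ", target)
  o <- ovl@overlaps
  sel <- if (is.null(selRows)) which(o$target == tidx) else selRows
  if (is.null(qualsInt)) qualsInt <- .readQualsInt(reads, ovl)
  tlen <- ovl@readLengths[tidx]
  tq <- qualsInt[[tidx]]
  if (!length(sel)) {
    return(new("PhasingTable", targetId = ovl@readIds[tidx],
               readIds = character(), positions = integer(),
               targetAllele = character(),
               phases = matrix(integer(), 0, 0), quals = matrix(integer(), 0, 0),
               strands = character(), targetQual = integer(),
               altSupport = integer(), mask = character()))
  }
  os <- o[sel, , drop = FALSE]
  # trimmed high-confidence interval of each overlap
  ts_t <- pmin(os$tstart + endTrim, os$tend)
  te_t <- pmax(os$tend - endTrim, os$tstart)
  dsel <- if (is.null(diffRows)) ovl@diffs[ovl@diffs$ovl %in% sel, , drop = FALSE]
          else ovl@diffs[diffRows, , drop = FALSE]
  dsel$ovl_local <- match(dsel$ovl, sel)
  # insertions anchored at the end of the target have no target base to
  # phase; boundary differences fall outside the trimmed interval
  keep <- dsel$tpos < tlen & dsel$tpos >= ts_t[dsel$ovl_local] &
    dsel$tpos < te_t[dsel$ovl_local]
  dsel <- dsel[keep, , drop = FALSE]
  qreads <- unique(os$query)
  col <- match(os$query, qreads)
  oq <- lapply(seq_along(sel), function(u) {
    q <- qualsInt[[os$query[u]]]
    if (os$strand[u] == "-") rev(q) else q
  })
  pp <- .pc_pileup(tlen, col, ts_t, te_t, os$qstart + endTrim, length(qreads),
                   dsel$ovl_local, dsel$tpos, dsel$kind, dsel$len, dsel$qseq,
                   dsel$qpos, oq, as.integer(flank))
  # per-read strand: strand of its overlap (split overlaps share the strand)
  strands <- os$strand[match(qreads, os$query)]
  pos <- pp$pos
  tseq <- if (!is.null(seqsChr)) seqsChr[[tidx]]
          else if (!is.null(reads)) as.character(reads)[[tidx]]
          else NULL
  tall <- if (!is.null(tseq) && length(pos))
    substring(tseq, pos + 1L, pos + 1L) else rep(NA_character_, length(pos))
  new("PhasingTable",
      targetId = ovl@readIds[tidx], readIds = ovl@readIds[qreads],
      positions = pos, targetAllele = tall,
      phases = pp$phase, quals = pp$qual, strands = strands,
      targetQual = if (length(pos)) tq[pos + 1L] else integer(),
      altSupport = pp$n1max,
      mask = rep("none", length(pos)))
}

# per-read integer base qualities (40 when absent)
.readQualsInt <- function(reads, ovl) {
  if (!is.null(reads) && methods::is(reads, "QualityScaledXStringSet")) {
    q <- Biostrings::quality(reads)
    lapply(as.character(q), function(s) utf8ToInt(s) - 33L)
  } else {
    lapply(ovl@readLengths, function(l) rep(40L, l))
  }
}

## ---- PAF input/output -------------------------------------------------------

.cigarFromDiffs <- function(tlen_int, qlen_int, d) {
  # reconstruct a cigar (M/X/I/D runs vs target) from interval length + diffs
  ops <- character(0); lens <- integer(0)
  push <- function(op, l) {
    if (l <= 0L) return()
    k <- length(ops)
    if (k && ops[k] == op) lens[k] <<- lens[k] + l
    else { ops[k + 1L] <<- op; lens[k + 1L] <<- l }
  }
  tp <- 0L
  if (nrow(d)) for (i in seq_len(nrow(d))) {
    push("M", d$tpos[i] - tp)
    tp <- d$tpos[i]
    if (d$kind[i] == "S") { push("X", 1L); tp <- tp + 1L }
    else if (d$kind[i] == "I") push("I", d$len[i])
    else { push("D", d$len[i]); tp <- tp + d$len[i] }
  }
  push("M", tlen_int - tp)
  paste0(lens, ops, collapse = "")
}

#' Write overlaps as PAF
#'
#' Standard 12-column PAF plus a `cg:Z` tag (cigar against the target, with
#' `M`(match)/`X`/`I`/`D` runs). Query coordinates follow PAF convention
#' (original strand, start < end). Only the primary orientation of each
#' aligned pair (target index < query index) is written.
#'
#' @param ovl An [OverlapSet].
#' @param path Output file.
#' @return Invisibly, the number of records written.
#' @export
writePAF <- function(ovl, path) {
  stopifnot(is(ovl, "OverlapSet"))
  o <- ovl@overlaps
  keep <- which(o$target < o$query)
  lines <- vapply(keep, function(i) {
    r <- o[i, ]
    qlen <- ovl@readLengths[r$query]
    if (r$strand == "-") { qs <- qlen - r$qend; qe <- qlen - r$qstart }
    else { qs <- r$qstart; qe <- r$qend }
    d <- ovl@diffs[ovl@diffs$ovl == i, , drop = FALSE]
    # at a shared anchor the insertion precedes the base-consuming event;
    # cigar coordinates are local to the overlap window
    d <- d[order(d$tpos, d$kind != "I"), , drop = FALSE]
    d$tpos <- d$tpos - r$tstart
    alen <- (r$tend - r$tstart) + sum(d$len[d$kind == "I"])
    nmatch <- alen - r$cost
    cg <- .cigarFromDiffs(r$tend - r$tstart, r$qend - r$qstart, d)
    paste(ovl@readIds[r$query], qlen, qs, qe, r$strand,
          ovl@readIds[r$target], ovl@readLengths[r$target], r$tstart, r$tend,
          nmatch, alen, 255L, paste0("cg:Z:", cg), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(length(lines))
}

#' Read overlaps from PAF
#'
#' Parses 12-column PAF with the `cg:Z` tag written by [writePAF()]. When
#' `reads` is supplied, per-base differences are reconstructed exactly by
#' replaying the cigar over the sequences, and the mirrored orientation of
#' each record is restored, yielding an [OverlapSet] equivalent to the one
#' written.
#'
#' @param path PAF file.
#' @param reads The read set (named sequences); required to recover
#'   differences.
#' @return An [OverlapSet].
#' @export
readPAF <- function(path, reads) {
  ids <- names(reads)
  seqs <- as.character(reads)
  names(seqs) <- ids
  lines <- readLines(path)
  if (!length(lines)) return(.emptyOverlapSet(ids, nchar(seqs)))
  orows <- vector("list", length(lines))
  drows <- vector("list", length(lines))
  for (u in seq_along(lines)) {
    f <- strsplit(lines[u], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) stop("malformed PAF record: ", substr(lines[u], 1, 60))
    qi <- match(f[1L], ids); ti <- match(f[6L], ids)
    if (is.na(qi) || is.na(ti)) stop("PAF references unknown read")
    qlen <- as.integer(f[2L]); qs <- as.integer(f[3L]); qe <- as.integer(f[4L])
    strand <- f[5L]
    if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    ts <- as.integer(f[8L]); te <- as.integer(f[9L])
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", f, value = TRUE)[1L])
    if (is.na(cg)) stop("PAF record lacks a cg:Z tag")
    tseq <- seqs[[ti]]
    qseqfull <- if (strand == "-") .pc_revcomp(seqs[[qi]]) else seqs[[qi]]
    ops_len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    ops <- regmatches(cg, gregexpr("[MXID]", cg))[[1L]]
    tp <- ts; qp <- qs; cost <- 0L
    dl <- list()
    for (k in seq_along(ops)) {
      L <- ops_len[k]
      if (ops[k] == "M") { tp <- tp + L; qp <- qp + L }
      else if (ops[k] == "X") {
        for (x in seq_len(L)) {
          dl[[length(dl) + 1L]] <- data.frame(
            ovl = u, tpos = tp, kind = "S", len = 1L,
            tseq = substring(tseq, tp + 1L, tp + 1L),
            qseq = substring(qseqfull, qp + 1L, qp + 1L), qpos = qp,
            stringsAsFactors = FALSE)
          tp <- tp + 1L; qp <- qp + 1L; cost <- cost + 1L
        }
      } else if (ops[k] == "I") {
        dl[[length(dl) + 1L]] <- data.frame(
          ovl = u, tpos = tp, kind = "I", len = L, tseq = "",
          qseq = substring(qseqfull, qp + 1L, qp + L), qpos = qp,
          stringsAsFactors = FALSE)
        qp <- qp + L; cost <- cost + L
      } else {
        dl[[length(dl) + 1L]] <- data.frame(
          ovl = u, tpos = tp, kind = "D", len = L,
          tseq = substring(tseq, tp + 1L, tp + L), qseq = "", qpos = qp,
          stringsAsFactors = FALSE)
        tp <- tp + L; cost <- cost + L
      }
    }
    orows[[u]] <- data.frame(target = ti, query = qi, strand = strand,
                             tstart = ts, tend = te, qstart = qs, qend = qe,
                             cost = cost, stringsAsFactors = FALSE)
    drows[[u]] <- if (length(dl)) do.call(rbind, dl) else NULL
  }
  ovl <- do.call(rbind, orows)
  dif <- do.call(rbind, drows[!vapply(drows, is.null, logical(1))])
  if (is.null(dif))
    dif <- data.frame(ovl = integer(), tpos = integer(), kind = character(),
                      len = integer(), tseq = character(), qseq = character(),
                      qpos = integer(), stringsAsFactors = FALSE)
  lens <- as.integer(nchar(seqs))
  flip <- .pc_flip_overlaps(ovl$target, ovl$query, ovl$strand,
                            ovl$tstart, ovl$tend, ovl$qstart, ovl$qend,
                            ovl$cost, dif$ovl, dif$tpos, dif$kind, dif$len,
                            dif$tseq, dif$qseq, dif$qpos, unname(seqs))
  fdif <- flip$diffs
  fdif$ovl <- fdif$ovl + nrow(ovl)
  ovl <- rbind(ovl, flip$overlaps)
  dif <- rbind(dif, fdif)
  o <- order(dif$ovl, dif$tpos)
  dif <- dif[o, , drop = FALSE]
  rownames(ovl) <- rownames(dif) <- NULL
  new("OverlapSet", overlaps = ovl, diffs = dif,
      readIds = as.character(ids), readLengths = lens)
}
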