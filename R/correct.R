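#' Select haplotype-consistent supporting reads
#'
#' A read is kept as support if and only if it shows no difference from the
#' target at any informative site it covers: its phase must be 0 or `*` at
#' every informative site. Phases at error or masked sites are ignored, so
#' reads differing from the target only at recurrent sequencing errors are
#' retained — the key improvement over the HiFi-style rule. Reads covering
#' few (or no) informative sites are still usable (`*` is non-conflicting).
#'
#' @param pt The filtered [PhasingTable].
#' @param classification Per-site classes (from [classifySites()], either the
#'   [DPResult] or its character vector).
#' @return Character vector of supporting read ids.
#' @export
selectSupports <- function(pt, classification) {
  stopifnot(is(pt, "PhasingTable"))
  if (is(classification, "DPResult")) classification <- classification@classification
  inf <- which(classification == "informative")
  if (!length(inf)) return(pt@readIds)
  ph <- pt@phases[inf, , drop = FALSE]
  ok <- colSums(ph == 1L, na.rm = TRUE) == 0L
  pt@readIds[ok]
}

#' Consensus correction of one target read
#'
#' Windowed plurality voting among the selected supports plus the target
#' itself. Support differences are grouped into clusters (separated by at
#' most `mergeGap` bases); over each cluster window, every spanning support
#' votes with the subsequence its alignment implies. Voting on sequence
#' content rather than on individual edit operations makes the outcome
#' independent of how equivalent alignments represent a dense difference
#' region. The window is rewritten when one alternative subsequence reaches
#' at least `minDepth` votes and at least `minRatio` of all votes; ties
#' retain the target. Votes involving bases below `qMin` are discarded
#' (including the target's own). Edits are applied right-to-left; edited
#' bases receive a support-depth-derived quality capped at 40.
#'
#' @param ovl An [OverlapSet].
#' @param target Target read id or index.
#' @param supports Character vector of supporting read ids (from
#'   [selectSupports()]).
#' @param reads Read set (sequences + qualities).
#' @param minDepth Minimum vote count for an edit.
#' @param minRatio Minimum vote fraction for an edit.
#' @param qMin Quality threshold for votes.
#' @param mergeGap Differences closer than this are voted as one window.
#' @param seqsChr,qualsInt Optional precomputed caches.
#' @param selRows,diffRows Optional precomputed row indices of the target's
#'   overlaps and diffs (pipeline fast path).
#' @return A [CorrectionResult].
#' @export
consensusCorrect <- function(ovl, target, supports, reads = NULL,
                             minDepth = 3L, minRatio = 0.5, qMin = 10L,
                             mergeGap = 3L, seqsChr = NULL, qualsInt = NULL,
                             selRows = NULL, diffRows = NULL) {
  stopifnot(is(ovl, "OverlapSet"))
  tidx <- if (is.character(target)) match(target, ovl@readIds) else as.integer(target)
  if (is.null(seqsChr)) seqsChr <- as.character(reads)
  if (is.null(qualsInt)) qualsInt <- .readQualsInt(reads, ovl)
  tseq <- seqsChr[[tidx]]
  tqual <- qualsInt[[tidx]]
  o <- ovl@overlaps
  sidx <- match(supports, ovl@readIds)
  cand <- if (is.null(selRows)) which(o$target == tidx) else selRows
  sel <- cand[o$query[cand] %in% sidx]
  if (!length(sel)) {
    return(new("CorrectionResult", targetId = ovl@readIds[tidx],
               seq = tseq, qual = tqual, supports = character(),
               edits = data.frame(), counters = c(supports = 0L, edits = 0L),
               uncorrected = TRUE))
  }
  os <- o[sel, , drop = FALSE]
  d <- if (is.null(diffRows)) ovl@diffs[ovl@diffs$ovl %in% sel, , drop = FALSE]
       else { dr <- diffRows[ovl@diffs$ovl[diffRows] %in% sel]
              ovl@diffs[dr, , drop = FALSE] }
  dsup <- match(d$ovl, sel)
  # per-support base qualities oriented to the alignment frame
  oq <- lapply(seq_along(sel), function(u) {
    q <- qualsInt[[os$query[u]]]
    if (os$strand[u] == "-") rev(q) else q
  })
  cons <- .pc_consensus(tseq, tqual, os$tstart, os$tend, os$qstart,
                        dsup, d$tpos, d$kind, d$len, d$tseq, d$qseq, oq,
                        as.integer(minDepth), minRatio, as.integer(qMin),
                        as.integer(mergeGap))
  new("CorrectionResult", targetId = ovl@readIds[tidx],
      seq = cons$seq, qual = cons$qual,
      supports = ovl@readIds[unique(os$query)],
      edits = cons$edits,
      counters = c(supports = length(unique(os$query)),
                   edits = nrow(cons$edits)),
      uncorrected = FALSE)
}

#' Correct a set of reads
#'
#' The full pipeline, applied per read and (optionally) over several rounds:
#' overlap detection, pileup, candidate filters, the LCG dynamic program,
#' site classification, support selection and consensus correction. Each
#' round re-overlaps the current (partially corrected) reads; later rounds
#' clean up errors that the first round could not call confidently because
#' too many supports still carried them (recurrent errors in particular).
#' Per-read processing is independent and deterministic, so parallel
#' execution (`threads`) yields byte-identical output to serial execution.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (or named character
#'   vector; qualities then default to 40).
#' @param rounds Number of correction rounds.
#' @param threads Worker processes (`parallel::mclapply`); 1 = serial.
#' @param truth Optional [SimTruth]: use truth-ledger overlap candidates in
#'   round 1 instead of minimizer detection.
#' @param k,window,minOverlapLen,maxDiv,band,maxIndel Overlap parameters, see
#'   [findReadOverlaps()].
#' @param minAlt,qThreshold,runLen,minShared,isoSupportThreshold,groupedSupportThreshold
#'   Phasing parameters, see [phaseTarget()].
#' @param minDepth,minRatio Consensus parameters, see [consensusCorrect()].
#' @return A list with:
#'   \describe{
#'     \item{reads}{corrected [Biostrings::QualityScaledDNAStringSet]}
#'     \item{report}{per-read `data.frame` (sites by class, supports, edits)}
#'     \item{sites}{round-1 per-site `data.frame` (`target_id`, `pos`, `n0`,
#'       `n1`, `mask`, `class`, `cluster`) for downstream evaluation}
#'     \item{supports}{round-1 list of supporting read ids per target}
#'     \item{sitesFinal, supportsFinal}{same, from the last round (the
#'       classification of the polished reads; equal to the above when
#'       `rounds = 1`)}
#'   }
#' @export
correctReads <- function(reads, rounds = 2L, threads = 1L, truth = NULL,
                         k = 15L, window = 10L, minOverlapLen = 1000L,
                         maxDiv = 0.15, band = 48L, maxIndel = 10L,
                         minAlt = 2L, qThreshold = 10L, runLen = 4L,
                         minShared = 8L, minShared1 = 2L, maxConflict = 1L,
                         strict = FALSE,
                         isoSupportThreshold = 28L,
                         groupedSupportThreshold = 2L,
                         minDepth = 3L, minRatio = 0.5) {
  ids <- names(reads)
  seqs <- as.character(reads)
  n <- length(seqs)
  if (n && is.null(ids)) stop("reads must be named")
  names(seqs) <- ids
  if (!n) {
    empty <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(character()), Biostrings::PhredQuality(character()))
    return(list(reads = empty,
                report = data.frame(), sites = data.frame(), supports = list()))
  }
  qualsInt <- if (methods::is(reads, "QualityScaledXStringSet"))
    lapply(as.character(Biostrings::quality(reads)), function(s) utf8ToInt(s) - 33L)
  else lapply(nchar(seqs), function(l) rep(40L, l))

  sites1 <- NULL; supports1 <- NULL; report <- NULL

  for (round in seq_len(rounds)) {
    cur <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(vapply(qualsInt, function(q)
        rawToChar(as.raw(q + 33L)), "")))
    ovl <- findReadOverlaps(cur, k = k, window = window,
                            minOverlapLen = minOverlapLen, maxDiv = maxDiv,
                            band = band, maxIndel = maxIndel,
                            truth = if (round == 1L) truth else NULL)
    ot <- ovl@overlaps$target
    byTarget <- split(seq_along(ot), ot)
    byTargetD <- split(seq_len(nrow(ovl@diffs)), ot[ovl@diffs$ovl])
    one <- function(i) {
      selRows <- byTarget[[as.character(i)]]
      diffRows <- byTargetD[[as.character(i)]]
      res <- phaseTarget(ovl, i, minAlt = minAlt, qThreshold = qThreshold,
                         runLen = runLen, minShared = minShared,
                         minShared1 = minShared1, maxConflict = maxConflict,
                         strict = strict,
                         isoSupportThreshold = isoSupportThreshold,
                         groupedSupportThreshold = groupedSupportThreshold,
                         seqsChr = seqs, qualsInt = qualsInt,
                         selRows = selRows, diffRows = diffRows)
      sup <- selectSupports(res$table, res$dp)
      cr <- consensusCorrect(ovl, i, sup, minDepth = minDepth,
                             minRatio = minRatio, qMin = qThreshold,
                             seqsChr = seqs, qualsInt = qualsInt,
                             selRows = selRows, diffRows = diffRows)
      cls <- res$dp@classification
      cluster <- rep(NA_integer_, length(res$table@positions))
      for (ci in seq_along(res$dp@clusters))
        cluster[res$dp@clusters[[ci]]] <- ci
      sup_tab <- siteSupport(res$table)
      list(seq = cr@seq, qual = cr@qual, supports = cr@supports,
           uncorrected = cr@uncorrected,
           stats = data.frame(
             target_id = rep(ids[i], length(res$table@positions)),
             pos = res$table@positions, n0 = sup_tab$n0, n1 = sup_tab$n1,
             mask = res$table@mask, class = cls, cluster = cluster,
             stringsAsFactors = FALSE),
           row = data.frame(
             read_id = ids[i],
             n_sites = length(res$table@positions),
             n_informative = sum(cls == "informative"),
             n_error = sum(cls == "error"),
             n_masked = sum(cls == "masked"),
             supports_kept = length(cr@supports),
             supports_rejected = length(res$table@readIds) - length(cr@supports),
             edits = nrow(cr@edits),
             uncorrected = cr@uncorrected,
             stringsAsFactors = FALSE))
    }
    out <- if (threads > 1L)
      parallel::mclapply(seq_len(n), one, mc.cores = threads,
                         mc.preschedule = TRUE)
    else lapply(seq_len(n), one)
    bad <- vapply(out, inherits, logical(1), "try-error")
    if (any(bad)) stop("correction failed for read ", which(bad)[1L])
    if (round == 1L) {
      sites1 <- do.call(rbind, lapply(out, `[[`, "stats"))
      supports1 <- setNames(lapply(out, `[[`, "supports"), ids)
    }
    if (round == rounds) {
      sitesF <- do.call(rbind, lapply(out, `[[`, "stats"))
      supportsF <- setNames(lapply(out, `[[`, "supports"), ids)
    }
    report <- do.call(rbind, lapply(out, `[[`, "row"))
    seqs <- setNames(vapply(out, `[[`, "", "seq"), ids)
    qualsInt <- lapply(out, `[[`, "qual")
  }

  corrected <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(vapply(qualsInt, function(q)
      rawToChar(as.raw(q + 33L)), "")))
  list(reads = corrected, report = report, sites = sites1,
       supports = supports1, sitesFinal = sitesF, supportsFinal = supportsF)
}
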