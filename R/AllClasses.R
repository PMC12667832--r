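#' Haplotype set for read simulation
#'
#' A reference sequence together with `ploidy` haplotypes derived from it by
#' single-nucleotide substitutions, so all haplotypes share the reference
#' coordinate system.
#'
#' @slot reference Character scalar, the reference sequence.
#' @slot haplotypes [Biostrings::DNAStringSet] of length `ploidy`.
#' @slot variants `data.frame` with columns `hap` (1-based haplotype index),
#'   `pos` (0-based reference position), `ref`, `alt`.
#' @slot ploidy Integer scalar, number of haplotypes.
#'
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(reference = "character", haplotypes = "ANY",
                 variants = "data.frame", ploidy = "integer"))

setValidity("HaplotypeSet", function(object) {
  msg <- NULL
  if (length(object@reference) != 1L) msg <- c(msg, "reference must be a single string")
  if (object@ploidy < 1L) msg <- c(msg, "ploidy must be >= 1")
  if (length(object@haplotypes) != object@ploidy)
    msg <- c(msg, "number of haplotypes must equal ploidy")
  v <- object@variants
  if (nrow(v)) {
    if (any(v$pos < 0L | v$pos >= nchar(object@reference)))
      msg <- c(msg, "variant positions out of range")
    for (h in unique(v$hap)) {
      p <- v$pos[v$hap == h]
      if (anyDuplicated(p) || is.unsorted(p))
        msg <- c(msg, "variant positions must be unique and sorted per haplotype")
    }
    # each haplotype differs from the reference exactly at its variants
    ref <- object@reference
    for (h in seq_len(object@ploidy)) {
      hs <- as.character(object@haplotypes[[h]])
      vh <- v[v$hap == h, , drop = FALSE]
      d <- which(utf8ToInt(hs) != utf8ToInt(ref)) - 1L
      if (!identical(sort(d), sort(vh$pos)))
        msg <- c(msg, sprintf("haplotype %d differs from reference away from its variants", h))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulation truth ledger
#'
#' Records, for every simulated read, its origin (haplotype, interval,
#' strand), the positions of its random sequencing errors, an exact per-base
#' map back to origin coordinates, plus the catalogue of planted recurrent
#' error sites and the reads carrying each recurrent allele.
#'
#' @slot reads `data.frame` with `read_id`, `hap`, `start`, `end` (0-based
#'   half-open on the haplotype), `strand` (`+`/`-`).
#' @slot recurrentSites `data.frame` with `pos` (0-based reference position),
#'   `ref`, `alt` (the fixed wrong allele).
#' @slot recurrentReads list (one entry per recurrent site) of integer read
#'   indices carrying the planted allele.
#' @slot randomErrors list (one entry per read) of `data.frame(pos, kind)`
#'   with read-coordinate error positions (`S`/`I`/`D`; `R` marks planted
#'   recurrent alleles).
#' @slot originMap list (one entry per read) of integer vectors giving, for
#'   every emitted base, its 0-based origin offset within `[start, end)` on
#'   the haplotype (`NA` for inserted bases). Stored in emitted (possibly
#'   reverse-complemented) orientation.
#'
#' @exportClass SimTruth
setClass("SimTruth",
  representation(reads = "data.frame", recurrentSites = "data.frame",
                 recurrentReads = "list", randomErrors = "list",
                 originMap = "list"))

setValidity("SimTruth", function(object) {
  msg <- NULL
  n <- nrow(object@reads)
  if (length(object@randomErrors) != n || length(object@originMap) != n)
    msg <- c(msg, "per-read ledgers must match the read table")
  if (length(object@recurrentReads) != nrow(object@recurrentSites))
    msg <- c(msg, "recurrentReads must match recurrentSites")
  if (is.null(msg)) TRUE else msg
})

#' Simulated read set
#'
#' Reads as a [Biostrings::QualityScaledDNAStringSet] plus the matching
#' [SimTruth] ledger.
#'
#' @slot reads [Biostrings::QualityScaledDNAStringSet].
#' @slot truth [SimTruth].
#'
#' @exportClass SimulatedReads
setClass("SimulatedReads", representation(reads = "ANY", truth = "SimTruth"))

setValidity("SimulatedReads", function(object) {
  if (!identical(names(object@reads), object@truth@reads$read_id))
    "read ids in the FASTQ and the truth ledger must match exactly"
  else TRUE
})

#' Pairwise overlaps between reads
#'
#' Overlap records and their per-base differences. Coordinates are 0-based
#' half-open. For `-` strand overlaps, query coordinates refer to the
#' reverse-complemented query, so the aligned query interval always runs
#' parallel to the target.
#'
#' @slot overlaps `data.frame` with `target`, `query` (1-based read indices),
#'   `strand`, `tstart`, `tend`, `qstart`, `qend`, `cost` (edit cost).
#' @slot diffs `data.frame` with `ovl` (1-based row of `overlaps`), `tpos`,
#'   `kind` (`S`/`I`/`D`), `len`, `tseq`, `qseq`, `qpos`.
#' @slot readIds Character vector of read identifiers (index space of
#'   `target`/`query`).
#' @slot readLengths Integer vector of read lengths.
#'
#' @exportClass OverlapSet
setClass("OverlapSet",
  representation(overlaps = "data.frame", diffs = "data.frame",
                 readIds = "character", readLengths = "integer"))

setValidity("OverlapSet", function(object) {
  o <- object@overlaps
  msg <- NULL
  if (nrow(o)) {
    if (any(o$tend <= o$tstart) || any(o$qend <= o$qstart))
      msg <- c(msg, "overlap intervals must satisfy end > start")
    if (any(o$target < 1L | o$target > length(object@readIds)) ||
        any(o$query < 1L | o$query > length(object@readIds)))
      msg <- c(msg, "overlap read indices out of range")
    if (any(o$tend > object@readLengths[o$target]) ||
        any(o$qend > object@readLengths[o$query]))
      msg <- c(msg, "overlap coordinates exceed read bounds")
  }
  d <- object@diffs
  if (nrow(d) && (any(d$ovl < 1L) || any(d$ovl > nrow(o))))
    msg <- c(msg, "diff records must reference an overlap row")
  if (is.null(msg)) TRUE else msg
})

#' Phased site table for one target read
#'
#' The ordered candidate informative sites of a target read, with the phase
#' of every overlapping read at every site: 0 = covers and matches the
#' target, 1 = covers and differs, `NA` = does not cover (the `*` state).
#'
#' @slot targetId Character scalar.
#' @slot readIds Character vector: the overlapping reads (matrix columns).
#' @slot positions Integer vector of 0-based target positions, strictly
#'   ascending.
#' @slot targetAllele Character vector: target base at each site.
#' @slot phases Integer matrix, sites x reads, values 0/1/`NA`.
#' @slot quals Integer matrix: query base quality at each (site, read).
#' @slot strands Character vector per read (`+`/`-`).
#' @slot targetQual Integer vector: the target's own base quality per site.
#' @slot altSupport Integer vector: the largest number of phase-1 reads
#'   sharing one identical alternative allele at the site (used for the
#'   candidate filter; 0-length when unknown, e.g. hand-built tables).
#' @slot mask Character vector per site: `"none"` or the masking filter that
#'   removed it (`"homopolymer"`, `"strand"`, `"quality"`).
#'
#' @exportClass PhasingTable
setClass("PhasingTable",
  representation(targetId = "character", readIds = "character",
                 positions = "integer", targetAllele = "character",
                 phases = "matrix", quals = "matrix", strands = "character",
                 targetQual = "integer", altSupport = "integer",
                 mask = "character"))

setValidity("PhasingTable", function(object) {
  msg <- NULL
  n <- length(object@positions)
  if (n && (is.unsorted(object@positions, strictly = TRUE)))
    msg <- c(msg, "site positions must be strictly ascending")
  if (nrow(object@phases) != n || length(object@mask) != n)
    msg <- c(msg, "per-site slots must have one entry per site")
  if (ncol(object@phases) != length(object@readIds))
    msg <- c(msg, "phase matrix must have one column per read")
  ph <- object@phases
  if (length(ph) && !all(ph[!is.na(ph)] %in% c(0L, 1L)))
    msg <- c(msg, "phases must be 0, 1 or NA")
  if (is.null(msg)) TRUE else msg
})

#' Largest-compatible-group dynamic programming result
#'
#' @slot lcg Integer vector: LCG score per site (size of the largest
#'   compatible chain ending at that site).
#' @slot pred Integer vector of predecessor indices (1-based, `NA` = none).
#' @slot siteIndex Integer vector mapping DP rows back to table rows (the DP
#'   runs on unmasked sites only).
#' @slot clusters List of integer vectors (table row indices), pairwise
#'   disjoint, each of size >= 2.
#' @slot classification Character vector per table site:
#'   `"informative"`, `"error"` or `"masked"` (empty until classified).
#'
#' @exportClass DPResult
setClass("DPResult",
  representation(lcg = "integer", pred = "integer", siteIndex = "integer",
                 clusters = "list", classification = "character"))

setValidity("DPResult", function(object) {
  msg <- NULL
  n <- length(object@lcg)
  if (length(object@pred) != n) msg <- c(msg, "pred must match lcg length")
  if (n) {
    ub <- seq_len(n)
    if (any(object@lcg < 1L) || any(object@lcg > ub))
      msg <- c(msg, "LCG scores must satisfy 1 <= LCG[i] <= i")
    has <- !is.na(object@pred)
    if (any(has) && !all(object@lcg[has] == object@lcg[object@pred[has]] + 1L))
      msg <- c(msg, "LCG[i] must equal LCG[pred[i]] + 1")
  }
  cl <- unlist(object@clusters)
  if (length(cl) && anyDuplicated(cl)) msg <- c(msg, "clusters must be disjoint")
  if (length(object@clusters) && any(lengths(object@clusters) < 2L))
    msg <- c(msg, "clusters must have size >= 2")
  if (is.null(msg)) TRUE else msg
})

#' Consensus correction result for one read
#'
#' @slot targetId Character scalar.
#' @slot seq Character scalar: corrected sequence.
#' @slot qual Integer vector: corrected per-base qualities.
#' @slot supports Character vector of supporting read ids.
#' @slot edits `data.frame` with `pos`, `kind` (`S`/`I`/`D`), `old`, `new`,
#'   `support` (vote depth).
#' @slot counters Named integer vector (sites by class, supports kept and
#'   rejected, edit count).
#' @slot uncorrected Logical: `TRUE` when no supports were available.
#'
#' @exportClass CorrectionResult
setClass("CorrectionResult",
  representation(targetId = "character", seq = "character", qual = "integer",
                 supports = "character", edits = "data.frame",
                 counters = "integer", uncorrected = "logical"))

#' Unitig graph
#'
#' A minimal bidirected assembly graph: nodes carry a sequence, a mean
#' coverage and a telomere flag; edges connect oriented node ends (GFA 1.0
#' semantics: `+` leaves the right end of `from` / enters the left end of
#' `to`).
#'
#' @slot nodes `data.frame` with `id`, `seq`, `cov`, `telomere`.
#' @slot edges `data.frame` with `from`, `fromOrient`, `to`, `toOrient`.
#'
#' @exportClass UnitigGraph
setClass("UnitigGraph",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("UnitigGraph", function(object) {
  msg <- NULL
  if (anyDuplicated(object@nodes$id)) msg <- c(msg, "node ids must be unique")
  e <- object@edges
  if (nrow(e)) {
    known <- e$from %in% object@nodes$id & e$to %in% object@nodes$id
    if (!all(known)) msg <- c(msg, "edge endpoints must reference existing nodes")
    if (!all(c(e$fromOrient, e$toOrient) %in% c("+", "-")))
      msg <- c(msg, "edge orientations must be + or -")
  }
  if (is.null(msg)) TRUE else msg
})

#' Scaffold plan
#'
#' Ordered, oriented contig placements interleaved with estimated N-gaps,
#' serialisable to AGP 2.1.
#'
#' @slot components `data.frame` with `object` (scaffold id), `part`,
#'   `type` (`W` contig / `N` gap), `comp_id`, `comp_beg`, `comp_end`
#'   (1-based inclusive, AGP style), `orientation`, `gap_len`, `gap_source`.
#'
#' @exportClass ScaffoldPlan
setClass("ScaffoldPlan", representation(components = "data.frame"))

setValidity("ScaffoldPlan", function(object) {
  cmp <- object@components
  msg <- NULL
  if (nrow(cmp)) {
    g <- cmp$type == "N"
    if (any(cmp$gap_len[g] < 1L)) msg <- c(msg, "gap lengths must be >= 1")
  }
  if (is.null(msg)) TRUE else msg
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d bp reference, ploidy %d, %d variants\n",
              nchar(object@reference), object@ploidy, nrow(object@variants)))
})

setMethod("show", "SimulatedReads", function(object) {
  cat(sprintf("SimulatedReads: %d reads, %d recurrent error sites\n",
              length(object@reads), nrow(object@truth@recurrentSites)))
})

setMethod("show", "OverlapSet", function(object) {
  cat(sprintf("OverlapSet: %d overlaps among %d reads (%d differences)\n",
              nrow(object@overlaps), length(object@readIds), nrow(object@diffs)))
})

setMethod("show", "PhasingTable", function(object) {
  cat(sprintf("PhasingTable for %s: %d sites x %d reads (%d masked)\n",
              object@targetId, length(object@positions),
              length(object@readIds), sum(object@mask != "none")))
})

setMethod("show", "DPResult", function(object) {
  cat(sprintf("DPResult: %d sites, max LCG %s, %d clusters\n",
              length(object@lcg),
              if (length(object@lcg)) max(object@lcg) else "-",
              length(object@clusters)))
})

setMethod("show", "CorrectionResult", function(object) {
  cat(sprintf("CorrectionResult for %s: %d edits, %d supports%s\n",
              object@targetId, nrow(object@edits), length(object@supports),
              if (object@uncorrected) " (uncorrected)" else ""))
})

setMethod("show", "UnitigGraph", function(object) {
  cat(sprintf("UnitigGraph: %d nodes, %d edges, %d telomere-flagged\n",
              nrow(object@nodes), nrow(object@edges), sum(object@nodes$telomere)))
})

setMethod("show", "ScaffoldPlan", function(object) {
  cmp <- object@components
  cat(sprintf("ScaffoldPlan: %d scaffolds, %d contigs, %d gaps\n",
              length(unique(cmp$object)), sum(cmp$type == "W"),
              sum(cmp$type == "N")))
})

## ---- accessors --------------------------------------------------------------

#' Accessors for phasecor classes
#'
#' Small accessor functions returning the main components of the S4 objects
#' without touching slots directly.
#'
#' @param x An object of the documented class.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
simReads <- function(x) { stopifnot(is(x, "SimulatedReads")); x@reads }

#' @rdname accessors
#' @export
simTruth <- function(x) { stopifnot(is(x, "SimulatedReads")); x@truth }

#' @rdname accessors
#' @export
truthReads <- function(x) { stopifnot(is(x, "SimTruth")); x@reads }

#' @rdname accessors
#' @export
recurrentSites <- function(x) { stopifnot(is(x, "SimTruth")); x@recurrentSites }

#' @rdname accessors
#' @export
haplotypes <- function(x) { stopifnot(is(x, "HaplotypeSet")); x@haplotypes }

#' @rdname accessors
#' @export
variants <- function(x) { stopifnot(is(x, "HaplotypeSet")); x@variants }

#' @rdname accessors
#' @export
overlapTable <- function(x) { stopifnot(is(x, "OverlapSet")); x@overlaps }

#' @rdname accessors
#' @export
overlapDiffs <- function(x) { stopifnot(is(x, "OverlapSet")); x@diffs }

#' @rdname accessors
#' @export
sitePositions <- function(x) { stopifnot(is(x, "PhasingTable")); x@positions }

#' @rdname accessors
#' @export
sitePhases <- function(x) { stopifnot(is(x, "PhasingTable")); x@phases }

#' @rdname accessors
#' @export
siteMask <- function(x) { stopifnot(is(x, "PhasingTable")); x@mask }

#' @rdname accessors
#' @export
lcgScores <- function(x) { stopifnot(is(x, "DPResult")); x@lcg }

#' @rdname accessors
#' @export
lcgPred <- function(x) { stopifnot(is(x, "DPResult")); x@pred }

#' @rdname accessors
#' @export
siteClusters <- function(x) { stopifnot(is(x, "DPResult")); x@clusters }

#' @rdname accessors
#' @export
siteClass <- function(x) { stopifnot(is(x, "DPResult")); x@classification }

#' @rdname accessors
#' @export
correctedSeq <- function(x) { stopifnot(is(x, "CorrectionResult")); x@seq }

#' @rdname accessors
#' @export
supportIds <- function(x) { stopifnot(is(x, "CorrectionResult")); x@supports }

#' @rdname accessors
#' @export
graphNodes <- function(x) { stopifnot(is(x, "UnitigGraph")); x@nodes }

#' @rdname accessors
#' @export
graphEdges <- function(x) { stopifnot(is(x, "UnitigGraph")); x@edges }

#' @rdname accessors
#' @export
scaffoldComponents <- function(x) { stopifnot(is(x, "ScaffoldPlan")); x@components }

#' Number of phased sites per read support
#'
#' Per-site support counts of a [PhasingTable]: `n0` and `n1` are the number
#' of covering reads in phase 0 and phase 1 (the target itself is implicit
#' phase 0 and never stored).
#'
#' @param x A [PhasingTable].
#' @return A `data.frame` with columns `pos`, `n0`, `n1`.
#' @export
siteSupport <- function(x) {
  stopifnot(is(x, "PhasingTable"))
  ph <- x@phases
  data.frame(pos = x@positions,
             n0 = as.integer(rowSums(ph == 0L, na.rm = TRUE)),
             n1 = as.integer(rowSums(ph == 1L, na.rm = TRUE)))
}
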