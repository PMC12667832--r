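#' Construct a unitig graph
#'
#' @param nodes `data.frame` with `id`, `seq`, `cov` and optionally
#'   `telomere` (default `FALSE`).
#' @param edges `data.frame` with `from`, `fromOrient`, `to`, `toOrient`
#'   (GFA 1.0 link semantics).
#' @return A [UnitigGraph].
#' @export
unitigGraph <- function(nodes, edges = NULL) {
  if (is.null(nodes$telomere)) nodes$telomere <- FALSE
  if (is.null(edges))
    edges <- data.frame(from = character(), fromOrient = character(),
                        to = character(), toOrient = character(),
                        stringsAsFactors = FALSE)
  nodes$id <- as.character(nodes$id)
  new("UnitigGraph", nodes = as.data.frame(nodes, stringsAsFactors = FALSE),
      edges = as.data.frame(edges, stringsAsFactors = FALSE))
}

#' Detect telomeric repeat arrays at sequence ends
#'
#' Scans the terminal `window` bases at each end of the sequence for the
#' telomere motif (default the vertebrate repeat `TTAGGG`) and its reverse
#' complement, and reports ends where the fraction of bases covered by motif
#' occurrences reaches `minDensity`. Sequences shorter than the window are
#' scanned as a single whole-sequence window.
#'
#' @param seq Character scalar (or `DNAString`).
#' @param motif Telomere repeat motif.
#' @param window Terminal window size in bp.
#' @param minDensity Minimum motif-covered fraction.
#' @return A `data.frame` with one row per telomeric terminal window:
#'   `end` (`"start"`/`"end"`), `start`, `width` (0-based half-open interval
#'   on the sequence) and `density`. Zero rows when no end qualifies.
#' @examples
#' detectTelomere(strrep("TTAGGG", 200))
#' @export
detectTelomere <- function(seq, motif = "TTAGGG", window = 1000L,
                           minDensity = 0.4) {
  seq <- as.character(seq)
  if (!nchar(motif)) stop("motif must be non-empty")
  n <- nchar(seq)
  wins <- if (n <= window)
    data.frame(end = "whole", start = 0L, width = n, stringsAsFactors = FALSE)
  else
    data.frame(end = c("start", "end"), start = c(0L, n - as.integer(window)),
               width = as.integer(window), stringsAsFactors = FALSE)
  dens <- vapply(seq_len(nrow(wins)), function(i) {
    s <- substring(seq, wins$start[i] + 1L, wins$start[i] + wins$width[i])
    .motifDensity(s, motif)
  }, numeric(1))
  wins$density <- dens
  wins[wins$density >= minDensity, , drop = FALSE]
}

.motifDensity <- function(s, motif) {
  subject <- Biostrings::DNAString(s)
  cov <- rep(FALSE, nchar(s))
  for (m in unique(c(motif, as.character(
         Biostrings::reverseComplement(Biostrings::DNAString(motif)))))) {
    hits <- Biostrings::matchPattern(m, subject)
    if (length(hits))
      for (i in seq_along(hits)) {
        st <- IRanges::start(hits)[i]; en <- IRanges::end(hits)[i]
        cov[st:en] <- TRUE
      }
  }
  mean(cov)
}

#' Flag telomeric nodes of a unitig graph
#'
#' Runs [detectTelomere()] on every node sequence and sets the node telomere
#' flag where any terminal window qualifies.
#'
#' @param graph A [UnitigGraph].
#' @param ... Passed to [detectTelomere()].
#' @return The graph with updated telomere flags.
#' @export
flagTelomeres <- function(graph, ...) {
  stopifnot(is(graph, "UnitigGraph"))
  graph@nodes$telomere <- vapply(graph@nodes$seq, function(s)
    nrow(detectTelomere(s, ...)) > 0L, logical(1), USE.NAMES = FALSE)
  graph
}

.endDegrees <- function(nodes, edges) {
  left <- setNames(integer(nrow(nodes)), nodes$id)
  right <- left
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]; t <- edges$to[i]
    if (edges$fromOrient[i] == "+") right[f] <- right[f] + 1L
    else left[f] <- left[f] + 1L
    if (edges$toOrient[i] == "+") left[t] <- left[t] + 1L
    else right[t] <- right[t] + 1L
  }
  list(left = left, right = right)
}

#' Remove graph tips, preserving telomeres
#'
#' A tip is a dead-end node: at least one of its two ends has no incident
#' edge. Tips whose sequence length is at most `maxTipLen` and whose
#' coverage is below `minCov` are removed — unless their telomere flag is
#' set, since genuine chromosome ends also present as tips and discarding
#' them silently drops telomere sequence from the assembly. Removal proceeds
#' in ascending node id order and iterates to a fixpoint.
#'
#' @param graph A [UnitigGraph] (flag telomeres first, e.g. with
#'   [flagTelomeres()]).
#' @param maxTipLen Maximum sequence length of a removable tip.
#' @param minCov Coverage below which a tip is removable.
#' @return The cleaned [UnitigGraph].
#' @export
cleanTips <- function(graph, maxTipLen = 50000L, minCov = 10) {
  stopifnot(is(graph, "UnitigGraph"))
  nodes <- graph@nodes
  edges <- graph@edges
  repeat {
    deg <- .endDegrees(nodes, edges)
    len <- nchar(nodes$seq)
    cand <- nodes$id[(deg$left[nodes$id] == 0L | deg$right[nodes$id] == 0L) &
                     len <= maxTipLen & nodes$cov < minCov & !nodes$telomere]
    if (!length(cand)) break
    removed <- FALSE
    for (id in sort(cand)) {
      # re-check degrees against the current edge set (sequential removal)
      deg <- .endDegrees(nodes, edges)
      i <- match(id, nodes$id)
      if (is.na(i)) next
      if (deg$left[id] != 0L && deg$right[id] != 0L) next
      nodes <- nodes[-i, , drop = FALSE]
      edges <- edges[edges$from != id & edges$to != id, , drop = FALSE]
      removed <- TRUE
    }
    if (!removed) break
  }
  rownames(nodes) <- rownames(edges) <- NULL
  new("UnitigGraph", nodes = nodes, edges = edges)
}

#' Dual-scaffolding across haplotypes
#'
#' Scaffolds the contigs of one haplotype using the other haplotype as a
#' reference: each contig is anchored onto the other haplotype's contigs by
#' minimizer chaining (anchor span at least `minAnchor`); two contigs whose
#' anchors land co-linearly on one gap-free companion contig, within
#' `maxGap`, are joined into a scaffold with an N-gap whose length is the
#' inter-anchor distance on the companion haplotype (floor 1). Contigs with
#' ambiguous or conflicting anchors are left unscaffolded, as are joins
#' whose spanned companion region contains `N`s (the companion must be
#' completely assembled across the gap).
#'
#' @param hap1,hap2 Named character vectors or `DNAStringSet`s of contigs.
#' @param minAnchor Minimum anchor span in bp.
#' @param maxGap Maximum estimated gap length to bridge.
#' @param k,window Minimizer parameters.
#' @return A list of two [ScaffoldPlan]s (`hap1` scaffolded against `hap2`
#'   and vice versa).
#' @export
dualScaffold <- function(hap1, hap2, minAnchor = 10000L, maxGap = 1000000L,
                         k = 15L, window = 10L) {
  n1 <- names(hap1); n2 <- names(hap2)
  h1 <- as.character(hap1); h2 <- as.character(hap2)
  if (!length(h1) || !length(h2)) stop("both haplotype contig sets must be non-empty")
  names(h1) <- if (is.null(n1)) sprintf("h1tg%03d", seq_along(h1)) else n1
  names(h2) <- if (is.null(n2)) sprintf("h2tg%03d", seq_along(h2)) else n2
  list(hap1 = .scaffoldOne(h1, h2, minAnchor, maxGap, k, window),
       hap2 = .scaffoldOne(h2, h1, minAnchor, maxGap, k, window))
}

.scaffoldOne <- function(ctgs, ref, minAnchor, maxGap, k, window) {
  cand <- .pc_overlap_candidates(unname(ref), unname(ctgs), k, window,
                                 2000L, 10L, as.integer(minAnchor), 200L, FALSE)
  # best unique anchor per contig
  anchors <- lapply(seq_along(ctgs), function(i) {
    h <- cand[cand$query == i, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h <- h[order(-h$nhits), , drop = FALSE]
    if (nrow(h) >= 2L && h$nhits[2L] >= 0.5 * h$nhits[1L] &&
        h$target[2L] != h$target[1L]) return(NULL)  # ambiguous
    if (h$tend[1L] - h$tstart[1L] < minAnchor) return(NULL)
    h[1L, ]
  })
  placed <- which(!vapply(anchors, is.null, logical(1)))
  plan <- list()
  used <- character()
  scafn <- 0L
  if (length(placed)) {
    a <- do.call(rbind, anchors[placed])
    a$ctg <- placed
    for (tid in sort(unique(a$target))) {
      grp <- a[a$target == tid, , drop = FALSE]
      grp <- grp[order(grp$tstart), , drop = FALSE]
      refseq <- ref[[tid]]
      chain <- list(grp[1L, ])
      for (i in seq_len(nrow(grp))[-1L]) {
        prev <- chain[[length(chain)]]
        gap <- grp$tstart[i] - prev$tend
        spanned <- if (gap > 0L)
          substring(refseq, prev$tend + 1L, grp$tstart[i]) else ""
        ok <- gap <= maxGap && gap > -minAnchor &&
          !grepl("N", spanned, fixed = TRUE)
        if (ok) chain[[length(chain) + 1L]] <- grp[i, ]
        else {
          plan[[length(plan) + 1L]] <- chain
          chain <- list(grp[i, ])
        }
      }
      plan[[length(plan) + 1L]] <- chain
    }
  }
  # emit components
  comp <- list()
  for (ch in plan) {
    scafn <- scafn + 1L
    obj <- sprintf("scaffold%03d", scafn)
    beg <- 1L; part <- 0L
    for (i in seq_along(ch)) {
      e <- ch[[i]]
      cid <- names(ctgs)[e$ctg]
      used <- c(used, cid)
      clen <- nchar(ctgs[[e$ctg]])
      if (i > 1L) {
        prev <- ch[[i - 1L]]
        gap <- max(1L, e$tstart - prev$tend)
        part <- part + 1L
        comp[[length(comp) + 1L]] <- data.frame(
          object = obj, part = part, type = "N", comp_id = NA_character_,
          comp_beg = beg, comp_end = beg + gap - 1L, orientation = NA_character_,
          gap_len = gap, gap_source = "other-haplotype",
          stringsAsFactors = FALSE)
        beg <- beg + gap
      }
      part <- part + 1L
      comp[[length(comp) + 1L]] <- data.frame(
        object = obj, part = part, type = "W", comp_id = cid,
        comp_beg = beg, comp_end = beg + clen - 1L,
        orientation = e$strand, gap_len = NA_integer_,
        gap_source = NA_character_, stringsAsFactors = FALSE)
      beg <- beg + clen
    }
  }
  # unplaced contigs become singleton scaffolds, in input order
  for (i in seq_along(ctgs)) {
    cid <- names(ctgs)[i]
    if (cid %in% used) next
    scafn <- scafn + 1L
    comp[[length(comp) + 1L]] <- data.frame(
      object = sprintf("scaffold%03d", scafn), part = 1L, type = "W",
      comp_id = cid, comp_beg = 1L, comp_end = nchar(ctgs[[i]]),
      orientation = "+", gap_len = NA_integer_, gap_source = NA_character_,
      stringsAsFactors = FALSE)
  }
  new("ScaffoldPlan", components = if (length(comp)) do.call(rbind, comp)
      else data.frame(object = character(), part = integer(), type = character(),
                      comp_id = character(), comp_beg = integer(),
                      comp_end = integer(), orientation = character(),
                      gap_len = integer(), gap_source = character(),
                      stringsAsFactors = FALSE))
}

## ---- GFA / AGP input and output --------------------------------------------

#' Write a unitig graph as GFA 1.0
#'
#' Segments carry coverage (`dp:f`) and the telomere flag (`tl:i`); links use
#' a `0M` overlap. The representation round-trips losslessly through
#' [readGFA()].
#'
#' @param graph A [UnitigGraph].
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
writeGFA <- function(graph, path) {
  stopifnot(is(graph, "UnitigGraph"))
  n <- graph@nodes; e <- graph@edges
  lines <- c("H\tVN:Z:1.0",
    sprintf("S\t%s\t%s\tdp:f:%.6g\ttl:i:%d", n$id, n$seq, n$cov,
            as.integer(n$telomere)),
    if (nrow(e)) sprintf("L\t%s\t%s\t%s\t%s\t0M", e$from, e$fromOrient,
                         e$to, e$toOrient))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFA 1.0 unitig graph
#'
#' @param path GFA file written by [writeGFA()] (or compatible: `S` lines
#'   with optional `dp:f`/`tl:i` tags, `L` lines).
#' @return A [UnitigGraph].
#' @export
readGFA <- function(path) {
  lines <- readLines(path)
  sl <- strsplit(lines[startsWith(lines, "S\t")], "\t", fixed = TRUE)
  el <- strsplit(lines[startsWith(lines, "L\t")], "\t", fixed = TRUE)
  tagval <- function(f, tag, default) {
    hit <- grep(paste0("^", tag, ":"), f)
    if (length(hit)) sub(paste0(tag, ":[A-Za-z]:"), "", f[hit[1L]]) else default
  }
  nodes <- do.call(rbind, lapply(sl, function(f)
    data.frame(id = f[2L], seq = f[3L],
               cov = as.numeric(tagval(f[-(1:3)], "dp", "0")),
               telomere = as.integer(tagval(f[-(1:3)], "tl", "0")) == 1L,
               stringsAsFactors = FALSE)))
  edges <- if (length(el)) do.call(rbind, lapply(el, function(f)
    data.frame(from = f[2L], fromOrient = f[3L], to = f[4L], toOrient = f[5L],
               stringsAsFactors = FALSE))) else NULL
  unitigGraph(nodes, edges)
}

#' Write a scaffold plan as AGP 2.1
#'
#' @param plan A [ScaffoldPlan].
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
writeAGP <- function(plan, path) {
  stopifnot(is(plan, "ScaffoldPlan"))
  cmp <- plan@components
  lines <- vapply(seq_len(nrow(cmp)), function(i) {
    r <- cmp[i, ]
    if (r$type == "W")
      paste(r$object, r$comp_beg, r$comp_end, r$part, "W", r$comp_id,
            1L, r$comp_end - r$comp_beg + 1L, r$orientation, sep = "\t")
    else
      paste(r$object, r$comp_beg, r$comp_end, r$part, "N", r$gap_len,
            "scaffold", "yes", "align_genus", sep = "\t")
  }, "")
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Read an AGP 2.1 scaffold plan
#'
#' @param path AGP file written by [writeAGP()].
#' @return A [ScaffoldPlan].
#' @export
readAGP <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  comp <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (f[5L] == "W")
      data.frame(object = f[1L], part = as.integer(f[4L]), type = "W",
                 comp_id = f[6L], comp_beg = as.integer(f[2L]),
                 comp_end = as.integer(f[3L]), orientation = f[9L],
                 gap_len = NA_integer_, gap_source = NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(object = f[1L], part = as.integer(f[4L]), type = "N",
                 comp_id = NA_character_, comp_beg = as.integer(f[2L]),
                 comp_end = as.integer(f[3L]), orientation = NA_character_,
                 gap_len = as.integer(f[6L]), gap_source = "other-haplotype",
                 stringsAsFactors = FALSE)
  }))
  new("ScaffoldPlan", components = comp)
}
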